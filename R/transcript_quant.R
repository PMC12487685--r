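#' Fragments per kilobase of transcript per million mapped fragments
#'
#' Computes FPKM as `count / (length_kb * library_size_millions)`. Isoform
#' counts should be pooled per gene before calling.
#'
#' @param fragment_count Mapped fragment count(s) per gene (>= 0).
#' @param length_kb Transcript length(s) in kilobases (> 0).
#' @param library_size_millions Total mapped fragments in millions (> 0).
#'
#' @return Numeric vector of FPKM values.
#' @examples
#' compute_fpkm(100, 2, 10)  # 5
#' @export
compute_fpkm <- function(fragment_count, length_kb, library_size_millions) {
  if (any(fragment_count < 0)) stop("`fragment_count` must be >= 0")
  if (any(length_kb <= 0))
    stop("`length_kb` must be > 0: a zero transcript length is invalid")
  if (any(library_size_millions <= 0))
    stop("`library_size_millions` must be > 0: empty library is invalid")
  fragment_count / (length_kb * library_size_millions)
}

#' Reference/alternate allele fractions and fold ratio
#'
#' From reference- and alternate-allele read counts at one variant
#' position, computes the two allele fractions (which sum to one) and the
#' reference-over-alternate fold ratio.
#'
#' @param ref_count Reads carrying the reference (wild-type, A) allele.
#' @param alt_count Reads carrying the alternate (mutant, G) allele.
#'
#' @return List with `ref_fraction`, `alt_fraction`, `ref_over_alt_fold`
#'   (`NA` with a warning when `alt_count` is 0).
#' @export
allele_fractions <- function(ref_count, alt_count) {
  if (ref_count < 0 || alt_count < 0) stop("counts must be >= 0")
  total <- ref_count + alt_count
  if (total <= 0) stop("total read count must be > 0")
  fold <- if (alt_count == 0) {
    warning("alternate count is 0; ref/alt fold is undefined")
    NA_real_
  } else ref_count / alt_count
  list(ref_fraction = ref_count / total,
       alt_fraction = alt_count / total,
       ref_over_alt_fold = fold)
}

#' Alternate-allele fraction implied by a reference/alternate fold ratio
#'
#' If reference reads exceed alternate reads by `fold`, the alternate
#' allele contributes `1 / (1 + fold)` of transcripts from that gene.
#'
#' @param ref_over_alt_fold Reference-over-alternate fold ratio (> 0).
#' @return Alternate-allele fraction in `(0, 1)`.
#' @examples
#' allele_fraction_from_fold(2.34)  # ~0.30
#' @export
allele_fraction_from_fold <- function(ref_over_alt_fold) {
  if (ref_over_alt_fold <= 0) stop("fold must be > 0")
  1 / (1 + ref_over_alt_fold)
}

#' Mutant allele share of the total calmodulin transcript pool
#'
#' The three Calm genes encode an identical protein, so the functional
#' impact of a mutant allele scales with its share of the pooled Calm
#' transcript output: `alt_fraction * FPKM_Calm1 / sum(FPKM_Calm1..3)`.
#'
#' @param alt_fraction Fraction of the mutated gene's transcripts carrying
#'   the mutant allele, in `[0, 1]`.
#' @param fpkm Numeric vector of per-gene FPKM values; the first element
#'   (or the element named `"Calm1"`) is the mutated gene.
#'
#' @return Share as a percentage rounded to one decimal; the unrounded
#'   value is kept in attribute `raw_percent`.
#' @examples
#' mutant_transcript_share(0.30, c(Calm1 = 34.8, Calm2 = 49, Calm3 = 41.4))
#' @export
mutant_transcript_share <- function(alt_fraction, fpkm) {
  if (alt_fraction < 0 || alt_fraction > 1)
    stop("`alt_fraction` must lie in [0, 1]")
  if (any(fpkm < 0)) stop("`fpkm` values must be >= 0")
  if (sum(fpkm) <= 0) stop("all-zero FPKM vector: share is undefined")
  idx <- if (!is.null(names(fpkm)) && "Calm1" %in% names(fpkm))
    which(names(fpkm) == "Calm1")[1] else 1L
  raw <- 100 * alt_fraction * fpkm[[idx]] / sum(fpkm)
  structure(round(raw, 1), raw_percent = raw)
}

#' Per-gene share of the pooled calmodulin transcript output
#'
#' @param fpkm Numeric vector of per-gene FPKM values (>= 0, not all zero).
#' @return Percentages rounded to one decimal (raw values in attribute
#'   `raw_percent`).
#' @export
gene_share_percent <- function(fpkm) {
  if (any(fpkm < 0)) stop("`fpkm` values must be >= 0")
  if (sum(fpkm) <= 0) stop("all-zero FPKM vector: shares are undefined")
  raw <- 100 * fpkm / sum(fpkm)
  structure(round(raw, 1), raw_percent = raw)
}

#' Chamber-level absolute transcript estimate by the 2^-ddCt method
#'
#' Computes relative expression of one gene in a target tissue versus a
#' calibrator tissue from qPCR threshold cycles, each normalised to a
#' reference gene (dCt = Ct_gene - Ct_reference), and scales the calibrator
#' tissue's FPKM by the resulting fold change to estimate absolute
#' transcript levels in the target tissue. Error margins follow the
#' `2^-(ddCt -/+ SEM)` convention, with the SEM taken over the
#' target-tissue dCt replicates.
#'
#' @param ct Data frame with columns `gene`, `tissue`, `replicate`, `ct`,
#'   `ref_ct` (threshold cycles of the gene of interest and the reference
#'   gene for the same replicate).
#' @param gene Gene to quantify.
#' @param target_tissue,calibrator_tissue Tissue labels present in `ct`.
#' @param calibrator_fpkm FPKM of `gene` in the calibrator tissue (the
#'   left-ventricle RNA-seq value in the intended workflow).
#'
#' @return List with `fold_change` (2^-ddCt), `estimate`
#'   (fold * calibrator FPKM), `margin_low`, `margin_high`, `ddct`, `sem`.
#' @export
ddct_estimate <- function(ct, gene, target_tissue, calibrator_tissue,
                          calibrator_fpkm) {
  need <- c("gene", "tissue", "ct", "ref_ct")
  if (!all(need %in% names(ct)))
    stop("`ct` must have columns gene, tissue, ct, ref_ct")
  sub <- ct[ct$gene == gene, , drop = FALSE]
  if (any(!is.finite(sub$ct)) || any(!is.finite(sub$ref_ct)))
    stop("missing reference-gene or target Ct values")
  dct <- sub$ct - sub$ref_ct
  tgt <- dct[sub$tissue == target_tissue]
  cal <- dct[sub$tissue == calibrator_tissue]
  if (length(tgt) < 1 || length(cal) < 1)
    stop("need at least one replicate per tissue")
  ddct <- mean(tgt) - mean(cal)
  sem <- if (length(tgt) > 1) stats::sd(tgt) / sqrt(length(tgt)) else NA_real_
  fold <- 2^(-ddct)
  list(fold_change = fold,
       estimate = fold * calibrator_fpkm,
       margin_low = 2^(-(ddct + sem)) * calibrator_fpkm,
       margin_high = 2^(-(ddct - sem)) * calibrator_fpkm,
       ddct = ddct, sem = sem)
}
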