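monoisotopic_deltas <- c(d13C = 1.003355, d15N = 0.997035)

#' Mass shift of an isotope-labelled peptide standard
#'
#' Monoisotopic mass increase produced by substituting `n_13c` carbons with
#' 13C (+1.003355 Da each) and `n_15n` nitrogens with 15N (+0.997035 Da
#' each), e.g. a heavy leucine with six 13C and one 15N shifts the peptide
#' by 7.017 Da, conventionally reported as a 7 Da shift.
#'
#' @param n_13c Number of 13C substitutions (>= 0).
#' @param n_15n Number of 15N substitutions (>= 0).
#'
#' @return Mass shift in Da (use `round()` for the integer convention).
#' @examples
#' heavy_label_mass_shift(6, 1)  # 7.017165
#' @export
heavy_label_mass_shift <- function(n_13c, n_15n) {
  if (n_13c < 0 || n_15n < 0) stop("isotope counts must be >= 0")
  n_13c * monoisotopic_deltas[["d13C"]] + n_15n * monoisotopic_deltas[["d15N"]]
}

#' Absolute peptide amount by single-point isotope dilution
#'
#' The endogenous (light) amount is the spiked heavy-standard amount scaled
#' by the light/heavy peak-area ratio. The estimate is invariant to any
#' common detector gain applied to both channels.
#'
#' @param light_area Light (endogenous) peak area (>= 0).
#' @param heavy_area Heavy (spiked standard) peak area (> 0).
#' @param spike_fmol Spiked standard amount in fmol (> 0).
#'
#' @return Amount in fmol (vectorised).
#' @examples
#' absolute_amount(2e5, 1e5, 10)  # 20 fmol
#' @export
absolute_amount <- function(light_area, heavy_area, spike_fmol) {
  if (any(light_area < 0)) stop("`light_area` must be >= 0")
  if (any(heavy_area <= 0))
    stop("`heavy_area` must be > 0: no standard signal, cannot quantify")
  if (any(spike_fmol <= 0)) stop("`spike_fmol` must be > 0")
  spike_fmol * light_area / heavy_area
}

#' Normalise a peptide amount to total protein
#'
#' @param amount_fmol Amount in fmol (>= 0).
#' @param total_protein_ug Total protein per sample in micrograms (> 0).
#' @return fmol per microgram of total protein (vectorised).
#' @export
normalize_amount <- function(amount_fmol, total_protein_ug) {
  if (any(amount_fmol < 0)) stop("`amount_fmol` must be >= 0")
  if (any(total_protein_ug <= 0)) stop("`total_protein_ug` must be > 0")
  amount_fmol / total_protein_ug
}

#' Mutant fraction of total calmodulin protein
#'
#' Percentage of the summed wild-type plus mutant amount contributed by the
#' mutant species: `100 * mut / (wt + mut)`. The unrounded value is
#' returned; round to one decimal for reporting.
#'
#' @param wt_amount Wild-type amount (>= 0).
#' @param mut_amount Mutant amount (>= 0).
#' @return Percentage in `[0, 100]` (vectorised).
#' @export
mutant_fraction <- function(wt_amount, mut_amount) {
  if (any(wt_amount < 0) || any(mut_amount < 0))
    stop("amounts must be >= 0")
  if (any(wt_amount + mut_amount <= 0))
    stop("wt + mut must be > 0: fraction undefined")
  100 * mut_amount / (wt_amount + mut_amount)
}

#' Median and range summaries per genotype group
#'
#' Median uses the midpoint-of-two convention for even group sizes (the
#' default of [stats::median()]), which matters at the small per-genotype
#' sample sizes typical of these cohorts.
#'
#' @param values Numeric vector of per-sample values.
#' @param genotype Grouping factor/character of the same length.
#'
#' @return Data frame with one row per genotype: `genotype`, `n`, `median`,
#'   `min`, `max`.
#' @export
summarize_by_genotype <- function(values, genotype) {
  if (length(values) != length(genotype))
    stop("`values` and `genotype` must have the same length")
  if (length(values) < 1) stop("need at least one sample")
  groups <- split(values, genotype)
  out <- data.frame(
    genotype = names(groups),
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, stats::median, numeric(1)),
    min = vapply(groups, min, numeric(1)),
    max = vapply(groups, max, numeric(1)),
    row.names = NULL)
  out
}
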