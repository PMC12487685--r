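#' Simulate allele-specific read counts at a variant position
#'
#' Draws the number of alternate-allele (mutant) reads at a single
#' heterozygous variant position as a binomial sample of the sequencing
#' depth, emulating allele-resolved counting of cDNA fragments that carry
#' the reference (A) or alternate (G) nucleotide.
#'
#' @param mutant_fraction Probability that a read carries the mutant
#'   (alternate) allele, in `[0, 1]`.
#' @param depth Total read depth at the position (non-negative integer).
#' @param seed Optional integer seed for reproducibility.
#' @param position Label for the variant position.
#'
#' @return A one-row data frame with columns `position`, `ref_count`,
#'   `alt_count` and an attribute `true_fraction`.
#' @examples
#' gen_allelic_reads(0.30, 10000, seed = 1)
#' @export
gen_allelic_reads <- function(mutant_fraction, depth, seed = NULL,
                              position = "chr12:100206105") {
  if (mutant_fraction < 0 || mutant_fraction > 1)
    stop("`mutant_fraction` must lie in [0, 1]")
  if (depth < 0) stop("`depth` must be >= 0")
  .set_seed(seed)
  alt <- stats::rbinom(1L, size = as.integer(depth), prob = mutant_fraction)
  out <- data.frame(position = position,
                    ref_count = as.integer(depth) - alt,
                    alt_count = alt)
  attr(out, "true_fraction") <- mutant_fraction
  out
}

#' Simulate gene-level fragment counts from true FPKM values
#'
#' Inverts the FPKM definition to obtain the expected fragment count per
#' gene, `fpkm * length_kb * library_size_millions`, and (optionally)
#' Poisson-samples it.
#'
#' @param true_fpkm Numeric vector of true FPKM values (>= 0).
#' @param lengths_kb Transcript lengths in kilobases (> 0), recycled.
#' @param total_mapped_millions Library size in millions of mapped
#'   fragments (> 0).
#' @param seed Optional integer seed.
#' @param noise If `TRUE` (default) counts are Poisson samples; if `FALSE`
#'   the exact expected counts are returned.
#' @param genes Gene labels.
#'
#' @return Data frame with columns `gene`, `length_kb`, `count`,
#'   `true_fpkm`, plus attribute `library_size_millions`.
#' @export
gen_fragment_counts <- function(true_fpkm, lengths_kb, total_mapped_millions,
                                seed = NULL, noise = TRUE,
                                genes = paste0("gene", seq_along(true_fpkm))) {
  if (any(true_fpkm < 0)) stop("`true_fpkm` must be >= 0")
  if (any(lengths_kb <= 0)) stop("`lengths_kb` must be > 0")
  if (total_mapped_millions <= 0)
    stop("`total_mapped_millions` must be > 0")
  lengths_kb <- rep_len(lengths_kb, length(true_fpkm))
  .set_seed(seed)
  mu <- true_fpkm * lengths_kb * total_mapped_millions
  count <- if (noise) stats::rpois(length(mu), mu) else mu
  out <- data.frame(gene = genes, length_kb = lengths_kb,
                    count = count, true_fpkm = true_fpkm)
  attr(out, "library_size_millions") <- total_mapped_millions
  out
}

#' Simulate light/heavy chromatographic peak areas for isotope-dilution
#' quantification
#'
#' Each peptide's light (endogenous) peak area is proportional to its true
#' amount and the heavy (spiked isotope-labelled standard) area to the spike
#' amount, with a shared per-sample detector gain and independent
#' multiplicative lognormal noise of unit median.
#'
#' @param true_amounts Named numeric vector of true peptide amounts (fmol,
#'   > 0); typical names are `"N98"` (wild-type) and `"S98"` (mutant).
#' @param spike_fmol Amount of heavy standard spiked per peptide (> 0).
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed Optional integer seed.
#' @param gain Detector response factor (area units per fmol), shared by
#'   light and heavy channels.
#'
#' @return Data frame with columns `peptide`, `light_area`, `heavy_area`,
#'   `spike_fmol`, `true_amount`.
#' @export
gen_srm_areas <- function(true_amounts, spike_fmol, cv = 0, seed = NULL,
                          gain = 1e4) {
  if (any(true_amounts <= 0)) stop("`true_amounts` must be > 0")
  if (spike_fmol <= 0) stop("`spike_fmol` must be > 0")
  .set_seed(seed)
  n <- length(true_amounts)
  peptide <- names(true_amounts)
  if (is.null(peptide)) peptide <- paste0("peptide", seq_len(n))
  data.frame(peptide = peptide,
             light_area = gain * true_amounts * .lognoise(n, cv),
             heavy_area = gain * spike_fmol * .lognoise(n, cv),
             spike_fmol = spike_fmol,
             true_amount = unname(true_amounts))
}

#' Simulate a cycloheximide-chase densitometry time course
#'
#' Band intensity decays exponentially with the supplied half-life
#' (expectation `100 * 2^(-t / half_life)` percent of the time-0 level);
#' the loading-control lane fluctuates around a constant. Both carry
#' multiplicative lognormal noise.
#'
#' @param half_life_h Protein half-life in hours (> 0; `Inf` for a stable
#'   protein).
#' @param times_h Chase time points in hours (must include 0).
#' @param cv Coefficient of variation of the noise.
#' @param seed Optional integer seed.
#'
#' @return Data frame with columns `time_h`, `band`, `control`,
#'   `true_percent`.
#' @export
gen_chase <- function(half_life_h, times_h = c(0, 6, 12, 24, 36), cv = 0,
                      seed = NULL) {
  if (half_life_h <= 0) stop("`half_life_h` must be > 0")
  if (!any(times_h == 0)) stop("`times_h` must include time 0")
  .set_seed(seed)
  nt <- length(times_h)
  true_percent <- 100 * 2^(-times_h / half_life_h)
  control <- .lognoise(nt, cv)
  band <- control * (true_percent / 100) * .lognoise(nt, cv)
  data.frame(time_h = times_h, band = band, control = control,
             true_percent = true_percent)
}

#' Simulate a per-beat RR/QT series with power-law rate dependence
#'
#' QT intervals follow `QT = alpha * (RR / mean(RR))^n` with multiplicative
#' lognormal noise; RR intervals are uniform over the supplied range.
#'
#' @param alpha_ms QT interval at the mean RR (ms).
#' @param exponent_n Rate-correction exponent.
#' @param rr_range_ms Length-2 range of RR intervals (ms).
#' @param n_beats Number of beats.
#' @param cv Coefficient of variation of the QT noise.
#' @param seed Optional integer seed.
#'
#' @return Data frame with columns `rr_ms`, `qt_ms`; attributes
#'   `exponent_n`, `alpha_ms`.
#' @export
gen_beats <- function(alpha_ms, exponent_n, rr_range_ms = c(90, 140),
                      n_beats = 200, cv = 0, seed = NULL) {
  if (alpha_ms <= 0) stop("`alpha_ms` must be > 0")
  if (any(rr_range_ms <= 0)) stop("`rr_range_ms` must be > 0")
  .set_seed(seed)
  rr <- stats::runif(n_beats, rr_range_ms[1], rr_range_ms[2])
  qt <- alpha_ms * (rr / mean(rr))^exponent_n * .lognoise(n_beats, cv)
  out <- data.frame(rr_ms = rr, qt_ms = qt)
  attr(out, "exponent_n") <- exponent_n
  attr(out, "alpha_ms") <- alpha_ms
  out
}

#' Simulate a whole-cell L-type current trace
#'
#' Generates an inward (negative) current elicited by a step depolarisation:
#' zero before the step, a linear rise to peak over `rise_ms`, then an
#' exponential decay. With a Ca2+ charge carrier the decay combines
#' voltage-dependent inactivation (VDI, `tau_vdi_ms`) and
#' calcium/calmodulin-dependent inactivation (CDI, `tau_cdi_ms`) as a
#' product of exponentials, i.e. a single exponential with summed rates;
#' with Ba2+ (which does not support CDI) only VDI applies. The fraction of
#' peak current remaining 50 ms after the peak therefore has the closed form
#' `exp(-50 * rate)`, stored as attribute `r50_true`.
#'
#' @param peak_pA Peak current magnitude (pA, > 0).
#' @param tau_cdi_ms CDI time constant (ms, > 0; may be `Inf`).
#' @param tau_vdi_ms VDI time constant (ms, > 0; may be `Inf`).
#' @param carrier `"Ca"` or `"Ba"`.
#' @param dt_ms Sampling interval (ms).
#' @param dur_ms Trace duration (ms).
#' @param onset_ms Step onset time (ms).
#' @param rise_ms Rise time from onset to peak (ms).
#'
#' @return Data frame with columns `time_ms`, `current_pA`; attributes
#'   `carrier`, `onset_ms`, `peak_time_ms`, `r50_true`.
#' @export
gen_current_trace <- function(peak_pA = 1000, tau_cdi_ms = 20,
                              tau_vdi_ms = 60, carrier = c("Ca", "Ba"),
                              dt_ms = 0.1, dur_ms = 400, onset_ms = 10,
                              rise_ms = 2) {
  carrier <- match.arg(carrier)
  if (peak_pA <= 0) stop("`peak_pA` must be > 0")
  if (tau_cdi_ms <= 0 || tau_vdi_ms <= 0)
    stop("time constants must be > 0 (use Inf for no inactivation)")
  rate <- 1 / tau_vdi_ms + if (carrier == "Ca") 1 / tau_cdi_ms else 0
  t <- seq(0, dur_ms, by = dt_ms)
  t_peak <- onset_ms + rise_ms
  amp <- ifelse(t < onset_ms, 0,
         ifelse(t < t_peak, (t - onset_ms) / rise_ms,
                exp(-(t - t_peak) * rate)))
  out <- data.frame(time_ms = t, current_pA = -peak_pA * amp)
  attr(out, "carrier") <- carrier
  attr(out, "onset_ms") <- onset_ms
  attr(out, "peak_time_ms") <- t_peak
  attr(out, "r50_true") <- exp(-50 * rate)
  out
}

#' Simulate an optical-mapping movie with an elliptical activation wavefront
#'
#' Activation spreads from a point origin with anisotropic conduction:
#' a pixel at offset `(dx, dy)` mm from the origin activates after
#' `sqrt((dx / cv_long)^2 + (dy / cv_trans)^2)` ms (the fast axis runs along
#' image columns). Each pixel's fluorescence trace is a stereotyped action
#' potential: a half-cosine upstroke of duration `upstroke_ms` followed by
#' an exponential repolarisation whose time constant is set so that the
#' local action-potential duration at 80\% repolarisation (APD80) equals
#' `apd80_ms` at that pixel. Activation time is defined as the time of
#' maximal upstroke slope (the upstroke midpoint), and the level-crossing
#' times of the template are available in closed form; ground-truth maps
#' are stored in the `truth` element.
#'
#' @param nrow,ncol Grid size in pixels.
#' @param cv_long_mm_per_ms Conduction speed along the fast (column) axis.
#' @param cv_trans_mm_per_ms Conduction speed across it.
#' @param origin_px Length-2 `(row, col)` pacing-site location in pixels.
#' @param apd80_ms Scalar or `nrow x ncol` matrix of true APD80 values (ms).
#' @param dt_ms Frame interval (ms).
#' @param pitch_mm Pixel pitch (mm).
#' @param dur_ms Movie duration (ms); computed from the geometry if `NULL`.
#' @param upstroke_ms Upstroke duration (ms).
#' @param t0_ms Stimulus time at the origin (ms).
#' @param noise_sd Additive Gaussian noise SD on the normalised fluorescence.
#' @param seed Optional integer seed (used only when `noise_sd > 0`).
#'
#' @return An object of class `"ap_movie"`: a list with elements `F`
#'   (`nrow x ncol x nt` array), `dt_ms`, `pitch_mm`, and `truth` (list of
#'   ground-truth maps `activation_ms`, `apd30`, `apd50`, `apd80`, plus the
#'   generating speeds).
#' @export
gen_ap_movie <- function(nrow = 41, ncol = 41,
                         cv_long_mm_per_ms = 0.6, cv_trans_mm_per_ms = 0.3,
                         origin_px = c((nrow + 1) / 2, (ncol + 1) / 2),
                         apd80_ms = 40, dt_ms = 0.2, pitch_mm = 0.1,
                         dur_ms = NULL, upstroke_ms = 1, t0_ms = 2,
                         noise_sd = 0, seed = NULL) {
  if (cv_long_mm_per_ms <= 0 || cv_trans_mm_per_ms <= 0)
    stop("conduction speeds must be > 0")
  if (pitch_mm <= 0 || dt_ms <= 0) stop("`pitch_mm` and `dt_ms` must be > 0")
  apd <- if (is.matrix(apd80_ms)) apd80_ms else
    matrix(apd80_ms, nrow, ncol)
  if (any(apd <= upstroke_ms / 2))
    stop("`apd80_ms` must exceed half the upstroke duration")
  .set_seed(seed)

  dx <- (matrix(seq_len(ncol), nrow, ncol, byrow = TRUE) - origin_px[2]) *
    pitch_mm
  dy <- (matrix(seq_len(nrow), nrow, ncol) - origin_px[1]) * pitch_mm
  delay <- sqrt((dx / cv_long_mm_per_ms)^2 + (dy / cv_trans_mm_per_ms)^2)
  t_start <- t0_ms + delay                      # upstroke foot
  act <- t_start + upstroke_ms / 2              # max-slope time
  tau <- (apd - upstroke_ms / 2) / log(5)       # APD80 = up/2 + tau*ln(5)

  if (is.null(dur_ms))
    dur_ms <- t0_ms + max(delay) + upstroke_ms + max(tau) * log(100) + 5
  t <- seq(0, dur_ms, by = dt_ms)
  nt <- length(t)

  F <- array(0, dim = c(nrow, ncol, nt))
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      ts <- t_start[r, c]
      rel <- t - ts
      f <- numeric(nt)
      up <- rel >= 0 & rel < upstroke_ms
      f[up] <- 0.5 * (1 - cos(pi * rel[up] / upstroke_ms))
      dn <- rel >= upstroke_ms
      f[dn] <- exp(-(rel[dn] - upstroke_ms) / tau[r, c])
      F[r, c, ] <- f
    }
  }
  if (noise_sd > 0)
    F <- F + array(stats::rnorm(length(F), 0, noise_sd), dim = dim(F))

  lev <- function(level) upstroke_ms / 2 + tau * log(100 / (100 - level))
  structure(list(
    F = F, dt_ms = dt_ms, pitch_mm = pitch_mm,
    truth = list(activation_ms = act,
                 apd30 = lev(30), apd50 = lev(50), apd80 = lev(80),
                 cv_long_mm_per_ms = cv_long_mm_per_ms,
                 cv_trans_mm_per_ms = cv_trans_mm_per_ms,
                 origin_px = origin_px)),
    class = "ap_movie")
}

#' Simulate a trichrome-style histology image with known fibrosis fraction
#'
#' Draws a circular tissue region on a near-black background. Tissue pixels
#' are red-dominant (muscle); a random subset of the requested fraction is
#' blue-dominant (collagen/fibrosis). The realised ground-truth masks and
#' fibrosis percentage are returned alongside the image.
#'
#' @param size Image side length in pixels.
#' @param fibrosis_fraction Target fraction of tissue pixels that are
#'   fibrotic, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param noise_sd Additive Gaussian noise SD on 0-255 channel values.
#'
#' @return List with elements `img` (`size x size x 3` array, 0-255),
#'   `tissue_mask`, `fibrotic_mask` (logical matrices) and `true_percent`
#'   (realised fibrotic percentage of tissue).
#' @export
gen_histology <- function(size = 512, fibrosis_fraction = 0.25, seed = NULL,
                          noise_sd = 8) {
  if (fibrosis_fraction < 0 || fibrosis_fraction > 1)
    stop("`fibrosis_fraction` must lie in [0, 1]")
  .set_seed(seed)
  ctr <- (size + 1) / 2
  d2 <- (row(matrix(0, size, size)) - ctr)^2 +
        (col(matrix(0, size, size)) - ctr)^2
  tissue <- d2 <= (0.45 * size)^2
  fib <- tissue & (matrix(stats::runif(size * size), size, size) <
                     fibrosis_fraction)

  img <- array(0, dim = c(size, size, 3))
  base <- list(background = c(8, 8, 8), muscle = c(190, 60, 60),
               fibrosis = c(70, 80, 200))
  for (ch in 1:3) {
    plane <- matrix(base$background[ch], size, size)
    plane[tissue] <- base$muscle[ch]
    plane[fib] <- base$fibrosis[ch]
    img[, , ch] <- plane
  }
  if (noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 255)

  list(img = img, tissue_mask = tissue, fibrotic_mask = fib,
       true_percent = 100 * sum(fib) / sum(tissue))
}
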