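#' Percent protein remaining during a cycloheximide chase
#'
#' Band intensities are first normalised to the loading control
#' (GAPDH by convention), then expressed as percentages of the normalised
#' time-0 value. The result is invariant to any common rescaling of the
#' band and control lanes.
#'
#' @param time_h Chase time points in hours (must include 0).
#' @param band Band densitometry intensities (>= 0).
#' @param control Loading-control intensities (> 0), same length.
#'
#' @return Data frame with columns `time_h`, `percent`.
#' @export
percent_remaining <- function(time_h, band, control) {
  if (length(time_h) != length(band) || length(band) != length(control))
    stop("`time_h`, `band`, `control` must have the same length")
  if (any(band < 0)) stop("`band` intensities must be >= 0")
  if (any(control <= 0)) stop("`control` intensities must be > 0")
  if (!any(time_h == 0)) stop("a time-0 measurement is required")
  normalized <- band / control
  n0 <- mean(normalized[time_h == 0])
  if (n0 <= 0) stop("time-0 normalised intensity must be > 0")
  data.frame(time_h = time_h, percent = 100 * normalized / n0)
}

#' Fit an exponential decay to a percent-remaining series
#'
#' Least-squares fit of `percent = 100 * 2^(-t / half_life)`. A series with
#' no decreasing trend is reported as stable (`rate_per_h = 0`,
#' `half_life_h = Inf`, `flat = TRUE`).
#'
#' @param time_h Time points in hours (>= 3 points).
#' @param percent Percent-remaining values.
#'
#' @return List with `rate_per_h`, `half_life_h`, `residual_norm`, `flat`.
#' @export
fit_decay <- function(time_h, percent) {
  if (length(time_h) < 3) stop("need at least 3 time points")
  if (length(time_h) != length(percent))
    stop("`time_h` and `percent` must have the same length")
  # starting value from the log-linear slope over positive observations
  pos <- percent > 0
  slope <- if (sum(pos) >= 2)
    unname(stats::coef(stats::lm(log(percent[pos]) ~ time_h[pos]))[2])
  else -log(2) / (max(time_h) / 2)
  if (!is.finite(slope) || slope >= -1e-12) {
    return(list(rate_per_h = 0, half_life_h = Inf,
                residual_norm = sqrt(sum((percent - 100)^2)), flat = TRUE))
  }
  hl0 <- -log(2) / slope
  fit <- minpack.lm::nlsLM(percent ~ 100 * 2^(-time_h / hl),
                           start = list(hl = hl0),
                           lower = c(hl = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  hl <- unname(stats::coef(fit)[["hl"]])
  list(rate_per_h = log(2) / hl, half_life_h = hl,
       residual_norm = sqrt(sum(stats::resid(fit)^2)), flat = FALSE)
}

#' Fold change of normalised intensity under proteasome inhibition
#'
#' @param treated Normalised intensity after inhibitor treatment (>= 0).
#' @param vehicle Normalised intensity in vehicle (DMSO) controls (> 0).
#' @return Fold change `treated / vehicle` (vectorised).
#' @export
inhibitor_fold_change <- function(treated, vehicle) {
  if (any(treated < 0)) stop("`treated` must be >= 0")
  if (any(vehicle <= 0)) stop("`vehicle` must be > 0")
  treated / vehicle
}
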