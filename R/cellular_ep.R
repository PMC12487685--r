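#' Fraction of peak current remaining 50 ms after the peak
#'
#' Finds the peak inward current within a search window after the step
#' onset (skipping the capacitive transient) and returns the ratio of the
#' current magnitude 50 ms later to the peak magnitude, with linear
#' interpolation between samples. The statistic is invariant to amplitude
#' scaling and to the sign convention of the trace.
#'
#' @param trace Data frame with columns `time_ms` and `current_pA`
#'   (e.g. from [gen_current_trace()]), or a two-column data frame.
#' @param onset_ms Step onset time (ms); taken from the trace's
#'   `onset_ms` attribute when present.
#' @param search_ms Length-2 window after onset, in ms, within which the
#'   peak is sought (default 2-100 ms, excluding the capacitive spike).
#'
#' @return r50 fraction in `[0, 1]`.
#' @export
r50 <- function(trace, onset_ms = attr(trace, "onset_ms"),
                search_ms = c(2, 100)) {
  t <- trace[[1]]
  i <- abs(trace[[2]])
  if (is.null(onset_ms)) onset_ms <- t[1]
  win <- which(t >= onset_ms + search_ms[1] & t <= onset_ms + search_ms[2])
  if (length(win) < 2) stop("no samples in the peak search window")
  ipk <- win[which.max(i[win])]
  t50 <- t[ipk] + 50
  if (t50 > max(t))
    stop("trace too short: need >= 50 ms of samples after the peak")
  i50 <- stats::approx(t, i, xout = t50)$y
  i50 / i[ipk]
}

#' CDI statistic f50 from paired Ca2+ and Ba2+ r50 values
#'
#' Ba2+ supports voltage-dependent inactivation only, so the excess decay
#' of the Ca2+ trace measures calcium/calmodulin-dependent inactivation:
#' `f50 = (r50_Ca - r50_Ba) / r50_Ba`, which is <= 0 when CDI is present
#' and 0 when the Ca2+ and Ba2+ decays coincide.
#'
#' @param r50_ca r50 with Ca2+ as charge carrier.
#' @param r50_ba r50 with Ba2+ as charge carrier (> 0).
#' @return f50 (dimensionless, vectorised).
#' @export
f50 <- function(r50_ca, r50_ba) {
  if (any(r50_ba <= 0)) stop("`r50_ba` must be > 0")
  (r50_ca - r50_ba) / r50_ba
}

#' Percent decrement of CDI strength relative to a reference group
#'
#' CDI strength is `|f50|`; the decrement of a group versus a reference
#' (typically mutant versus wild-type medians) is
#' `100 * (|f50_ref| - |f50_group|) / |f50_ref|`.
#'
#' @param f50_group Group median f50.
#' @param f50_ref Reference-group median f50 (non-zero).
#' @return Percent decrement (positive when CDI is weaker in the group).
#' @export
cdi_decrement <- function(f50_group, f50_ref) {
  if (any(abs(f50_ref) <= 0)) stop("reference |f50| must be > 0")
  100 * (abs(f50_ref) - abs(f50_group)) / abs(f50_ref)
}
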