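#' Signal-averaged beat from aligned waveform segments
#'
#' Superimposes beats at a fiduciary point (the QRS maximum or minimum of
#' each segment) and takes the pointwise mean over the region where all
#' beats overlap. Averaging N beats with independent noise reduces the
#' noise amplitude by about `1/sqrt(N)`.
#'
#' @param beats List of numeric waveform vectors (>= 1 beat; >= 2 for a
#'   true average), all sampled at the same rate.
#' @param fiducial `"max"` or `"min"`: align on each beat's extremum.
#' @param fs Optional sampling rate(s); if more than one distinct value is
#'   supplied the beats are not alignable and an error is raised.
#'
#' @return Averaged waveform (numeric vector) with attribute
#'   `fiducial_index` giving the alignment sample.
#' @export
signal_average <- function(beats, fiducial = c("max", "min"), fs = NULL) {
  fiducial <- match.arg(fiducial)
  if (!is.list(beats) || length(beats) < 1)
    stop("`beats` must be a non-empty list of numeric vectors")
  if (!is.null(fs) && length(unique(fs)) > 1)
    stop("mixed sampling rates: beats cannot be averaged")
  fidx <- vapply(beats, function(b)
    if (fiducial == "max") which.max(b) else which.min(b), integer(1))
  pre <- min(fidx - 1L)
  post <- min(vapply(beats, length, integer(1)) - fidx)
  aligned <- vapply(seq_along(beats), function(i)
    beats[[i]][(fidx[i] - pre):(fidx[i] + post)], numeric(pre + post + 1L))
  if (!is.matrix(aligned)) aligned <- matrix(aligned, nrow = 1L)
  out <- rowMeans(aligned)
  attr(out, "fiducial_index") <- pre + 1L
  out
}

#' Fit the QT rate-correction exponent from a beat series
#'
#' Ordinary least-squares regression of `ln(QT)` on `ln(RR / RR_reference)`;
#' the slope is the correction exponent n of the power-law QT-RR
#' relationship `QT = a * (RR / RR_ref)^n`. By default the reference RR is
#' the mean RR of the series; when pooling animals, pass the cohort mean of
#' per-animal 24-hour average RR intervals as `rr_reference`.
#'
#' @param rr_ms Per-beat RR intervals (ms, > 0).
#' @param qt_ms Per-beat QT intervals (ms, > 0).
#' @param rr_reference Optional reference RR (ms); defaults to `mean(rr_ms)`.
#'
#' @return Object of class `"qtc_model"`: list with `exponent_n`,
#'   `intercept` (ln ms), `rr_reference`, `r_squared`.
#' @export
fit_qtc_exponent <- function(rr_ms, qt_ms, rr_reference = NULL) {
  if (length(rr_ms) < 2) stop("need at least 2 beats")
  if (length(rr_ms) != length(qt_ms))
    stop("`rr_ms` and `qt_ms` must have the same length")
  if (any(rr_ms <= 0) || any(qt_ms <= 0))
    stop("intervals must be > 0")
  if (any(qt_ms >= rr_ms))
    warning("some beats have QT >= RR; check interval annotation")
  if (stats::var(rr_ms) == 0)
    stop("RR intervals show no variation; exponent is not identifiable")
  rr_ref <- if (is.null(rr_reference)) mean(rr_ms) else rr_reference
  fit <- stats::lm(log(qt_ms) ~ log(rr_ms / rr_ref))
  ss_tot <- sum((log(qt_ms) - mean(log(qt_ms)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  structure(list(exponent_n = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 rr_reference = rr_ref,
                 r_squared = r2),
            class = "qtc_model")
}

#' @export
print.qtc_model <- function(x, ...) {
  cat(sprintf(
    "QT rate-correction model: n = %.3f, RR_ref = %.1f ms, R^2 = %.3f\n",
    x$exponent_n, x$rr_reference, x$r_squared))
  invisible(x)
}

#' Rate-corrected QT interval
#'
#' Applies the fitted power-law correction `QTc = QT / (RR / RR_ref)^n`
#' (the exponent form of Mitchell's rodent QT correction). At the
#' reference RR the corrected and raw QT coincide.
#'
#' @param qt_ms QT interval(s) in ms.
#' @param rr_ms RR interval(s) in ms (> 0).
#' @param model A `"qtc_model"` from [fit_qtc_exponent()], or any list with
#'   elements `exponent_n` and `rr_reference`.
#'
#' @return Corrected QT in ms (vectorised).
#' @export
qtc <- function(qt_ms, rr_ms, model) {
  if (is.null(model$exponent_n) || is.null(model$rr_reference))
    stop("`model` must provide `exponent_n` and `rr_reference`")
  if (any(rr_ms <= 0)) stop("`rr_ms` must be > 0")
  qt_ms / (rr_ms / model$rr_reference)^model$exponent_n
}

.score_types <- c("PVC", "bigeminy", "couplet", "NSVT")

#' Ventricular arrhythmia score for an observation window
#'
#' Grades the worst ventricular arrhythmia in the window: 1 - no or
#' isolated premature ventricular complexes (PVCs); 2 - ventricular
#' bigeminy and/or frequent PVCs (> 10 per minute); 3 - ventricular
#' couplet; 4 - non-sustained ventricular tachycardia (NSVT) lasting
#' between 3 and 15 s. Sustained VT episodes (> 15 s) do not raise the
#' score beyond 4 but are flagged in the `sustained_vt` attribute.
#'
#' @param events Data frame with columns `t_start_s`, `type` (one of
#'   `"PVC"`, `"bigeminy"`, `"couplet"`, `"NSVT"`, `"BVT"`) and
#'   `duration_s` (used for tachycardia episodes). May have zero rows.
#' @param window Length-2 numeric `(start, end)` of the scoring window in
#'   seconds; events outside it are ignored with a warning.
#'
#' @return Integer score in 1..4 with attribute `sustained_vt`.
#' @export
arrhythmia_score <- function(events, window) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("`window` must be (start, end) with end > start")
  if (nrow(events) > 0) {
    inside <- events$t_start_s >= window[1] & events$t_start_s <= window[2]
    if (any(!inside))
      warning(sum(!inside), " event(s) outside the window were ignored")
    events <- events[inside, , drop = FALSE]
  }
  dur <- if ("duration_s" %in% names(events)) events$duration_s else
    rep(0, nrow(events))
  if (any(dur < 0, na.rm = TRUE)) stop("durations must be >= 0")

  minutes <- (window[2] - window[1]) / 60
  pvc_rate <- sum(events$type == "PVC") / minutes
  score <- 1L
  if (any(events$type == "bigeminy") || pvc_rate > 10) score <- 2L
  if (any(events$type == "couplet")) score <- 3L
  nsvt <- events$type %in% c("NSVT", "BVT") &
    !is.na(dur) & dur >= 3 & dur <= 15
  if (any(nsvt)) score <- 4L
  sustained <- any(events$type %in% c("NSVT", "BVT") &
                     !is.na(dur) & dur > 15)
  structure(score, sustained_vt = sustained)
}

#' Incidence of bidirectional ventricular tachycardia across animals
#'
#' Counts animals (not episodes) with at least one BVT episode longer than
#' 3 s, i.e. non-sustained (3-15 s) or sustained (> 15 s) BVT.
#'
#' @param events Data frame of annotated events with columns `animal`,
#'   `type`, `duration_s`.
#' @param animals Vector of all animals observed (animals without events
#'   count in the denominator); defaults to the animals present in
#'   `events`.
#'
#' @return List with `n_affected`, `n_animals`, `proportion`.
#' @export
bvt_incidence <- function(events, animals = unique(events$animal)) {
  if (length(animals) < 1) stop("need at least one animal")
  hit <- events$type == "BVT" & !is.na(events$duration_s) &
    events$duration_s > 3
  affected <- unique(events$animal[hit])
  affected <- affected[affected %in% animals]
  list(n_affected = length(affected),
       n_animals = length(animals),
       proportion = length(affected) / length(animals))
}
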