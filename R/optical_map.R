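#' Activation time of a single optical action-potential trace
#'
#' Activation is the time of maximal upstroke slope (dF/dt), refined to
#' sub-sample precision by a parabolic fit through the three derivative
#' samples around the maximum. A pixel is masked (`NA`) when the maximal
#' derivative does not exceed `threshold_sd` times the standard deviation
#' of the derivative over the pre-stimulus baseline samples, or when the
#' trace is flat.
#'
#' @param trace Numeric fluorescence vector, uniformly sampled.
#' @param dt_ms Sampling interval in ms.
#' @param baseline_n Number of initial samples treated as pre-stimulus
#'   baseline for the derivative-noise estimate.
#' @param threshold_sd Upstroke detection threshold in baseline-derivative
#'   standard deviations.
#'
#' @return Activation time in ms (time of sample 1 is 0), or `NA` if
#'   masked.
#' @export
activation_time <- function(trace, dt_ms, baseline_n = 5, threshold_sd = 5) {
  n <- length(trace)
  if (n < 5) return(NA_real_)
  if (diff(range(trace)) <= 0) return(NA_real_)
  d <- c(NA, (trace[3:n] - trace[1:(n - 2)]) / (2 * dt_ms), NA)
  bl <- d[2:max(3, min(baseline_n, n - 1))]
  noise <- stats::sd(bl)
  imax <- which.max(d)
  if (!is.finite(d[imax])) return(NA_real_)
  if (is.finite(noise) && noise > 0 && d[imax] <= threshold_sd * noise)
    return(NA_real_)
  if (d[imax] <= 0) return(NA_real_)
  off <- 0
  if (imax > 2 && imax < n - 1) {
    y1 <- d[imax - 1]; y2 <- d[imax]; y3 <- d[imax + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && den < 0) off <- 0.5 * (y1 - y3) / den
  }
  (imax - 1 + off) * dt_ms
}

#' Action-potential duration at a repolarisation level
#'
#' Duration from the activation time to the first interpolated crossing of
#' the given repolarisation level: APD80 is the time until the trace has
#' returned 80\% of the way from peak toward baseline, i.e. falls below
#' baseline + 20\% of the amplitude. Baseline is the mean of the
#' pre-upstroke samples; amplitude is peak minus baseline.
#'
#' @param trace Numeric fluorescence vector.
#' @param dt_ms Sampling interval in ms.
#' @param level Repolarisation level in percent (30, 50 or 80 typically).
#' @param act Optional precomputed activation time (ms); computed with
#'   [activation_time()] when `NULL`.
#' @param baseline_n Number of initial samples used for the baseline mean.
#'
#' @return APD in ms, or `NA` when no activation or no crossing is found.
#' @export
apd <- function(trace, dt_ms, level, act = NULL, baseline_n = 5) {
  if (!level > 0 || !level < 100) stop("`level` must be in (0, 100)")
  if (is.null(act)) act <- activation_time(trace, dt_ms,
                                           baseline_n = baseline_n)
  if (is.na(act)) return(NA_real_)
  n <- length(trace)
  baseline <- mean(trace[seq_len(min(baseline_n, n))])
  t <- (seq_len(n) - 1) * dt_ms
  after <- which(t >= act)
  ipk <- after[which.max(trace[after])]
  amplitude <- trace[ipk] - baseline
  if (amplitude <= 0) return(NA_real_)
  target <- baseline + amplitude * (1 - level / 100)
  for (j in seq(ipk + 1L, n)) {
    if (trace[j] <= target && trace[j - 1] > target) {
      tc <- t[j - 1] + dt_ms * (trace[j - 1] - target) /
        (trace[j - 1] - trace[j])
      return(tc - act)
    }
  }
  NA_real_
}

#' Per-pixel activation and repolarisation maps from an optical movie
#'
#' Applies [activation_time()] and [apd()] to every pixel trace of a
#' movie, producing an activation-time map, APD maps at the requested
#' repolarisation levels, and a validity mask. On valid pixels the APD
#' level ordering APD30 <= APD50 <= APD80 holds by construction.
#'
#' @param movie An `"ap_movie"` (list with `F`, `dt_ms`, `pitch_mm`), e.g.
#'   from [gen_ap_movie()].
#' @param levels Repolarisation levels in percent.
#' @param baseline_n,threshold_sd Passed to the per-trace functions.
#'
#' @return Object of class `"activation_map"`: list with `activation_ms`
#'   matrix, one `apd<level>` matrix per level, `mask` (logical matrix of
#'   valid pixels) and `pitch_mm`.
#' @export
activation_map <- function(movie, levels = c(30, 50, 80), baseline_n = 5,
                           threshold_sd = 5) {
  F <- movie$F
  dt <- movie$dt_ms
  nr <- dim(F)[1]; nc <- dim(F)[2]
  act <- matrix(NA_real_, nr, nc)
  apds <- lapply(levels, function(l) matrix(NA_real_, nr, nc))
  names(apds) <- paste0("apd", levels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      tr <- F[r, c, ]
      a <- activation_time(tr, dt, baseline_n = baseline_n,
                           threshold_sd = threshold_sd)
      act[r, c] <- a
      if (!is.na(a))
        for (k in seq_along(levels))
          apds[[k]][r, c] <- apd(tr, dt, levels[k], act = a,
                                 baseline_n = baseline_n)
    }
  }
  structure(c(list(activation_ms = act), apds,
              list(mask = !is.na(act), pitch_mm = movie$pitch_mm)),
            class = "activation_map")
}

#' Anisotropic conduction velocities from an activation-time map
#'
#' Fits a local plane to the activation time in a sliding window; the
#' plane's gradient gives a per-pixel conduction-velocity vector with
#' speed `1 / |grad t|` and direction along the gradient. Speeds are
#' binned by propagation direction (modulo 180 degrees) and summarised by
#' bin medians; the maximal and minimal bin medians are reported as CV_max
#' and CV_min, with the fast-axis angle taken from the fastest bin.
#' Pixels with a near-zero gradient are excluded as degenerate.
#'
#' @param act Activation-time matrix in ms (or an `"activation_map"`,
#'   whose `activation_ms` element is used).
#' @param pitch_mm Pixel pitch in mm (taken from the map when available).
#' @param window Odd window size for the local plane fit (default 5).
#' @param bin_deg Width of the direction bins in degrees.
#' @param min_bin_n Minimum number of velocity vectors for a bin to count.
#'
#' @return List with `cv_max`, `cv_min` (mm/ms), `axis_angle_deg` (fast
#'   axis, degrees from the column axis, in `[0, 180)`), `n_vectors`.
#' @export
conduction_velocity <- function(act, pitch_mm = NULL, window = 5,
                                bin_deg = 10, min_bin_n = 5) {
  if (inherits(act, "activation_map")) {
    if (is.null(pitch_mm)) pitch_mm <- act$pitch_mm
    act <- act$activation_ms
  }
  if (is.null(pitch_mm) || pitch_mm <= 0) stop("`pitch_mm` must be > 0")
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  nr <- nrow(act); nc <- ncol(act)
  half <- window %/% 2
  if (nr < window || nc < window || sum(!is.na(act)) < 25)
    stop("need at least a 5x5 block of valid pixels")

  # symmetric window => plane-fit slopes reduce to normalised correlations
  offs <- seq(-half, half) * pitch_mm
  dx <- matrix(offs, window, window, byrow = TRUE)  # along columns
  dy <- matrix(offs, window, window)                # along rows
  sxx <- sum(dx^2)

  speed <- numeric(0)
  angle <- numeric(0)
  for (r in seq(half + 1, nr - half)) {
    for (c in seq(half + 1, nc - half)) {
      tw <- act[(r - half):(r + half), (c - half):(c + half)]
      if (any(is.na(tw))) next
      gx <- sum(tw * dx) / sxx    # ms/mm along columns
      gy <- sum(tw * dy) / sxx
      g <- sqrt(gx^2 + gy^2)
      if (g < 1e-9) next          # degenerate (flat) gradient
      speed <- c(speed, 1 / g)
      angle <- c(angle, atan2(gy, gx) * 180 / pi)
    }
  }
  if (length(speed) == 0) stop("no usable velocity vectors")
  angle <- angle %% 180
  bin <- floor(angle / bin_deg)
  med <- tapply(speed, bin, stats::median)
  cnt <- tapply(speed, bin, length)
  keep <- cnt >= min(min_bin_n, max(cnt))
  med <- med[keep]
  fast <- names(med)[which.max(med)]
  list(cv_max = unname(max(med)), cv_min = unname(min(med)),
       axis_angle_deg = (as.numeric(fast) + 0.5) * bin_deg,
       n_vectors = length(speed))
}

#' Isochron (equal-time band) raster from a time map
#'
#' Bins a per-pixel time map into consecutive intervals, producing the
#' integer band labels used to render activation or repolarisation
#' isochron maps. The number of occupied bands is at most
#' `ceiling(range / interval)`.
#'
#' @param time_map Matrix of times in ms (`NA` allowed).
#' @param interval_ms Band width in ms (> 0).
#' @return Integer matrix of band labels (1-based; `NA` preserved).
#' @export
isochron_map <- function(time_map, interval_ms) {
  if (interval_ms <= 0) stop("`interval_ms` must be > 0")
  tmin <- min(time_map, na.rm = TRUE)
  lab <- ceiling((time_map - tmin) / interval_ms)
  lab[!is.na(lab) & lab < 1] <- 1
  mode(lab) <- "integer"
  lab
}
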