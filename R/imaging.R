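# Otsu threshold on values scaled to [0, 1]
.otsu <- function(x) {
  EBImage::otsu(EBImage::Image(x), range = c(0, 1))
}

# scale an image array to [0, 1] assuming 8- or 16-bit integer ranges
.scale01 <- function(img) {
  m <- max(img)
  if (m <= 1) img else if (m <= 255) img / 255 else img / 65535
}

#' Fibrosis fraction by channel-difference thresholding
#'
#' Quantifies the fibrotic percentage of myocardial tissue in a
#' trichrome-stained section: fibrotic pixels are extracted by thresholding
#' the difference image of the blue and red channels (blue-stained collagen
#' gives a positive difference), total tissue by thresholding the grayscale
#' image (channel mean), and the result is
#' `100 * |fibrotic AND tissue| / |tissue|`. Thresholds are chosen by
#' Otsu's method unless fixed values are supplied, making the measurement
#' invariant to uniform brightness scaling.
#'
#' @param img `H x W x 3` numeric array (0-1, 0-255 or 0-65535 range).
#' @param direction `"B-R"` (default, trichrome blue collagen) or `"R-B"`
#'   for stains where fibrosis is red-dominant.
#' @param fibrosis_threshold,tissue_threshold Optional fixed thresholds on
#'   the `[0, 1]` scale, replacing Otsu.
#'
#' @return Percent fibrosis (numeric) with attribute `masks`, a list with
#'   logical `fibrotic` and `tissue` matrices.
#' @export
fibrosis_fraction <- function(img, direction = c("B-R", "R-B"),
                              fibrosis_threshold = NULL,
                              tissue_threshold = NULL) {
  direction <- match.arg(direction)
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("`img` must be an H x W x 3 array")
  img <- .scale01(img)
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  thr_t <- if (is.null(tissue_threshold)) .otsu(gray) else tissue_threshold
  tissue <- gray > thr_t
  if (sum(tissue) == 0) stop("empty tissue mask: nothing to quantify")

  d <- if (direction == "B-R") img[, , 3] - img[, , 1] else
    img[, , 1] - img[, , 3]
  d <- pmax(d, 0)
  fibrotic <- if (max(d) <= 1e-6) {
    matrix(FALSE, nrow(d), ncol(d))
  } else {
    thr_f <- if (is.null(fibrosis_threshold)) .otsu(d) else fibrosis_threshold
    d > thr_f
  }
  structure(100 * sum(fibrotic & tissue) / sum(tissue),
            masks = list(fibrotic = fibrotic, tissue = tissue))
}

# bilinear interpolation; x along columns, y along rows (1-based, clamped)
.bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Averaged intensity profile along a line across striations
#'
#' Samples the image along a line drawn perpendicular to the fluorescence
#' bands and averages, at each position, over a band of total height
#' `2 * band_half` pixels (50 pixels by default) perpendicular to the
#' line, producing a 1-D intensity profile suitable for striation-spacing
#' analysis.
#'
#' @param img Grayscale matrix, or `H x W x 3` array (channel mean used).
#' @param from,to Length-2 `(x, y)` endpoints in pixel coordinates
#'   (x = column, y = row).
#' @param band_half Half-height of the averaging band in pixels.
#'
#' @return Data frame with columns `position_px` (distance from `from`)
#'   and `intensity`.
#' @export
striation_profile <- function(img, from, to, band_half = 25) {
  if (length(dim(img)) == 3)
    img <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  len <- sqrt(sum((to - from)^2))
  if (len < 1) stop("line must span at least one pixel")
  u <- (to - from) / len
  v <- c(-u[2], u[1])
  s <- seq(0, floor(len))
  offs <- seq(-band_half + 0.5, band_half - 0.5, by = 1)
  intensity <- vapply(s, function(si) {
    px <- from[1] + si * u[1] + offs * v[1]
    py <- from[2] + si * u[2] + offs * v[2]
    mean(.bilinear(img, px, py))
  }, numeric(1))
  data.frame(position_px = s, intensity = intensity)
}

# indices of local maxima with at least the requested prominence
.find_peaks <- function(v, prominence) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] &
                  v[2:(n - 1)] >= v[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    h <- v[i]
    left <- if (i > 1) {
      j <- max(c(0, which(v[1:(i - 1)] > h)))
      min(v[(j + 1):(i - 1)])
    } else h
    right <- if (i < n) {
      up <- which(v[(i + 1):n] > h)
      j <- if (length(up)) i + min(up) else n + 1L
      min(v[(i + 1):(j - 1)])
    } else h
    (h - max(left, right)) >= prominence
  }, logical(1))
  cand[keep]
}

#' Mean striation spacing from an intensity profile
#'
#' Detects intensity peaks with a prominence of at least
#' `prominence_frac` of the profile's dynamic range and returns the mean
#' distance between successive peaks, converted to micrometres when a
#' pixel scale is supplied.
#'
#' @param profile Data frame from [striation_profile()] (columns
#'   `position_px`, `intensity`).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   profile dynamic range.
#' @param scale_um_per_px Optional pixel size in micrometres.
#'
#' @return Mean peak-to-peak spacing (pixels, or micrometres when scaled),
#'   with attribute `peak_positions`.
#' @export
striation_spacing <- function(profile, prominence_frac = 0.1,
                              scale_um_per_px = NULL) {
  v <- profile$intensity
  rng <- diff(range(v))
  if (rng <= 0) stop("flat profile: no striations detectable")
  pk <- .find_peaks(v, prominence = prominence_frac * rng)
  if (length(pk) < 2)
    stop("need at least 2 detected peaks to measure spacing")
  pos <- profile$position_px[pk]
  spacing <- mean(diff(pos))
  if (!is.null(scale_um_per_px)) {
    spacing <- spacing * scale_um_per_px
    pos <- pos * scale_um_per_px
  }
  structure(spacing, peak_positions = pos)
}
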