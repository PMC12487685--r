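make_beat <- function(n = 100, peak_at = 30) {
  b <- numeric(n)
  b[peak_at] <- 1
  b + 0.1 * sin(seq_len(n) / 5)
}

test_that("signal averaging aligns at the fiducial and averages overlap", {
  b <- make_beat()
  avg <- signal_average(list(b, b, b))
  expect_equal(as.numeric(avg), b, ignore_attr = TRUE)
  expect_equal(attr(avg, "fiducial_index"), 30)

  one <- signal_average(list(b))
  expect_equal(as.numeric(one), b)

  # a time-shifted copy still aligns on the QRS extremum: the average
  # over the overlap region equals the common beat shape
  shifted <- list(b, c(numeric(7), b)[1:100])  # peak moves to sample 37
  avg2 <- signal_average(shifted)
  expect_length(avg2, 93)                      # pre = 29, post = 63
  expect_lt(max(abs(avg2 - b[1:93])), 1e-12)

  expect_error(signal_average(list(b, b), fs = c(1000, 2000)), "sampling")
})

test_that("signal averaging attenuates independent noise like 1/sqrt(N)", {
  set.seed(51)
  b <- make_beat()
  n_rep <- 64
  noisy <- lapply(seq_len(n_rep), function(i) b + rnorm(100, 0, 0.02))
  # fiducial jitter is absent because the peak dominates the noise
  avg <- signal_average(noisy)
  expect_length(avg, 100)  # identical peaks => full overlap
  resid_one <- sd(noisy[[1]] - b)
  resid_avg <- sd(avg - b)
  expect_lt(resid_avg, resid_one / sqrt(n_rep) * 2)
})

test_that("the rate-correction exponent is recovered from noiseless data", {
  set.seed(52)
  rr <- runif(100, 90, 140)
  qt <- 40 * (rr / mean(rr))^0.5
  m <- fit_qtc_exponent(rr, qt)
  expect_equal(m$exponent_n, 0.5, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)

  m0 <- fit_qtc_exponent(rr, rep(40, 100))
  expect_equal(m0$exponent_n, 0, tolerance = 1e-12)
  expect_error(fit_qtc_exponent(rep(100, 10), rep(40, 10)), "variation")
})

test_that("exponent fitting is scale-invariant in QT units", {
  b <- gen_beats(40, 0.575, n_beats = 150, cv = 0.02, seed = 53)
  m1 <- fit_qtc_exponent(b$rr_ms, b$qt_ms)
  # rescaled QT exceeds RR on some beats, which is warned about but valid
  m2 <- suppressWarnings(fit_qtc_exponent(b$rr_ms, b$qt_ms * 2.5))
  expect_equal(m1$exponent_n, m2$exponent_n)
  expect_equal(m2$intercept - m1$intercept, log(2.5))
})

test_that("QTc correction removes the rate dependence", {
  set.seed(54)
  rr <- runif(200, 90, 140)
  qt <- 40 * (rr / mean(rr))^0.575
  m <- fit_qtc_exponent(rr, qt)
  corrected <- qtc(qt, rr, m)
  expect_lt(max(corrected) / min(corrected) - 1, 1e-9)
  # identity at the reference rate and with a zero exponent
  expect_equal(qtc(42, m$rr_reference, m), 42)
  m0 <- list(exponent_n = 0, rr_reference = 120)
  expect_equal(qtc(qt, rr, m0), qt)
})

test_that("arrhythmia scoring applies the worst-event rubric", {
  win <- c(0, 3600)
  empty <- data.frame(t_start_s = numeric(0), type = character(0),
                      duration_s = numeric(0))
  expect_equal(as.integer(arrhythmia_score(empty, win)), 1L)

  pvc11 <- data.frame(t_start_s = seq(0, 59, length.out = 11) + 1,
                      type = "PVC", duration_s = 0)
  expect_equal(as.integer(arrhythmia_score(pvc11, c(0, 60))), 2L)

  mixed <- data.frame(t_start_s = c(10, 20), type = c("bigeminy", "couplet"),
                      duration_s = c(0, 0))
  expect_equal(as.integer(arrhythmia_score(mixed, win)), 3L)

  nsvt <- data.frame(t_start_s = 100, type = "NSVT", duration_s = 5)
  expect_equal(as.integer(arrhythmia_score(nsvt, win)), 4L)
  # a 2-second run does not qualify as NSVT
  short <- data.frame(t_start_s = 100, type = "NSVT", duration_s = 2)
  expect_equal(as.integer(arrhythmia_score(short, win)), 1L)
  # sustained VT flagged but score capped at 4
  sus <- data.frame(t_start_s = c(100, 200), type = c("NSVT", "BVT"),
                    duration_s = c(5, 20))
  sc <- arrhythmia_score(sus, win)
  expect_equal(as.integer(sc), 4L)
  expect_true(attr(sc, "sustained_vt"))

  outside <- data.frame(t_start_s = 4000, type = "couplet", duration_s = 0)
  expect_warning(sc2 <- arrhythmia_score(outside, win), "ignored")
  expect_equal(as.integer(sc2), 1L)
})

test_that("adding events never lowers the arrhythmia score", {
  set.seed(55)
  win <- c(0, 3600)
  types <- c("PVC", "bigeminy", "couplet", "NSVT")
  for (k in 1:25) {
    n <- sample(0:8, 1)
    ev <- data.frame(t_start_s = runif(n, 0, 3600),
                     type = sample(types, n, replace = TRUE),
                     duration_s = runif(n, 0, 20))
    extra <- data.frame(t_start_s = runif(1, 0, 3600),
                        type = sample(types, 1),
                        duration_s = runif(1, 0, 20))
    s1 <- as.integer(arrhythmia_score(ev, win))
    s2 <- as.integer(arrhythmia_score(rbind(ev, extra), win))
    expect_gte(s2, s1)
  }
})

test_that("BVT incidence counts animals, not episodes", {
  no_bvt <- data.frame(animal = c("a1", "a2"), type = "PVC", duration_s = 0)
  expect_equal(bvt_incidence(no_bvt, animals = paste0("a", 1:6))$proportion, 0)

  ev <- data.frame(
    animal = c("m1", "m1", "m2", "m3", "m4", "m5", "m6"),
    type = c("BVT", "BVT", "BVT", "BVT", "BVT", "BVT", "PVC"),
    duration_s = c(5, 8, 12, 4, 20, 2, 0))
  # m1..m4 have BVT > 3 s (m1 twice, counted once); m5's 2 s run does not
  inc <- bvt_incidence(ev, animals = paste0("m", 1:9))
  expect_equal(inc$n_affected, 4)
  expect_equal(inc$n_animals, 9)

  ev5 <- data.frame(animal = paste0("h", 1:5), type = "BVT", duration_s = 10)
  expect_equal(bvt_incidence(ev5, animals = paste0("h", 1:9))$proportion, 5 / 9)
})
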