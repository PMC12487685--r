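# analytic AP template matching the generator: half-cosine upstroke then
# exponential repolarisation
ap_template <- function(t, t_start, up = 1, tau = 20) {
  f <- numeric(length(t))
  rise <- t >= t_start & t < t_start + up
  f[rise] <- 0.5 * (1 - cos(pi * (t[rise] - t_start) / up))
  dec <- t >= t_start + up
  f[dec] <- exp(-(t[dec] - t_start - up) / tau)
  f
}

test_that("activation time finds the upstroke midpoint", {
  dt <- 0.2
  t <- seq(0, 60, by = dt)
  tr <- ap_template(t, t_start = 10)
  a <- activation_time(tr, dt)
  expect_lt(abs(a - 10.5), dt / 2)

  # time-shift equivariance
  tr2 <- ap_template(t, t_start = 17.3)
  expect_equal(activation_time(tr2, dt) - a, 7.3, tolerance = dt / 2)

  expect_true(is.na(activation_time(rep(0.4, 200), dt)))
})

test_that("APD reproduces square-pulse and exponential closed forms", {
  dt <- 0.5
  t <- seq(0, 200, by = dt)
  square <- as.numeric(t >= 20 & t < 120)  # 100 ms square pulse
  a80 <- apd(square, dt, 80)
  expect_equal(a80, 100, tolerance = dt)

  tau <- 20
  tr <- ap_template(t, t_start = 20, tau = tau)
  # closed form: APD_L = up/2 + tau * log(100 / (100 - L))
  for (lev in c(30, 50, 80)) {
    expect_equal(apd(tr, dt, lev), 0.5 + tau * log(100 / (100 - lev)),
                 tolerance = 0.3)
  }
  # APD50 - APD30 = tau * (ln(2) - ln(10/7))
  expect_equal(apd(tr, dt, 50) - apd(tr, dt, 30),
               tau * (log(2) - log(10 / 7)), tolerance = 0.3)
})

test_that("APD level ordering holds on every valid movie pixel", {
  m <- gen_ap_movie(nrow = 13, ncol = 13, apd80_ms = 30, noise_sd = 0.01,
                    seed = 61)
  am <- activation_map(m)
  ok <- am$mask & !is.na(am$apd30) & !is.na(am$apd50) & !is.na(am$apd80)
  expect_gt(sum(ok), 100)
  expect_true(all(am$apd30[ok] <= am$apd50[ok]))
  expect_true(all(am$apd50[ok] <= am$apd80[ok]))
  # repolarisation time is never before activation
  expect_true(all(am$apd30[ok] > 0))
})

test_that("plane waves give equal CV in all reported bins", {
  pitch <- 0.1
  act <- matrix(rep((0:20) * pitch / 0.5, each = 21), 21, 21, byrow = TRUE)
  cv <- conduction_velocity(act, pitch_mm = pitch)
  expect_equal(cv$cv_max, 0.5, tolerance = 1e-9)
  expect_equal(cv$cv_min, 0.5, tolerance = 1e-9)
})

test_that("elliptical wavefront speeds are recovered and rotation swaps axes", {
  m <- gen_ap_movie()  # 0.6 / 0.3 mm/ms, fast axis along columns
  am <- activation_map(m)
  cv <- conduction_velocity(am)
  expect_lt(abs(cv$cv_max - 0.6) / 0.6, 0.1)
  expect_lt(abs(cv$cv_min - 0.3) / 0.3, 0.1)
  expect_lt(min(cv$axis_angle_deg %% 180, 180 - cv$axis_angle_deg %% 180), 15)

  # rotating the activation map 90 degrees leaves the speeds unchanged
  rot <- t(am$activation_ms)[, nrow(am$activation_ms):1]
  cv_rot <- conduction_velocity(rot, pitch_mm = m$pitch_mm)
  expect_equal(cv_rot$cv_max, cv$cv_max, tolerance = 0.02)
  expect_equal(cv_rot$cv_min, cv$cv_min, tolerance = 0.02)
  ang <- abs(cv_rot$axis_angle_deg - cv$axis_angle_deg) %% 180
  expect_lt(min(abs(ang - 90), abs(180 - ang - 90)), 20)
})

test_that("CV is invariant to fluorescence rescaling and baseline offset", {
  m <- gen_ap_movie(nrow = 21, ncol = 21, cv_long_mm_per_ms = 0.5,
                    cv_trans_mm_per_ms = 0.25)
  m2 <- m
  m2$F <- m$F * 3.1 + 0.7
  cv1 <- conduction_velocity(activation_map(m))
  cv2 <- conduction_velocity(activation_map(m2))
  expect_equal(cv1$cv_max, cv2$cv_max)
  expect_equal(cv1$cv_min, cv2$cv_min)
})

test_that("isochron maps bin times deterministically", {
  # plane wave: parallel straight bands, constant along the wavefront
  act <- matrix(rep(seq(0, 20, length.out = 21), each = 15), 15, 21,
                byrow = FALSE)
  act <- matrix(rep(seq(0, 20, length.out = 21), each = 15), 15, 21)
  iso <- isochron_map(act, 5)
  expect_true(all(apply(iso, 2, function(col) length(unique(col)) == 1)))
  expect_lte(length(unique(as.vector(iso))), ceiling(20 / 5) + 1)

  # point source: concentric bands (label depends only on radius)
  d <- sqrt((row(matrix(0, 31, 31)) - 16)^2 + (col(matrix(0, 31, 31)) - 16)^2)
  iso2 <- isochron_map(d, 3)
  expect_equal(length(unique(as.vector(iso2))),
               length(unique(pmax(1, ceiling((d - min(d)) / 3)))))
  expect_error(isochron_map(d, 0), "interval")
})
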