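test_that("FPKM matches direct arithmetic and rejects bad inputs", {
  expect_equal(compute_fpkm(100, 2, 10), 5)
  expect_equal(compute_fpkm(0, 2, 10), 0)
  expect_error(compute_fpkm(10, 0, 10), "length_kb")
  expect_error(compute_fpkm(10, 2, 0), "library")
  expect_error(compute_fpkm(-1, 2, 10), "fragment_count")
})

test_that("vectorised FPKM agrees with a scalar loop oracle", {
  set.seed(21)
  n <- 200
  counts <- rpois(n, 500)
  len <- runif(n, 0.5, 10)
  lib <- 37.5
  oracle <- numeric(n)
  for (i in seq_len(n)) oracle[i] <- counts[i] / (len[i] * lib)
  expect_lt(max(abs(compute_fpkm(counts, len, lib) - oracle)), 1e-12)
})

test_that("allele fractions sum to one and invert fold ratios", {
  eq <- allele_fractions(50, 50)
  expect_equal(eq$ref_fraction, 0.5)
  expect_equal(eq$alt_fraction, 0.5)
  expect_equal(eq$ref_over_alt_fold, 1)

  x <- allele_fractions(702, 300)
  expect_equal(x$ref_fraction + x$alt_fraction, 1)
  expect_equal(x$ref_over_alt_fold, 2.34)
  expect_equal(allele_fraction_from_fold(x$ref_over_alt_fold),
               x$alt_fraction)

  only_alt <- allele_fractions(0, 10)
  expect_equal(only_alt$alt_fraction, 1)
  expect_warning(allele_fractions(10, 0), "undefined")
  expect_error(allele_fractions(0, 0), "total")
})

test_that("mutant transcript share behaves and is monotone", {
  expect_equal(as.numeric(mutant_transcript_share(0, c(30, 50, 40))), 0)
  expect_error(mutant_transcript_share(0.3, c(0, 0, 0)), "zero")

  # monotone in the allele fraction and in the mutated gene's FPKM
  fr <- seq(0, 1, by = 0.1)
  sh <- vapply(fr, function(a)
    attr(mutant_transcript_share(a, c(34.8, 49, 41.4)), "raw_percent"),
    numeric(1))
  expect_true(all(diff(sh) > 0))
  f1 <- seq(10, 60, by = 5)
  sh2 <- vapply(f1, function(f)
    attr(mutant_transcript_share(0.3, c(f, 49, 41.4)), "raw_percent"),
    numeric(1))
  expect_true(all(diff(sh2) > 0))
})

test_that("gene shares total 100 percent", {
  set.seed(5)
  for (k in 1:20) {
    fpkm <- runif(3, 5, 80)
    sh <- gene_share_percent(fpkm)
    expect_equal(sum(attr(sh, "raw_percent")), 100)
    # each one-decimal rounding contributes at most 0.05 to the sum error
    expect_lte(abs(sum(sh) - 100), 0.05 * length(fpkm) + 1e-12)
  }
})

test_that("ddCt estimation inverts a known fold change", {
  mk_ct <- function(fold, reps = 3) {
    # calibrator dCt = 4; target dCt = 4 - log2(fold)
    rbind(
      data.frame(gene = "Calm1", tissue = "LV", replicate = seq_len(reps),
                 ct = 22, ref_ct = 18),
      data.frame(gene = "Calm1", tissue = "atria", replicate = seq_len(reps),
                 ct = 18 + 4 - log2(fold), ref_ct = 18))
  }
  ct <- mk_ct(3.4)
  est <- ddct_estimate(ct, "Calm1", "atria", "LV", calibrator_fpkm = 34.8)
  expect_equal(est$fold_change, 3.4)
  expect_equal(est$estimate, 3.4 * 34.8)
  expect_equal(est$sem, 0)

  # calibrator identity and the one-cycle halving
  ident <- ddct_estimate(mk_ct(1), "Calm1", "atria", "LV", 34.8)
  expect_equal(ident$fold_change, 1)
  expect_equal(ident$estimate, 34.8)
  half <- ddct_estimate(mk_ct(0.5), "Calm1", "atria", "LV", 34.8)
  expect_equal(half$ddct, 1)
  expect_equal(half$fold_change, 0.5)
})

test_that("swapping target and calibrator gives the reciprocal fold", {
  set.seed(9)
  ct <- rbind(
    data.frame(gene = "Calm2", tissue = "LV", replicate = 1:4,
               ct = rnorm(4, 21, 0.3), ref_ct = rnorm(4, 18, 0.2)),
    data.frame(gene = "Calm2", tissue = "RV", replicate = 1:4,
               ct = rnorm(4, 22, 0.3), ref_ct = rnorm(4, 18, 0.2)))
  fwd <- ddct_estimate(ct, "Calm2", "RV", "LV", 1)
  rev <- ddct_estimate(ct, "Calm2", "LV", "RV", 1)
  expect_lt(abs(fwd$fold_change * rev$fold_change - 1), 1e-9)
})

test_that("ddCt margins bracket the estimate", {
  set.seed(13)
  ct <- rbind(
    data.frame(gene = "Calm3", tissue = "LV", replicate = 1:5,
               ct = rnorm(5, 21, 0.4), ref_ct = 18),
    data.frame(gene = "Calm3", tissue = "atria", replicate = 1:5,
               ct = rnorm(5, 22, 0.4), ref_ct = 18))
  est <- ddct_estimate(ct, "Calm3", "atria", "LV", 40)
  expect_true(est$margin_low <= est$estimate)
  expect_true(est$estimate <= est$margin_high)
  bad <- ct; bad$ref_ct[1] <- NA
  expect_error(ddct_estimate(bad, "Calm3", "atria", "LV", 40), "reference")
})
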