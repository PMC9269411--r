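test_that("thresholded integral is zero on flat traces and exact on
           rectangles", {
  tm <- seq(-100, 250)
  flat <- response_waveform(tm, rep(1.3, length(tm)))
  expect_equal(as.numeric(ztest_threshold_integral(flat)), 0)
  # rectangle sitting 2 mV above the baseline bound for 100 ms
  set.seed(1)
  base <- rnorm(length(tm), sd = 0.1)
  y <- base
  bound <- mean(base[tm <= 0]) + qnorm(0.95) * sd(base[tm <= 0])
  y[tm >= 50 & tm < 150] <- bound + 2
  w <- response_waveform(tm, y)
  got <- as.numeric(ztest_threshold_integral(w))
  expect_equal(got, 200, tolerance = 0.05 * 200)
  # translation equivariance: shifting the whole trace leaves it unchanged
  w2 <- response_waveform(tm, y + 11)
  expect_equal(as.numeric(ztest_threshold_integral(w2)), got,
               tolerance = 1e-9)
  expect_error(ztest_threshold_integral(w, window = c(0, 900)), "outside")
})

test_that("permutation envelope matches the exhaustive enumeration for
           3 vs 3 trials", {
  set.seed(21)
  A <- matrix(rnorm(3 * 40), 3)
  B <- matrix(rnorm(3 * 40), 3)
  env <- permutation_envelope(A, B, 1:40, n_perm = 50, alpha = 0.1,
                              exhaustive = TRUE)
  expect_equal(env$n_perm, choose(6, 3))
  cmb <- utils::combn(6, 3)
  X <- rbind(A, B)
  S <- sapply(seq_len(ncol(cmb)), function(i) {
    colMeans(X[cmb[, i], , drop = FALSE]) -
      colMeans(X[-cmb[, i], , drop = FALSE])
  })
  expect_equal(env$upper,
               apply(S, 1, quantile, 0.9, names = FALSE), tolerance = 1e-12)
  expect_equal(env$lower,
               apply(S, 1, quantile, 0.1, names = FALSE), tolerance = 1e-12)
  expect_equal(env$observed, colMeans(A) - colMeans(B))
})

test_that("permutation envelope enforces its preconditions and flags strong
           effects", {
  A <- matrix(rnorm(10 * 200), 10)
  B <- matrix(rnorm(10 * 200), 10)
  expect_error(permutation_envelope(A, B, 1:200, n_perm = 10, alpha = 0.05),
               "n_perm")
  expect_error(permutation_envelope(A[1, , drop = FALSE], B, 1:200), ">= 2")
  # +5 sigma offset over 50 ms: a contiguous significant region appears
  A2 <- A
  A2[, 100:149] <- A2[, 100:149] + 5
  env <- permutation_envelope(A2, B, 1:200, n_perm = 500, alpha = 0.05,
                              min_consecutive_ms = 7, seed = 3)
  runs <- rle(env$mask)
  expect_gte(max(runs$lengths[runs$values]), 50 - 7)
  expect_true(all(which(env$mask) >= 95 & which(env$mask) <= 155))
})

test_that("responsiveness screening accepts driven cells and rejects
           noise", {
  set.seed(5)
  tm <- seq(-50, 200)
  blank <- matrix(rnorm(15 * length(tm)), 15)
  driven <- matrix(rnorm(15 * length(tm)), 15)
  driven[, tm >= 20 & tm <= 100] <- driven[, tm >= 20 & tm <= 100] + 3
  expect_true(screen_responsive(driven, blank, tm, n_perm = 999, seed = 2))
  quiet <- matrix(rnorm(15 * length(tm)), 15)
  expect_false(screen_responsive(quiet, blank, tm, n_perm = 999, seed = 2))
})

test_that("onset latency interpolates half-height and three-sigma
           crossings", {
  # linear ramp 0 -> 1 mV over 0-10 ms: half-height at 5 ms
  tm <- 0:20
  ramp <- response_waveform(tm, pmin(tm / 10, 1))
  expect_equal(onset_latency(ramp, "half_height", reference = 1), 5)
  # three-sigma rule: blank mean 0, sd 1, trace reaches 3 at t = 12
  y <- c(rep(0, 12), seq(3, 9, length.out = 9))
  w <- response_waveform(tm, y)
  expect_equal(onset_latency(w, "three_sigma",
                             blank_stats = list(mean = 0, sd = 1)), 12,
               tolerance = 1)
  # no crossing -> NA sentinel
  expect_true(is.na(onset_latency(response_waveform(tm, rep(0, 21)),
                                  "three_sigma",
                                  blank_stats = list(mean = 0, sd = 1))))
  expect_error(onset_latency(response_waveform(tm, rep(-1, 21)),
                             "half_height", reference = -2), "positive")
})

test_that("contextual modulation is null on identical conditions and
           antisymmetric in latency", {
  set.seed(9)
  tm <- seq(-50, 250)
  shape <- 4 * psp_kernel(tm - 40)
  mk <- function(shift = 0) {
    t(replicate(12, 4 * psp_kernel(tm - 40 - shift) +
                    rnorm(length(tm), sd = 0.05)))
  }
  a <- mk(); b <- mk()
  m <- contextual_modulation(a, b, tm, n_perm = 499, seed = 4)
  expect_equal(m$delta_latency_ms, 0, tolerance = 1.5)
  expect_equal(m$delta_integral_ratio, 1, tolerance = 0.05)
  expect_false(m$significant_integral)
  # a shifted copy: advance appears with the right sign and flips
  adv <- mk(-8)   # earlier by 8 ms
  m2 <- contextual_modulation(adv, b, tm, n_perm = 499, seed = 4)
  expect_equal(m2$delta_latency_ms, 8, tolerance = 1.5)
  m3 <- contextual_modulation(b, adv, tm, n_perm = 499, seed = 4)
  expect_equal(m3$delta_latency_ms, -m2$delta_latency_ms, tolerance = 1.5)
})

test_that("peak ratios reproduce the worked-example arithmetic", {
  expect_equal(peak_ratio_pct(4.4, 7.4), 100 * 4.4 / 7.4)
  tm <- 0:100
  a <- response_waveform(tm, 2 * psp_kernel(tm - 10))
  b <- response_waveform(tm, 8 * psp_kernel(tm - 10))
  expect_equal(peak_ratio_pct(a, b), 25, tolerance = 1e-6)
})

test_that("scalar permutation test is calibrated at the 5% level", {
  set.seed(31)
  rej <- 0
  runs <- 200
  for (r in seq_len(runs)) {
    p <- permutation_scalar_test(rnorm(8), rnorm(8), n_perm = 399,
                                 alternative = "two.sided",
                                 seed = r)$p_value
    rej <- rej + (p < 0.05)
  }
  ci <- stats::binom.test(rej, runs, 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})
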