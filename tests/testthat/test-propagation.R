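test_that("the latency basin regression recovers slope and speed exactly on
           a line", {
  fit <- fit_latency_basin(c(0, 2, 4), c(10, 20, 30), magnification = 1)
  expect_equal(fit$slope, 5)
  expect_equal(fit$ashp, 0.2)
  expect_equal(fit$r2, 1)
  expect_equal(fit$intercept, 10)
  # additive latency offsets are absorbed by the intercept
  fit2 <- fit_latency_basin(c(0, 2, 4), c(10, 20, 30) + 33)
  expect_equal(fit2$ashp, fit$ashp)
  # a non-positive slope has no propagation signature
  fit3 <- fit_latency_basin(c(0, 2, 4), c(30, 20, 10))
  expect_true(is.na(fit3$ashp))
  expect_error(fit_latency_basin(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("speed unit conversions roundtrip and match the printed
           equivalences", {
  expect_equal(retinal_to_cortical_speed(150), 0.15)
  expect_equal(retinal_to_cortical_speed(250), 0.25)
  expect_equal(cortical_to_retinal_speed(retinal_to_cortical_speed(217)),
               217)
  expect_equal(species_equivalent_speed(64, 3), 192)
})

test_that("input phase is signed center-minus-surround", {
  expect_equal(input_phase(30, 30), 0)
  expect_equal(input_phase(30, 40), 10)    # lateral leads by 10 ms
  expect_equal(input_phase(c(50, 20), c(40, 40)), c(-10, 20))
  expect_true(is.na(input_phase(NA, 40)))
})

test_that("centripetal flows lead and centrifugal flows lag the feedforward
           drive in the generator", {
  rf <- fix_rf()
  proto <- build_cardinal_protocol(rf, "surround_only")
  ct <- condition_table(proto)
  p <- quiet_params(ashp_true = 0.3)
  onset_of <- function(entry) {
    sq <- proto$condition_set[[entry]]
    cm <- sim_matrix(sq, rf, p, seeds = 1, pad_ms = 400)
    ref <- center_reference_time(sq)
    w <- build_pstw(cm$vm, cm$time_ms - ref)
    onset_latency(w, "half_height", window = c(-80, 250))
  }
  ctr <- onset_of(ct$entry[ct$condition == "CENTER_ONLY"])
  cp <- onset_of(ct$entry[ct$condition == "CP-ISO" &
                            ct$trajectory == "surround_only"][1])
  cf <- onset_of(ct$entry[ct$condition == "CF-ISO" &
                            ct$trajectory == "surround_only"][1])
  expect_gt(input_phase(cp, ctr), 0)
  expect_lt(input_phase(cf, ctr), 0)
})

test_that("the bilinear fit recovers exact two-segment data and beats a
           single line", {
  x <- seq(-10, 10)
  y <- ifelse(x > 0, 0.5 * x, 0)
  f <- fit_bilinear(x, y)
  expect_equal(f$breakpoint, 0)
  expect_equal(f$left_slope, 0, tolerance = 1e-10)
  expect_equal(f$right_slope, 0.5, tolerance = 1e-10)
  expect_lt(f$sse, 1e-18)
  # nested models: bilinear SSE never exceeds the single-line SSE
  set.seed(4)
  x2 <- runif(30, -20, 20); y2 <- 0.4 * pmax(x2, 0) + rnorm(30, 0.3)
  f2 <- fit_bilinear(x2, y2)
  sse_line <- sum(resid(lm(y2 ~ x2))^2)
  expect_lte(f2$sse, sse_line + 1e-9)
  # brute-force oracle: no candidate hinge does better
  cand <- sort(unique(c(x2, head(sort(x2), -1) + diff(sort(x2)) / 2)))
  cand <- cand[sapply(cand, function(b) sum(x2 < b) >= 2 & sum(x2 > b) >= 2)]
  sse_all <- sapply(cand, function(b) {
    sum(resid(lm(y2 ~ pmin(x2 - b, 0) + pmax(x2 - b, 0)))^2)
  })
  expect_equal(f2$sse, min(sse_all), tolerance = 1e-9)
  expect_error(fit_bilinear(1:4, 1:4), ">= 6")
})

test_that("independent-halves mode fits each side separately", {
  set.seed(6)
  x <- c(runif(15, -20, -1), runif(15, 1, 20))
  y <- ifelse(x > 0, 2 + 0.5 * x, -1) + rnorm(30, sd = 0.1)
  f <- fit_bilinear(x, y, connex = FALSE)
  expect_equal(f$right_slope, 0.5, tolerance = 0.1)
  expect_equal(f$left_slope, 0, tolerance = 0.1)
})

test_that("the Gaussian KDE integrates to one and peaks at the sample
           mode", {
  set.seed(8)
  d <- kde_density(rnorm(10000))
  dx <- diff(d$x[1:2])
  expect_equal(sum(d$density) * dx, 1, tolerance = 1e-3)
  expect_equal(d$x[which.max(d$density)], 0, tolerance = 0.15)
  d2 <- kde_density(c(rep(3, 50), 3.001))
  expect_equal(d2$x[which.max(d2$density)], 3, tolerance = 0.05)
  expect_error(kde_density(1), ">= 2")
})
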