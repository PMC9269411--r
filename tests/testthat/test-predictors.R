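test_that("the surround linear predictor is the brute-force shifted sum", {
  tm <- 0:199
  pulse <- function(t0) {
    y <- rep(0, 200); y[tm >= t0 & tm < t0 + 10] <- 1
    response_waveform(tm, y)
  }
  iso <- list(D1 = pulse(50), D2 = pulse(80))
  ev <- rbind(
    data.frame(stroke_index = 1L, node_label = "D2", onset_ms = 0,
               duration_ms = 10, x_deg = 10, y_deg = 0, ecc_deg = 10,
               orientation_deg = 0, sf_cpd = 0.5, phase_deg = 0,
               contrast = 0.9),
    data.frame(stroke_index = 2L, node_label = "D1", onset_ms = 30,
               duration_ms = 10, x_deg = 5, y_deg = 0, ecc_deg = 5,
               orientation_deg = 0, sf_cpd = 0.5, phase_deg = 0,
               contrast = 0.9))
  sq <- am_sequence("CP-ISO", "SECTOR", ev)
  slp <- surround_linear_predictor(iso, sq, time_ms = tm)
  brute <- rep(0, 200)
  brute[tm >= 80 & tm < 90] <- brute[tm >= 80 & tm < 90] + 1   # D2 + 0
  brute[tm >= 80 & tm < 90] <- brute[tm >= 80 & tm < 90] + 1   # D1 + 30
  expect_equal(slp$mean, brute)
  # zero components give a zero predictor; missing nodes error by name
  zero <- list(D1 = response_waveform(tm, rep(0, 200)),
               D2 = response_waveform(tm, rep(0, 200)))
  expect_equal(surround_linear_predictor(zero, sq, tm)$mean, rep(0, 200))
  expect_error(surround_linear_predictor(iso["D1"], sq, tm), "D2")
})

test_that("with no interaction the predictor equals the simulated
           surround-only response pointwise", {
  rf <- fix_rf()
  proto <- build_radial_protocol(rf)
  p <- quiet_params(interaction_gain = 0)
  sq <- radial_entry(proto, "CP-ISO", "SECTOR", "surround_only")
  obs <- sim_matrix(sq, rf, p, seeds = 1)
  iso <- radial_isolated_trials(proto, rf, p, n_trials = 1, seed0 = 100)
  iso_w <- lapply(iso, function(x) response_waveform(x$time_ms, x$vm[1, ]))
  slp <- surround_linear_predictor(iso_w, sq, time_ms = obs$time_ms)
  expect_equal(slp$mean, obs$vm[1, ], tolerance = 1e-6)
  # linearity: scaling every component scales the predictor
  iso_s <- lapply(iso_w, function(w) response_waveform(w$time_ms,
                                                       2.5 * w$mean))
  expect_equal(surround_linear_predictor(iso_s, sq, obs$time_ms)$mean,
               2.5 * slp$mean, tolerance = 1e-9)
})

test_that("center subtraction recovers the surround component of the
           additive model and exceeds it under the gate", {
  rf <- fix_rf()
  proto <- build_radial_protocol(rf)
  ct <- condition_table(proto)
  ctr_sq <- proto$condition_set[[ct$entry[ct$condition == "CENTER_ONLY"]]]
  # slow replay so lateral activity leads the feedforward stroke
  full_sq <- scale_speed(
    radial_entry(proto, "CP-ISO", "SECTOR", "surround_then_center"), 0.5)
  so_sq <- scale_speed(
    radial_entry(proto, "CP-ISO", "SECTOR", "surround_only"), 0.5)

  run_case <- function(gain) {
    p <- quiet_params(interaction_gain = gain)
    full <- sim_matrix(full_sq, rf, p, seeds = 1, pad_ms = 400)
    so <- sim_matrix(so_sq, rf, p, seeds = 1, pad_ms = 400)
    ctr <- sim_matrix(ctr_sq, rf, p, seeds = 1, pad_ms = 400)
    ref <- center_reference_time(full_sq)
    common <- seq(0, 250)
    ia <- match(common + ref, round(full$time_ms, 6))
    ib <- match(common, round(ctr$time_ms, 6))
    ic <- match(common + ref, round(so$time_ms, 6))
    pred <- center_subtraction_predictor(
      response_waveform(common, full$vm[1, ia]),
      response_waveform(common, ctr$vm[1, ib]))
    list(pred = pred$mean, so = so$vm[1, ic])
  }
  addv <- run_case(0)
  expect_equal(addv$pred, addv$so, tolerance = 1e-6)
  gated <- run_case(1.5)
  # the full-sequence response holds the boosted feedforward PSP, so the
  # predictor exceeds the simulated surround-only component somewhere
  expect_gt(max(gated$pred - gated$so), 0.5)
  # never materially below: small interpolation wiggle tolerated
  expect_gt(min(gated$pred - gated$so), -0.05)
})

test_that("identical full and center responses give a zero predictor and
           time bases are enforced", {
  tm <- 0:99
  w <- response_waveform(tm, sin(tm / 9))
  expect_equal(center_subtraction_predictor(w, w)$mean, rep(0, 100))
  w2 <- response_waveform(0:49, sin(0:49 / 9))
  expect_error(center_subtraction_predictor(w, w2), "time base")
})

test_that("a strong plateau above the predictor is always detected", {
  set.seed(12)
  tm <- 0:150
  obs <- t(replicate(15, rnorm(length(tm), sd = 0.5)))
  obs[, tm >= 40 & tm <= 70] <- obs[, tm >= 40 & tm <= 70] + 2.5  # 5 sigma
  slp <- response_waveform(tm, rep(0, length(tm)))
  nt <- nonlinearity_test(obs, slp, tm, n_perm = 999, seed = 8)
  expect_true(nt$significant)
  expect_true(any(nt$mask[nt$time_ms >= 40 & nt$time_ms <= 70]))
})
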