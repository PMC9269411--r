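test_that("lateral kernel follows the linear-latency / exponential-amplitude
           laws", {
  p <- generator_params(ashp_true = 0.2, base_latency = 30,
                        magnification = 1, a0 = 4, lambda_decay = 8)
  lk <- lateral_kernel(4, p)
  expect_equal(lk$onset_latency, 30 + 4 / 0.2)   # 50 ms
  lk2 <- lateral_kernel(8, p)                    # one space constant
  expect_equal(lk2$peak_amplitude, 4 / exp(1), tolerance = 1e-12)
  expect_error(lateral_kernel(-1, p))
})

test_that("latencies generated by the kernel are inverted exactly by the
           basin regression", {
  p <- generator_params(ashp_true = 0.25, base_latency = 37)
  ecc <- c(0, 2, 4, 6)
  lk <- lateral_kernel(ecc, p)
  fit <- fit_latency_basin(ecc, lk$onset_latency, magnification = 1)
  expect_equal(fit$ashp, 0.25, tolerance = 1e-10)
  expect_equal(fit$intercept, 37, tolerance = 1e-8)
  expect_equal(fit$r2, 1)
})

test_that("blank trials reduce to the resting potential in the noise-free
           limit", {
  rf <- fix_rf()
  proto <- build_cardinal_protocol(rf, "center_surround")
  blank <- proto$condition_set[[10]]
  tr <- simulate_trial(blank, rf, quiet_params(), seed = 1)
  expect_true(all(abs(tr$vm - quiet_params()$v_rest) < 1e-6))
  expect_length(tr$spike_times, 0)
})

test_that("a center-only trial is a single PSP with feedforward onset and
           contrast-scaled peak", {
  rf <- fix_rf()
  proto <- build_cardinal_protocol(rf, "center_surround")
  ct <- condition_table(proto)
  sq <- proto$condition_set[[ct$entry[ct$condition == "CENTER_ONLY"]]]
  p <- quiet_params()
  tr <- simulate_trial(sq, rf, p, seed = 1)
  dep <- tr$vm - p$v_rest
  expect_lt(max(abs(dep[tr$time_ms <= p$base_latency])), 1e-6)
  expect_gt(dep[which.min(abs(tr$time_ms - (p$base_latency + 1)))], 0)
  # peak equals ff_amplitude x contrast (kernel has unit peak)
  expect_equal(max(dep), p$ff_amplitude * 0.406, tolerance = 1e-3)
})

test_that("at the matched speed all lateral onsets coincide and peaks sum", {
  rf <- fix_rf()
  # 25 ms strokes over 5 deg spacing = 200 deg/s = ashp 0.2 at 1 mm/deg
  proto <- build_radial_protocol(rf, gabor_spec(duration_ms = 25))
  sq <- radial_entry(proto, "CP-ISO", "SECTOR", "surround_only")
  p <- quiet_params(ashp_true = 0.2)
  tr <- simulate_trial(sq, rf, p, seed = 1, pad_ms = 400)
  dep <- tr$vm - p$v_rest
  # direct summation oracle: every (patch) PSP lands at the same onset
  amps <- lateral_kernel(sq$events$ecc_deg, p)$peak_amplitude *
    sq$events$contrast
  expect_equal(max(dep), sum(amps), tolerance = 0.02 * sum(amps))
})

test_that("CF flows leave the feedforward onset untouched in the additive
           model", {
  rf <- fix_rf()
  proto <- build_radial_protocol(rf)
  p <- quiet_params()
  ct <- condition_table(proto)
  ctr <- proto$condition_set[[ct$entry[ct$condition == "CENTER_ONLY"]]]
  cf <- radial_entry(proto, "CF-ISO", "SECTOR", "surround_then_center")
  tr_ctr <- simulate_trial(ctr, rf, p, seed = 1)
  tr_cf <- simulate_trial(cf, rf, p, seed = 1)
  ## CF center stroke is at sequence start: identical early rise
  i_ctr <- tr_ctr$time_ms >= 0 & tr_ctr$time_ms <= p$base_latency + 10
  i_cf <- tr_cf$time_ms >= 0 & tr_cf$time_ms <= p$base_latency + 10
  expect_equal(tr_cf$vm[i_cf], tr_ctr$vm[i_ctr], tolerance = 1e-6)
})

test_that("OU noise matches its stationary variance and correlation time", {
  set.seed(99)
  x <- ou_noise(1e6, 0.1, 1.5, 12)
  expect_equal(stats::var(x), 1.5^2, tolerance = 0.1 * 1.5^2)
  rho <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(-0.1 / log(rho), 12, tolerance = 0.1 * 12)
})

test_that("dataset generation is reproducible and honors priors", {
  rf <- fix_rf()
  proto <- build_cardinal_protocol(rf, "center_surround")
  d1 <- generate_dataset(proto, n_cells = 2, n_blocks = 2,
                         param_priors = list(ashp_true = c(0.1, 0.3)),
                         seed = 5)
  d2 <- generate_dataset(proto, n_cells = 2, n_blocks = 2,
                         param_priors = list(ashp_true = c(0.1, 0.3)),
                         seed = 5)
  expect_identical(d1$recordings, d2$recordings)
  expect_equal(nrow(d1$index), 2 * 2 * 10)
  ashp <- vapply(d1$cells, function(cl) cl$params$ashp_true, 0)
  expect_true(all(ashp >= 0.1 & ashp <= 0.3))
  # every cell has blank trials
  expect_true(all(vapply(1:2, function(ci)
    length(dataset_trials(d1, ci, trajectory = "blank")) > 0, TRUE)))
})

test_that("the supra-linear gate boosts only PSPs led by earlier
           depolarization", {
  rf <- fix_rf()
  proto <- build_radial_protocol(rf)
  sq <- radial_entry(proto, "CP-ISO", "SECTOR", "surround_only")
  p0 <- quiet_params(interaction_gain = 0)
  pg <- quiet_params(interaction_gain = 1)
  tr0 <- simulate_trial(sq, rf, p0, seed = 1)
  trg <- simulate_trial(sq, rf, pg, seed = 1)
  expect_gt(max(trg$vm), max(tr0$vm))
  # center-only has no earlier depolarization: gain changes nothing
  ct <- condition_table(proto)
  ctr <- proto$condition_set[[ct$entry[ct$condition == "CENTER_ONLY"]]]
  expect_equal(simulate_trial(ctr, rf, pg, seed = 2)$vm,
               simulate_trial(ctr, rf, p0, seed = 2)$vm)
})
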