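test_that("cardinal protocol enumerates the printed condition sets", {
  rf <- fix_rf()
  so <- build_cardinal_protocol(rf, "surround_only")
  cs <- build_cardinal_protocol(rf, "center_surround")
  expect_equal(n_conditions(so), 18L)
  expect_equal(n_conditions(cs), 10L)
  tab <- condition_table(so)
  expect_equal(sum(tab$condition == "CENTER_ONLY"), 1L)
  expect_equal(sum(tab$condition == "BLANK"), 1L)
  # 8 flow configurations x 2 directions
  expect_equal(sum(tab$trajectory == "surround_only"), 16L)
  # geometry rules: mask 150% of MDF length, spacing 120% of mask
  expect_equal(so$mask_length_deg, 1.5 * rf$mdf_length)
  expect_equal(so$node_spacing_deg, 1.2 * so$mask_length_deg)
  ev <- so$condition_set[[1]]$events
  expect_equal(unique(ev$duration_ms), 16.6)
})

test_that("invalid RF geometry is rejected", {
  expect_error(rf_geometry(mdf_length = -1), "positive")
  expect_error(rf_geometry(mdf_length = 3, srf_extent = 2), "srf_extent")
  expect_error(gabor_spec(contrast = 0), "contrast")
})

test_that("radial protocol enumerates 43 entries with 21 isolated patches", {
  rf <- fix_rf()
  proto <- build_radial_protocol(rf)
  expect_equal(n_conditions(proto), 43L)
  tab <- condition_table(proto)
  expect_equal(sum(tab$trajectory %in% c("isolated", "center_only")), 21L)
  expect_equal(sum(tab$trajectory == "blank"), 6L)
  expect_equal(sum(tab$trajectory %in% c("surround_only",
                                         "surround_then_center")), 16L)
  # ring eccentricities at multiples of the SRF extent
  eccs <- sort(unique(proto$condition_set[[1]]$events$ecc_deg))
  expect_true(all(eccs %in% (rf$srf_extent * 0:5)))
  iso1 <- radial_entry(proto, "GP-ISO-D1", "SECTOR", "isolated")
  expect_equal(unique(iso1$events$ecc_deg), rf$srf_extent)
})

test_that("centripetal flows decrease in eccentricity and CF mirrors CP", {
  rf <- fix_rf()
  proto <- build_radial_protocol(rf)
  cp <- radial_entry(proto, "CP-ISO", "SECTOR", "surround_only")
  cf <- radial_entry(proto, "CF-ISO", "SECTOR", "surround_only")
  cp_ecc <- cp$events$ecc_deg[!duplicated(cp$events$stroke_index)]
  cf_ecc <- cf$events$ecc_deg[!duplicated(cf$events$stroke_index)]
  expect_true(all(diff(cp_ecc) < 0))
  expect_equal(cf_ecc, rev(cp_ecc))
  # full trajectories end (CP) or start (CF) at the RF center
  cp_full <- radial_entry(proto, "CP-ISO", "SECTOR", "surround_then_center")
  expect_equal(cp_full$events$node_label[which.max(cp_full$events$onset_ms)],
               "D0")
  cf_full <- radial_entry(proto, "CF-ISO", "SECTOR", "surround_then_center")
  expect_equal(cf_full$events$node_label[which.min(cf_full$events$onset_ms)],
               "D0")
})

test_that("sequence speed follows spacing over onset interval and rescales", {
  ev <- rbind(
    data.frame(stroke_index = 1L, node_label = "D2", onset_ms = 0,
               duration_ms = 25, x_deg = 10, y_deg = 0, ecc_deg = 10,
               orientation_deg = 0, sf_cpd = 0.5, phase_deg = 0,
               contrast = 0.9),
    data.frame(stroke_index = 2L, node_label = "D1", onset_ms = 25,
               duration_ms = 25, x_deg = 5, y_deg = 0, ecc_deg = 5,
               orientation_deg = 0, sf_cpd = 0.5, phase_deg = 0,
               contrast = 0.9))
  sq <- am_sequence("CP-ISO", "SECTOR", ev)
  expect_equal(sequence_speed(sq), 5 / 0.025)   # 200 deg/s
  expect_equal(sequence_speed(scale_speed(sq, 0.5)), 100)
  # identity at fraction 1, durations never altered
  expect_equal(scale_speed(sq, 1)$events$onset_ms, sq$events$onset_ms)
  expect_equal(scale_speed(sq, 0.3)$events$duration_ms,
               sq$events$duration_ms)
  expect_error(scale_speed(sq, 0), "fraction")
  expect_error(scale_speed(sq, 1.2), "fraction")
})

test_that("sequence randomization preserves energy, pins the center last,
           and is deterministic", {
  rf <- fix_rf()
  proto <- build_radial_protocol(rf)
  cp <- radial_entry(proto, "CP-ISO", "SECTOR", "surround_then_center")
  r1 <- randomize_sequence(cp, seed = 11)
  r2 <- randomize_sequence(cp, seed = 11)
  expect_identical(r1$events, r2$events)
  expect_equal(r1$condition, "RND-ISO")
  # same multiset of (position, feature) pairs as the coherent sequence
  key <- function(s) {
    e <- s$events
    sort(paste(e$x_deg, e$y_deg, e$orientation_deg, e$contrast))
  }
  expect_equal(key(r1), key(cp))
  # same stroke onsets, final stroke at the RF center
  expect_equal(sort(unique(r1$events$onset_ms)),
               sort(unique(cp$events$onset_ms)))
  expect_equal(r1$events$node_label[which.max(r1$events$onset_ms)], "D0")
  expect_error(randomize_sequence(blank_seq <- am_sequence(
    "BLANK", "SECTOR", cp$events[0, ], trajectory = "blank"), 1), "empty")
})

test_that("randomized slot assignment is uniform over seeds", {
  # 4-node pool: D0 pinned last, 3 free slots; each node should occupy each
  # free slot with frequency 1/3
  rf <- fix_rf()
  proto <- build_radial_protocol(rf, rings = 3)
  cp <- radial_entry(proto, "CP-ISO", "SECTOR", "surround_then_center")
  n_seeds <- 900
  counts <- matrix(0, 3, 3,
                   dimnames = list(paste0("slot", 1:3), paste0("D", 1:3)))
  for (s in seq_len(n_seeds)) {
    r <- randomize_sequence(cp, seed = s)
    st <- r$events[!duplicated(r$events$stroke_index), ]
    st <- st[order(st$onset_ms), ]
    for (slot in 1:3) {
      counts[slot, st$node_label[slot]] <- counts[slot, st$node_label[slot]] + 1
    }
  }
  freq <- counts / n_seeds
  # binomial 99.9% envelope around 1/3 at n = 900
  tol <- 3.3 * sqrt((1 / 3) * (2 / 3) / n_seeds)
  expect_true(all(abs(freq - 1 / 3) < tol))
})

test_that("block order is a seeded permutation and event tables roundtrip", {
  rf <- fix_rf()
  proto <- build_cardinal_protocol(rf, "center_surround",
                                   block_order_seed = 3)
  o1 <- block_order(proto, 1)
  expect_setequal(o1, seq_len(10))
  expect_identical(o1, block_order(proto, 1))
  expect_false(identical(o1, block_order(proto, 2)))
  ev <- protocol_events(proto, blocks = 2)
  expect_equal(length(unique(ev$trial[ev$block == 1])), 10L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, path)
  back <- read_event_table(path)
  expect_equal(back$onset_ms, ev$onset_ms)
  expect_equal(back$condition, ev$condition)
})
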