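## Apparent-motion protocol construction: node geometry, condition
## enumeration, sequence timing, seeded randomization.

#' Construct an apparent-motion sequence
#'
#' Low-level constructor. `events` is a data frame with one row per flashed
#' Gabor patch; multi-patch strokes (e.g. the symmetric pair of a SECTOR ring
#' or the several patches of a FULL ring) share a `stroke_index` and an onset.
#'
#' @param condition one of `"CP-ISO"`, `"CF-ISO"`, `"CP-CROSS"`, `"CF-CROSS"`,
#'   `"RND-ISO"`, `"CENTER_ONLY"`, `"SURROUND_ONLY"` variants or `"BLANK"`.
#' @param configuration `"SECTOR"`, `"FULL"` or `"CARDINAL_AXIS"`.
#' @param events data frame with columns `stroke_index`, `node_label`,
#'   `onset_ms`, `duration_ms`, `x_deg`, `y_deg`, `ecc_deg`,
#'   `orientation_deg`, `sf_cpd`, `phase_deg`, `contrast`.
#' @param speed_fraction fraction of the nominal speed (1.0, 0.7, 0.5, 0.3).
#' @param axis,direction optional annotations (cardinal protocol).
#' @param trajectory `"surround_only"`, `"surround_then_center"`,
#'   `"center_only"`, `"isolated"` or `"blank"`.
#' @return An object of class `am_sequence`.
#' @export
am_sequence <- function(condition, configuration, events,
                        speed_fraction = 1.0, axis = NA_character_,
                        direction = NA_integer_,
                        trajectory = "surround_only") {
  if (nrow(events) > 0) {
    events <- events[order(events$onset_ms, events$stroke_index), ]
    rownames(events) <- NULL
  }
  structure(
    list(condition = condition, configuration = configuration,
         events = events, speed_fraction = speed_fraction,
         axis = axis, direction = direction, trajectory = trajectory),
    class = "am_sequence")
}

event_row <- function(stroke_index, node_label, onset_ms, x, y, ecc, gabor,
                      orientation = gabor$orientation) {
  data.frame(stroke_index = stroke_index, node_label = node_label,
             onset_ms = onset_ms, duration_ms = gabor$duration_ms,
             x_deg = x, y_deg = y, ecc_deg = ecc,
             orientation_deg = orientation,
             sf_cpd = gabor$spatial_frequency, phase_deg = gabor$phase,
             contrast = gabor$contrast, stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(stroke_index = integer(0), node_label = character(0),
             onset_ms = numeric(0), duration_ms = numeric(0),
             x_deg = numeric(0), y_deg = numeric(0), ecc_deg = numeric(0),
             orientation_deg = numeric(0), sf_cpd = numeric(0),
             phase_deg = numeric(0), contrast = numeric(0),
             stringsAsFactors = FALSE)
}

blank_sequence <- function(configuration = "CARDINAL_AXIS") {
  am_sequence("BLANK", configuration, empty_events(), trajectory = "blank")
}

#' Build the cardinal apparent-motion protocol
#'
#' Two- or three-stroke sequences flashed along the two cardinal RF axes (the
#' preferred-orientation axis and the orthogonal width axis), one side of the
#' RF at a time.  The Gabor mask is sized to 150% of the spiking discharge
#' field length, its Gaussian envelope s.d. to 20% of the mask, and the
#' inter-node distance to 120% of the mask.  ISO/CROSS refer to the local
#' inducer orientation relative to the motion axis.
#'
#' The `surround_only` variant enumerates 8 flow configurations (CP/CF x
#' ISO/CROSS x main/width axis) x 2 directions plus Center-Only and Blank,
#' i.e. 18 conditions.  The `center_surround` variant enumerates 4 flows
#' (CP-ISO main axis, CP-CROSS width axis, CF-ISO main axis, CF-CROSS width
#' axis) x 2 directions, each terminating with a third stroke in the RF
#' center, plus Center-Only and Blank: 10 conditions.
#'
#' @param rf an [rf_geometry()].
#' @param variant `"surround_only"` or `"center_surround"`.
#' @param gabor template [gabor_spec()]; its mask and envelope are resized
#'   from the RF, its duration defaults to one 60 Hz frame (16.6 ms).
#' @param surround_contrast,center_contrast contrasts of the surround and
#'   center patches (defaults are the protocol means, 0.925 and 0.406).
#' @param block_order_seed integer seed used to shuffle conditions per block.
#' @return A `protocol_spec` (list with fields `protocol_family`,
#'   `condition_set`, `blanks_per_block`, `block_order_seed`, `rf`,
#'   `node_spacing_deg`).
#' @export
build_cardinal_protocol <- function(rf,
                                    variant = c("surround_only",
                                                "center_surround"),
                                    gabor = gabor_spec(),
                                    surround_contrast = 0.925,
                                    center_contrast = 0.406,
                                    block_order_seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(rf, "rf_geometry"))
  mask <- 1.5 * rf$mdf_length
  sigma <- 0.2 * mask
  spacing <- 1.2 * mask
  dur <- gabor$duration_ms
  theta <- rf$preferred_orientation * pi / 180
  axes <- list(main = c(cos(theta), sin(theta)),
               width = c(-sin(theta), cos(theta)))

  g_sur <- gabor_spec(orientation = gabor$orientation,
                      spatial_frequency = gabor$spatial_frequency,
                      phase = gabor$phase, contrast = surround_contrast,
                      mask_length = mask, envelope_sigma = sigma,
                      duration_ms = dur)
  g_ctr <- gabor_spec(orientation = 0,
                      spatial_frequency = gabor$spatial_frequency,
                      phase = gabor$phase, contrast = center_contrast,
                      mask_length = mask, envelope_sigma = sigma,
                      duration_ms = dur)

  flow_seq <- function(flow, ori_rel, axis, dir, with_center) {
    u <- axes[[axis]] * dir
    ## node positions: D2 and D1 along the axis; D0 is the RF center
    nodes <- list(D2 = list(pos = rf$center_position + 2 * spacing * u,
                            ecc = 2 * spacing),
                  D1 = list(pos = rf$center_position + spacing * u,
                            ecc = spacing))
    ## ISO: inducer along the motion axis; CROSS: orthogonal to it
    axis_ori <- if (axis == "main") 0 else 90
    ori <- (axis_ori + if (ori_rel == "ISO") 0 else 90) %% 180
    order_lab <- if (flow == "CP") c("D2", "D1") else c("D1", "D2")
    ev <- do.call(rbind, lapply(seq_along(order_lab), function(k) {
      nd <- nodes[[order_lab[k]]]
      g <- g_sur
      g$orientation <- ori
      event_row(k, order_lab[k], (k - 1) * dur,
                nd$pos[1], nd$pos[2], nd$ecc, g)
    }))
    if (with_center) {
      ev <- if (flow == "CF") {
        ## centrifugal flow starts with the center test stroke
        ev$stroke_index <- ev$stroke_index + 1L
        ev$onset_ms <- ev$onset_ms + dur
        rbind(event_row(1, "D0", 0, rf$center_position[1],
                        rf$center_position[2], 0, g_ctr), ev)
      } else {
        rbind(ev, event_row(nrow(ev) + 1, "D0", nrow(ev) * dur,
                            rf$center_position[1], rf$center_position[2],
                            0, g_ctr))
      }
    }
    am_sequence(paste0(flow, "-", ori_rel), "CARDINAL_AXIS", ev,
                axis = axis, direction = dir,
                trajectory = if (with_center) "surround_then_center"
                             else "surround_only")
  }

  combos <- if (variant == "surround_only") {
    expand.grid(flow = c("CP", "CF"), ori = c("ISO", "CROSS"),
                axis = c("main", "width"), dir = c(1, -1),
                stringsAsFactors = FALSE)
  } else {
    ## the four tested flows pair ISO with the main axis and CROSS with the
    ## width axis
    merge(data.frame(flow = c("CP", "CP", "CF", "CF"),
                     ori = c("ISO", "CROSS", "ISO", "CROSS"),
                     axis = c("main", "width", "main", "width"),
                     stringsAsFactors = FALSE),
          data.frame(dir = c(1, -1)))
  }
  seqs <- lapply(seq_len(nrow(combos)), function(i) {
    flow_seq(combos$flow[i], combos$ori[i], combos$axis[i], combos$dir[i],
             with_center = (variant == "center_surround"))
  })

  center_only <- am_sequence(
    "CENTER_ONLY", "CARDINAL_AXIS",
    event_row(1, "D0", 0, rf$center_position[1], rf$center_position[2],
              0, g_ctr),
    trajectory = "center_only")

  condition_set <- c(seqs, list(center_only, blank_sequence("CARDINAL_AXIS")))
  structure(
    list(protocol_family = "cardinal", variant = variant,
         condition_set = condition_set, blanks_per_block = 1L,
         block_order_seed = as.integer(block_order_seed), rf = rf,
         node_spacing_deg = spacing, mask_length_deg = mask),
    class = "protocol_spec")
}

#' Build the radial apparent-motion protocol
#'
#' The visual field is paved with concentric rings of increasing eccentricity
#' around the RF center; inter-ring spacing and patch size are set from the
#' full extent of the subthreshold depolarizing receptive field (SRF), so the
#' nearest ring D1 does not encroach on the SRF.  Each block contains 16
#' apparent-motion sequences (4 conditions x 2 trajectories x 2
#' configurations), 21 isolated-patch stimulations (5 peripheral rings x
#' ISO/CROSS x SECTOR/FULL + 1 center patch), and 6 blanks: 43 entries.
#'
#' @param rf an [rf_geometry()].
#' @param gabor template [gabor_spec()]; mask resized to the SRF extent.
#' @param rings number of concentric rings (>= 2; the printed protocol
#'   uses 5).
#' @param sector_halfwidth angular half-width of the SECTOR configuration,
#'   degrees.
#' @param stroke_duration_ms stroke duration, ms (default 30).
#' @param full_axes number of motion axes represented in the FULL
#'   configuration (patches per ring = `2 * full_axes`).
#' @param surround_contrast,center_contrast surround and center contrasts.
#' @param rnd_seed seed of the RND-ISO spatio-temporal shuffle.
#' @param blanks_per_block number of blank trials per block (default 6).
#' @param block_order_seed integer seed used to shuffle entries per block.
#' @return A `protocol_spec`.
#' @export
build_radial_protocol <- function(rf, gabor = gabor_spec(duration_ms = 30),
                                  rings = 5L, sector_halfwidth = 30,
                                  stroke_duration_ms = gabor$duration_ms,
                                  full_axes = 4L,
                                  surround_contrast = 0.925,
                                  center_contrast = 0.406,
                                  rnd_seed = 1L,
                                  blanks_per_block = 6L,
                                  block_order_seed = 1L) {
  stopifnot(inherits(rf, "rf_geometry"), rings >= 2)
  spacing <- rf$srf_extent
  mask <- rf$srf_extent
  if (spacing - mask / 2 < rf$srf_extent / 2 - 1e-9) {
    stop("invalid geometry: ring D1 would overlap the SRF", call. = FALSE)
  }
  theta <- rf$preferred_orientation * pi / 180
  dur <- stroke_duration_ms

  mk_gabor <- function(ori, contrast) {
    gabor_spec(orientation = ori,
               spatial_frequency = gabor$spatial_frequency,
               phase = gabor$phase, contrast = contrast,
               mask_length = mask, envelope_sigma = 0.2 * mask,
               duration_ms = dur)
  }

  ## patch centers on ring k for a configuration: SECTOR = symmetric pair on
  ## the preferred-orientation axis; FULL = 2*full_axes patches spread evenly
  ring_positions <- function(k, configuration) {
    r <- k * spacing
    ang <- if (configuration == "SECTOR") {
      theta + c(0, pi)
    } else {
      theta + seq(0, 2 * pi, length.out = 2 * full_axes + 1)[-(2 * full_axes + 1)]
    }
    data.frame(x = rf$center_position[1] + r * cos(ang),
               y = rf$center_position[2] + r * sin(ang), ecc = r)
  }

  ring_stroke <- function(k, stroke_index, onset, configuration, ori_rel) {
    pos <- ring_positions(k, configuration)
    ## ISO: co-aligned with the (radial) motion axis / preferred orientation;
    ## CROSS: orthogonal
    ori <- if (ori_rel == "ISO") 0 else 90
    g <- mk_gabor(ori, surround_contrast)
    do.call(rbind, lapply(seq_len(nrow(pos)), function(i) {
      event_row(stroke_index, paste0("D", k), onset,
                pos$x[i], pos$y[i], pos$ecc[i], g)
    }))
  }

  center_stroke <- function(stroke_index, onset) {
    event_row(stroke_index, "D0", onset, rf$center_position[1],
              rf$center_position[2], 0, mk_gabor(0, center_contrast))
  }

  make_am <- function(condition, configuration, trajectory, rnd_seed_k) {
    ring_order <- switch(condition,
      "CP-ISO" = , "CP-CROSS" = rev(seq_len(rings)),
      "CF-ISO" = seq_len(rings),
      "RND-ISO" = {
        rs <- local({set.seed(rnd_seed_k); sample(seq_len(rings))})
        rs
      })
    ori_rel <- if (condition == "CP-CROSS") "CROSS" else "ISO"
    n_strokes <- rings + as.integer(trajectory == "surround_then_center")
    ev <- do.call(rbind, lapply(seq_along(ring_order), function(s) {
      ring_stroke(ring_order[s], s, (s - 1) * dur, configuration, ori_rel)
    }))
    if (trajectory == "surround_then_center") {
      ## full trajectories always end in the RF center
      if (condition == "CF-ISO") {
        ## centrifugal full sequence starts at the center
        ev$stroke_index <- ev$stroke_index + 1L
        ev$onset_ms <- ev$onset_ms + dur
        ev <- rbind(center_stroke(1L, 0), ev)
      } else {
        ev <- rbind(ev, center_stroke(rings + 1L, rings * dur))
      }
    }
    am_sequence(condition, configuration, ev, trajectory = trajectory)
  }

  conditions <- c("CP-ISO", "CF-ISO", "CP-CROSS", "RND-ISO")
  am_entries <- list()
  k <- 0L
  for (cond in conditions) for (traj in c("surround_only",
                                          "surround_then_center"))
    for (cfg in c("SECTOR", "FULL")) {
      k <- k + 1L
      am_entries[[k]] <- make_am(cond, cfg, traj,
                                 rnd_seed_k = rnd_seed + k)
    }

  iso_entries <- list()
  k <- 0L
  for (ring in seq_len(rings)) for (ori_rel in c("ISO", "CROSS"))
    for (cfg in c("SECTOR", "FULL")) {
      k <- k + 1L
      ev <- ring_stroke(ring, 1L, 0, cfg, ori_rel)
      iso_entries[[k]] <- am_sequence(
        paste0("GP-", ori_rel, "-D", ring), cfg, ev,
        trajectory = "isolated")
    }
  iso_entries[[k + 1L]] <- am_sequence("CENTER_ONLY", "SECTOR",
                                       center_stroke(1L, 0),
                                       trajectory = "center_only")

  blanks <- replicate(blanks_per_block, blank_sequence("SECTOR"),
                      simplify = FALSE)

  structure(
    list(protocol_family = "radial", variant = "radial",
         condition_set = c(am_entries, iso_entries, blanks),
         blanks_per_block = as.integer(blanks_per_block),
         block_order_seed = as.integer(block_order_seed), rf = rf,
         node_spacing_deg = spacing, mask_length_deg = mask,
         rings = as.integer(rings), sector_halfwidth = sector_halfwidth),
    class = "protocol_spec")
}

#' Number of stimulation entries in a protocol block
#' @param protocol a `protocol_spec`.
#' @return integer count (blanks included).
#' @export
n_conditions <- function(protocol) length(protocol$condition_set)

#' Labels of the entries of a protocol
#' @param protocol a `protocol_spec`.
#' @return data frame with `entry`, `condition`, `configuration`,
#'   `trajectory`.
#' @export
condition_table <- function(protocol) {
  data.frame(
    entry = seq_along(protocol$condition_set),
    condition = vapply(protocol$condition_set, `[[`, "", "condition"),
    configuration = vapply(protocol$condition_set, `[[`, "",
                           "configuration"),
    trajectory = vapply(protocol$condition_set, `[[`, "", "trajectory"),
    stringsAsFactors = FALSE)
}

#' Apparent-motion speed of a sequence
#'
#' Speed is the inter-node distance divided by the inter-stroke onset
#' interval, in degrees per second.  Strokes sharing an onset (multi-patch
#' rings) count once.
#'
#' @param seq an `am_sequence` with at least two strokes at distinct
#'   eccentricities.
#' @return speed in degrees/s.
#' @export
sequence_speed <- function(seq) {
  ev <- seq$events
  strokes <- ev[!duplicated(ev$stroke_index), ]
  if (nrow(strokes) < 2 || length(unique(strokes$ecc_deg)) < 2) {
    stop("sequence_speed needs >= 2 strokes at distinct positions",
         call. = FALSE)
  }
  d_ecc <- abs(diff(strokes$ecc_deg))
  d_t <- diff(strokes$onset_ms)
  stats::median(d_ecc / (d_t / 1000))
}

#' Replay a sequence at a fraction of its nominal speed
#'
#' Inserts inter-stroke delays so that the returned sequence's speed equals
#' `fraction` times the nominal speed; stroke durations are unchanged.
#'
#' @param seq an `am_sequence`.
#' @param fraction in `(0, 1]`.
#' @return the rescaled `am_sequence` (with `speed_fraction` recorded).
#' @export
scale_speed <- function(seq, fraction) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("speed fraction must lie in (0, 1]", call. = FALSE)
  }
  ev <- seq$events
  if (nrow(ev) > 0) {
    t0 <- min(ev$onset_ms)
    ev$onset_ms <- t0 + (ev$onset_ms - t0) / fraction
  }
  out <- am_sequence(seq$condition, seq$configuration, ev,
                     speed_fraction = seq$speed_fraction * fraction,
                     axis = seq$axis, direction = seq$direction,
                     trajectory = seq$trajectory)
  out
}

#' Spatio-temporal randomization of an apparent-motion sequence (RND-ISO)
#'
#' Permutes the assignment of nodes to stroke slots while keeping the stroke
#' onsets, durations and Gabor features, so that the randomized sequence has
#' the same energy distribution as the coherent one.  If the sequence ends in
#' the RF center (node `D0`), that final stroke is left in place: the last
#' stimulus location is always the RF center.
#'
#' @param seq an `am_sequence` (typically a CP-ISO template).
#' @param seed integer; the permutation is deterministic given the seed.
#' @return an `am_sequence` with condition `"RND-ISO"`.
#' @export
randomize_sequence <- function(seq, seed) {
  ev <- seq$events
  if (nrow(ev) == 0) stop("cannot randomize an empty sequence",
                          call. = FALSE)
  strokes <- sort(unique(ev$stroke_index))
  has_center <- "D0" %in% ev$node_label
  center_stroke <- if (has_center)
    unique(ev$stroke_index[ev$node_label == "D0"]) else integer(0)
  free <- setdiff(strokes, center_stroke)
  perm <- local({
    set.seed(as.integer(seed))
    free[sample.int(length(free))]
  })
  ## timing template per stroke slot
  slot_onset <- vapply(strokes,
                       function(s) min(ev$onset_ms[ev$stroke_index == s]), 0)
  names(slot_onset) <- as.character(strokes)
  acc <- lapply(seq_along(free), function(i) {
    new_rows <- ev[ev$stroke_index == perm[i], ] # node group -> slot free[i]
    new_rows$stroke_index <- free[i]
    new_rows$onset_ms <- slot_onset[[as.character(free[i])]]
    new_rows
  })
  keep <- ev[ev$stroke_index %in% center_stroke, ]
  out_ev <- rbind(do.call(rbind, acc), keep)
  am_sequence("RND-ISO", seq$configuration, out_ev,
              speed_fraction = seq$speed_fraction, axis = seq$axis,
              direction = seq$direction, trajectory = seq$trajectory)
}

#' Block presentation order
#'
#' Every block presents each entry of the condition set exactly once, in a
#' seeded random order (blanks are interleaved as ordinary entries).
#'
#' @param protocol a `protocol_spec`.
#' @param block block number (>= 1).
#' @return integer permutation of the entry indices.
#' @export
block_order <- function(protocol, block) {
  n <- n_conditions(protocol)
  seed <- derive_seed(protocol$block_order_seed, 7L, block)
  local({set.seed(seed); sample(n)})
}

#' Full stimulus event table of a protocol
#'
#' One row per flashed patch per entry, in the canonical CSV schema.
#'
#' @param protocol a `protocol_spec`.
#' @param blocks number of blocks to enumerate (default 1).
#' @return data frame with columns `block`, `trial`, `entry`, `condition`,
#'   `configuration`, plus the per-event columns.
#' @export
protocol_events <- function(protocol, blocks = 1L) {
  out <- list()
  for (b in seq_len(blocks)) {
    ord <- block_order(protocol, b)
    for (t in seq_along(ord)) {
      sq <- protocol$condition_set[[ord[t]]]
      ev <- sq$events
      if (nrow(ev) == 0) {
        ev <- empty_events()[0, ]
        ev[1, ] <- NA
        ev$stroke_index <- NA_integer_
      }
      ev$block <- b
      ev$trial <- t
      ev$entry <- ord[t]
      ev$condition <- sq$condition
      ev$configuration <- sq$configuration
      out[[length(out) + 1]] <- ev
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("block", "trial", "entry", "condition", "configuration",
          "stroke_index", "node_label", "onset_ms", "duration_ms",
          "x_deg", "y_deg", "ecc_deg", "orientation_deg", "sf_cpd",
          "phase_deg", "contrast")]
}

#' Write / read a stimulus event table as CSV
#' @param events data frame from [protocol_events()].
#' @param path CSV path.
#' @return `read_event_table` returns the data frame.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
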