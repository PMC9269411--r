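## Dataset container I/O and the four-stage pipeline:
## simulate -> preprocess -> analyze -> report.

#' Expected center-stroke reference time of a sequence
#'
#' The common temporal reference for phase and modulation analyses: the
#' onset of the center stroke if present, otherwise the time at which the
#' center stimulus would have appeared (one inter-stroke interval after the
#' last surround stroke onset).
#'
#' @param seq an `am_sequence`.
#' @return time in ms on the sequence clock.
#' @export
center_reference_time <- function(seq) {
  ev <- seq$events
  if (nrow(ev) == 0) return(0)
  if ("D0" %in% ev$node_label) {
    return(min(ev$onset_ms[ev$node_label == "D0"]))
  }
  strokes <- ev[!duplicated(ev$stroke_index), ]
  strokes <- strokes[order(strokes$onset_ms), ]
  if (nrow(strokes) >= 2) {
    step <- stats::median(diff(strokes$onset_ms))
    if (all(diff(strokes$ecc_deg) > 0)) {
      ## centrifugal: the omitted center stroke precedes the flow
      strokes$onset_ms[1] - step
    } else {
      max(strokes$onset_ms) + step
    }
  } else {
    max(ev$onset_ms) + ev$duration_ms[which.max(ev$onset_ms)]
  }
}

#' Shift a trial matrix onto a center-referenced time base
#'
#' Interpolates each trial so that time 0 is the (expected) center stroke
#' onset; samples shifted outside the recorded window are dropped.
#'
#' @param vm trials x time matrix.
#' @param time_ms time base (0 = sequence start).
#' @param reference_ms the center reference time to map to 0.
#' @return list `time_ms`, `vm`.
#' @export
shift_to_reference <- function(vm, time_ms, reference_ms) {
  new_t <- time_ms - reference_ms
  keep <- seq_along(new_t)
  grid <- seq(ceiling(min(new_t)), floor(max(new_t)), by = 1)
  out <- t(apply(as.matrix(vm), 1, function(r) {
    stats::approx(new_t, r, xout = grid)$y
  }))
  list(time_ms = grid, vm = out)
}

#' Pipeline run configuration
#'
#' @param protocol_family `"cardinal"` or `"radial"`.
#' @param variant cardinal variant (`"center_surround"` or
#'   `"surround_only"`); ignored for radial.
#' @param rf the [rf_geometry()] shared by the synthetic cells.
#' @param n_cells,n_blocks dataset size.
#' @param param_priors priors for [generate_dataset()].
#' @param n_permutations permutations for all randomization tests.
#' @param alpha test level.
#' @param min_consecutive_ms duration criterion for pointwise tests.
#' @param magnification mm/degree for ASHP conversion.
#' @param master_seed master seed; every stochastic stage derives a named
#'   substream from it.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(protocol_family = "cardinal",
                       variant = "center_surround",
                       rf = rf_geometry(),
                       n_cells = 3L, n_blocks = 20L,
                       param_priors = list(ashp_true = c(0.1, 0.3)),
                       n_permutations = 1000L, alpha = 0.05,
                       min_consecutive_ms = 1, magnification = 1,
                       master_seed = 1L, out_dir = tempfile("lf_run_")) {
  if (1 / n_permutations > alpha) {
    stop("config refused: n_permutations < 1/alpha leaves the test level ",
         "unreachable", call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

build_protocol_from_config <- function(config) {
  if (config$protocol_family == "cardinal") {
    build_cardinal_protocol(config$rf, variant = config$variant,
                            block_order_seed = derive_seed(
                              config$master_seed, 5L))
  } else {
    build_radial_protocol(config$rf,
                          rnd_seed = derive_seed(config$master_seed, 6L),
                          block_order_seed = derive_seed(
                            config$master_seed, 5L))
  }
}

#' Run the full pipeline: simulate, preprocess, analyze, report
#'
#' Simulates a dataset under the configured protocol, conditions every
#' trial, and computes per cell: responsiveness screening, blank-referenced
#' permutation significance of Surround-Only responses, contextual
#' modulation (latency and integral) of every full sequence against
#' Center-Only, and (radial) the latency basin and ASHP from isolated-patch
#' responses.  Results tables, population summaries and a run manifest are
#' written to the output directory.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with `dataset`, `results` (per-cell data
#'   frame), `ashp` (per-cell data frame), `out_dir`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  proto <- build_protocol_from_config(config)

  ## --- simulate ---
  ds <- generate_dataset(proto, n_cells = config$n_cells,
                         n_blocks = config$n_blocks,
                         param_priors = config$param_priors,
                         seed = config$master_seed)
  write_event_table(protocol_events(proto),
                    file.path(config$out_dir, "stimulus_events.csv"))

  ## --- preprocess + analyze per cell ---
  results <- list()
  ashp_rows <- list()
  ct <- condition_table(proto)
  for (ci in seq_len(config$n_cells)) {
    blanks <- condition_trials(dataset_trials(ds, ci,
                                              trajectory = "blank"))
    blank_w <- build_pstw(blanks$vm, blanks$time_ms)
    blank_stats <- list(mean = mean(blank_w$mean), sd = stats::sd(blank_w$mean))
    ## blank reference interpolated onto each entry's own time base
    blank_on <- function(t) {
      stats::approx(blank_w$time_ms, blank_w$mean, xout = t, rule = 2)$y
    }
    center <- condition_trials(dataset_trials(ds, ci,
                                              trajectory = "center_only"))
    center_bs <- subtract_blank_trials(center$vm, blank_on(center$time_ms))
    blank_bs <- subtract_blank_trials(blanks$vm, blank_w$mean)
    responsive <- screen_responsive(center_bs, blank_bs, center$time_ms,
                                    n_perm = config$n_permutations,
                                    seed = derive_seed(config$master_seed,
                                                       21L, ci))
    groups <- unique(ct[ct$trajectory %in% c("surround_only",
                                             "surround_then_center"),
                        c("condition", "configuration", "trajectory")])
    for (g in seq_len(nrow(groups))) {
      gc <- groups[g, ]
      entries <- ct$entry[ct$condition == gc$condition &
                            ct$configuration == gc$configuration &
                            ct$trajectory == gc$trajectory]
      sq <- proto$condition_set[[entries[1]]]
      tl <- dataset_trials(ds, ci, condition = gc$condition,
                           configuration = gc$configuration,
                           trajectory = gc$trajectory)
      cm <- condition_trials(tl)
      ref <- center_reference_time(sq)
      sh <- shift_to_reference(subtract_blank_trials(cm$vm,
                                                     blank_on(cm$time_ms)),
                               cm$time_ms, ref)
      ## surround-only pointwise significance vs blank
      so_sig <- NA
      if (gc$trajectory == "surround_only") {
        bl_sh <- shift_to_reference(blank_bs, blanks$time_ms, 0)
        common <- intersect(sh$time_ms, bl_sh$time_ms)
        common <- common[common >= 0 & common <= 120]
        if (length(common) > 20) {
          ia <- match(common, sh$time_ms); ib <- match(common, bl_sh$time_ms)
          env <- permutation_envelope(
            sh$vm[, ia, drop = FALSE], bl_sh$vm[, ib, drop = FALSE],
            common, n_perm = config$n_permutations, alpha = config$alpha,
            min_consecutive_ms = config$min_consecutive_ms,
            seed = derive_seed(config$master_seed, 22L, ci, g))
          so_sig <- any(env$mask)
        }
      }
      ## contextual modulation for full sequences
      dl <- ratio <- p_lat <- p_int <- NA_real_
      if (gc$trajectory == "surround_then_center" && isTRUE(responsive)) {
        common <- intersect(sh$time_ms, center$time_ms)
        common <- common[common >= -50 & common <= 250]
        ia <- match(common, sh$time_ms); ib <- match(common, center$time_ms)
        mod <- contextual_modulation(
          sh$vm[, ia, drop = FALSE], center_bs[, ib, drop = FALSE], common,
          window = c(0, min(250, max(common))),
          latency_window = c(0, min(120, max(common))),
          n_perm = config$n_permutations, alpha = config$alpha,
          seed = derive_seed(config$master_seed, 23L, ci, g))
        dl <- mod$delta_latency_ms; ratio <- mod$delta_integral_ratio
        p_lat <- mod$p_latency; p_int <- mod$p_integral
      }
      results[[length(results) + 1]] <- data.frame(
        cell = ci, condition = gc$condition,
        configuration = gc$configuration, trajectory = gc$trajectory,
        speed_fraction = sq$speed_fraction, responsive = isTRUE(responsive),
        delta_latency_ms = dl, delta_integral_ratio = ratio,
        p_latency = p_lat, p_integral = p_int,
        surround_only_significant = so_sig, stringsAsFactors = FALSE)
    }
    ## latency basin from isolated-patch responses (radial protocol)
    if (proto$protocol_family == "radial") {
      iso <- ct[ct$trajectory == "isolated" &
                  grepl("^GP-ISO", ct$condition) &
                  ct$configuration == "SECTOR", ]
      lat <- ecc <- numeric(0)
      for (e in iso$entry) {
        sq <- proto$condition_set[[e]]
        tl <- dataset_trials(ds, ci, condition = sq$condition,
                             configuration = "SECTOR")
        cm <- condition_trials(tl)
        w <- build_pstw(subtract_blank_trials(cm$vm, blank_on(cm$time_ms)),
                        cm$time_ms)
        l <- onset_latency(w, "half_height", window = c(0, 250),
                           sustain_ms = 5)
        if (is.finite(l)) {
          lat <- c(lat, l)
          ecc <- c(ecc, sq$events$ecc_deg[1])
        }
      }
      if (length(unique(ecc)) >= 3) {
        fit <- fit_latency_basin(ecc, lat,
                                 magnification = config$magnification)
        ashp_rows[[length(ashp_rows) + 1]] <- data.frame(
          cell = ci, slope_ms_per_deg = fit$slope, ashp_mm_per_ms = fit$ashp,
          r2 = fit$r2, true_ashp = ds$cells[[ci]]$params$ashp_true)
      }
    }
  }
  results <- do.call(rbind, results)
  ashp_tab <- if (length(ashp_rows)) do.call(rbind, ashp_rows) else NULL

  ## --- report ---
  tables <- list(cell_results = results)
  if (!is.null(ashp_tab)) tables$ashp <- ashp_tab
  write_results(config$out_dir, tables)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lateralflow")),
    master_seed = config$master_seed,
    protocol_family = config$protocol_family,
    n_cells = config$n_cells, n_blocks = config$n_blocks,
    n_permutations = config$n_permutations, alpha = config$alpha,
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dataset = ds, results = results, ashp = ashp_tab,
                 out_dir = config$out_dir))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(
    lapply(cfg, function(v) if (is.list(v)) lapply(v, unclass) else unclass(v)),
    tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write results tables to a directory as CSV
#' @param dir output directory.
#' @param tables named list of data frames.
#' @return (invisibly) the written paths.
#' @export
write_results <- function(dir, tables) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Write / read a dataset container
#'
#' One directory per dataset: per-trial arrays as `.rds` under `trials/`,
#' an `index.csv`, and a `meta.json` sidecar carrying the master seed,
#' sampling parameters, per-cell generator parameters and any extra metadata
#' keys (preserved verbatim on roundtrip).
#'
#' @param dataset an `lf_dataset`.
#' @param dir container directory.
#' @return `read_dataset` returns the `lf_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "trials"), showWarnings = FALSE,
             recursive = TRUE)
  utils::write.csv(dataset$index, file.path(dir, "index.csv"),
                   row.names = FALSE)
  for (key in names(dataset$recordings)) {
    saveRDS(dataset$recordings[[key]],
            file.path(dir, "trials", paste0(key, ".rds")))
  }
  saveRDS(dataset$cells, file.path(dir, "cells.rds"))
  meta <- c(list(master_seed = dataset$master_seed, fs = dataset$fs,
                 pre_ms = dataset$pre_ms, pad_ms = dataset$pad_ms,
                 schema_version = 1L),
            dataset$extra_meta)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("not a dataset container: missing ",
                                    meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1L) {
    stop("unsupported dataset schema version: ",
         deparse(meta$schema_version), call. = FALSE)
  }
  index <- utils::read.csv(file.path(dir, "index.csv"),
                           stringsAsFactors = FALSE)
  recs <- list()
  for (key in index$key) {
    p <- file.path(dir, "trials", paste0(key, ".rds"))
    rec <- tryCatch(readRDS(p), error = function(e) {
      stop("corrupt or truncated trial file: ", p, call. = FALSE)
    })
    recs[[key]] <- rec
  }
  known <- c("master_seed", "fs", "pre_ms", "pad_ms", "schema_version")
  structure(
    list(cells = readRDS(file.path(dir, "cells.rds")), recordings = recs,
         index = index, master_seed = meta$master_seed, fs = meta$fs,
         pre_ms = meta$pre_ms, pad_ms = meta$pad_ms,
         extra_meta = meta[setdiff(names(meta), known)]),
    class = "lf_dataset")
}
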