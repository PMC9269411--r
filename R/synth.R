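## Synthetic membrane-potential generator embodying the working hypothesis:
## feedforward PSPs to center strokes, lateral PSPs whose onset latency grows
## linearly and amplitude decays exponentially with eccentricity, OU
## background noise, threshold spiking, and an optional gated supra-linear
## interaction.

#' Generator parameters for the synthetic membrane-potential model
#'
#' The lateral (horizontal) pathway is parameterized by an apparent speed of
#' horizontal propagation (ASHP, mm/ms), a cortical magnification factor
#' (mm/degree), a peak amplitude at zero eccentricity and an exponential
#' space constant; a surround stroke at eccentricity `e` evokes a PSP with
#' onset `base_latency + e * magnification / ashp_true` (ms) and peak
#' `a0 * exp(-e / lambda_decay)` (mV).  Feedforward PSPs to center strokes
#' have onset `base_latency` and peak `ff_amplitude`.  Both are scaled by the
#' stroke contrast.
#'
#' The supra-linear interaction is a gated gain: a PSP whose onset is led by
#' accumulated depolarization from earlier strokes by more than
#' `interaction_lag_threshold` (default 5.5 ms) is boosted by
#' `1 + interaction_gain`.  With `interaction_gain = 0` the model is exactly
#' additive.
#'
#' @param ashp_true apparent speed of horizontal propagation, mm/ms
#'   (physiological range roughly 0.05-0.60).
#' @param base_latency feedforward onset latency at the RF center, ms.
#' @param magnification cortical magnification, mm per degree.
#' @param a0 lateral PSP peak at zero eccentricity, mV.
#' @param lambda_decay exponential space constant of the lateral amplitude,
#'   degrees (> 0).
#' @param ff_amplitude feedforward PSP peak at unit contrast, mV.
#' @param psp_rise,psp_decay PSP kernel time constants, ms.
#' @param v_rest resting potential, mV.
#' @param noise_sigma stationary s.d. of the OU background noise, mV.
#' @param noise_tau OU correlation time, ms.
#' @param spike_threshold spike threshold, mV.
#' @param refractory absolute refractory period, ms.
#' @param interaction_gain supra-linear boost gain (>= 0; 0 = additive).
#' @param interaction_lag_threshold minimum lead of accumulated lateral
#'   depolarization over a PSP onset for the boost to engage, ms.
#' @param soft_clip logical; saturate depolarizations towards a synaptic
#'   reversal potential (off by default).
#' @param e_rev synaptic reversal potential used by `soft_clip`, mV.
#' @param rng_seed optional integer seed stored with the parameters.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(ashp_true = 0.2,
                             base_latency = 40,
                             magnification = 1,
                             a0 = 4,
                             lambda_decay = 15,
                             ff_amplitude = 8,
                             psp_rise = 4,
                             psp_decay = 20,
                             v_rest = -70,
                             noise_sigma = 1,
                             noise_tau = 15,
                             spike_threshold = -60,
                             refractory = 3,
                             interaction_gain = 0,
                             interaction_lag_threshold = 5.5,
                             soft_clip = FALSE,
                             e_rev = 0,
                             rng_seed = NULL) {
  stopifnot(ashp_true > 0, lambda_decay > 0, noise_sigma >= 0,
            noise_tau > 0, psp_rise > 0, psp_decay > psp_rise,
            interaction_gain >= 0)
  structure(as.list(environment()), class = "generator_params")
}

#' Normalized double-exponential PSP kernel
#'
#' `k(t) = (exp(-t/decay) - exp(-t/rise)) / k_peak` for `t >= 0`, zero
#' before onset; the peak value is 1 at
#' `t_peak = rise * decay / (decay - rise) * log(decay / rise)`.
#'
#' @param t_ms time from PSP onset, ms (vectorized).
#' @param rise,decay time constants, ms (`decay > rise`).
#' @return kernel values, unit peak.
#' @export
psp_kernel <- function(t_ms, rise = 4, decay = 20) {
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  out <- numeric(length(t_ms))
  pos <- t_ms > 0
  out[pos] <- (exp(-t_ms[pos] / decay) - exp(-t_ms[pos] / rise)) / peak
  out
}

#' Onset latency and peak amplitude of the lateral PSP at an eccentricity
#'
#' @param eccentricity degrees from the RF center (>= 0, vectorized).
#' @param p a [generator_params()].
#' @return data frame with `onset_latency` (ms) and `peak_amplitude` (mV).
#' @export
lateral_kernel <- function(eccentricity, p) {
  stopifnot(all(eccentricity >= 0))
  data.frame(
    onset_latency = p$base_latency +
      eccentricity * p$magnification / p$ashp_true,
    peak_amplitude = p$a0 * exp(-eccentricity / p$lambda_decay))
}

#' Ornstein-Uhlenbeck background noise
#'
#' Exact discretization of a stationary OU process with s.d. `sigma` and
#' correlation time `tau`.
#'
#' @param n number of samples.
#' @param dt_ms sampling step, ms.
#' @param sigma stationary standard deviation, mV.
#' @param tau correlation time, ms.
#' @return numeric vector of length `n`.
#' @export
ou_noise <- function(n, dt_ms, sigma, tau) {
  if (sigma <= 0) return(numeric(n))
  rho <- exp(-dt_ms / tau)
  innov <- stats::rnorm(n, sd = sigma * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, sd = sigma)   # stationary start
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

spike_shape <- function(n, dt_ms, amp = 45, tau = 0.35) {
  t <- seq_len(n) * dt_ms
  amp * (t / tau) * exp(1 - t / tau)
}

## Deterministic PSP schedule of a sequence: one lateral PSP per surround
## patch, one feedforward PSP per center stroke, with the gated supra-linear
## boost resolved from onsets and noise-free accumulated depolarization.
psp_schedule <- function(seq, p, eps = 0.05) {
  ev <- seq$events
  if (nrow(ev) == 0) {
    return(data.frame(onset = numeric(0), amp = numeric(0),
                      type = character(0), boosted = logical(0)))
  }
  is_center <- ev$node_label == "D0"
  lk <- lateral_kernel(ev$ecc_deg, p)
  onset <- ifelse(is_center,
                  ev$onset_ms + p$base_latency,
                  ev$onset_ms + lk$onset_latency)
  amp <- ifelse(is_center,
                p$ff_amplitude * ev$contrast,
                lk$peak_amplitude * ev$contrast)
  sch <- data.frame(onset = onset, amp = amp,
                    type = ifelse(is_center, "ff", "lateral"),
                    boosted = FALSE, stringsAsFactors = FALSE)
  sch <- sch[order(sch$onset), ]
  rownames(sch) <- NULL
  if (p$interaction_gain > 0 && nrow(sch) > 1) {
    for (i in 2:nrow(sch)) {
      earlier <- sch[seq_len(i - 1), , drop = FALSE]
      lead <- sch$onset[i] - min(earlier$onset)
      prior <- sum(earlier$amp *
                     psp_kernel(sch$onset[i] - earlier$onset,
                                p$psp_rise, p$psp_decay))
      if (lead > p$interaction_lag_threshold && prior > eps) {
        sch$boosted[i] <- TRUE
        sch$amp[i] <- sch$amp[i] * (1 + p$interaction_gain)
      }
    }
  }
  sch
}

#' Simulate one trial of an apparent-motion sequence
#'
#' The membrane potential is the resting potential plus OU background noise,
#' plus one lateral PSP per surround patch (onset and amplitude from
#' [lateral_kernel()], scaled by the stroke contrast), plus a feedforward PSP
#' per center stroke, with the gated supra-linear boost of
#' [generator_params()].  Spikes are emitted at upward threshold crossings
#' with an absolute refractory period, and a stereotyped spike waveform is
#' added to the trace so that spike removal can be exercised downstream.
#'
#' @param seq an `am_sequence` from a protocol consistent with `rf`.
#' @param rf the cell's [rf_geometry()].
#' @param p a [generator_params()].
#' @param seed integer seed; the trial is deterministic given the seed.
#' @param fs sampling rate, Hz (10 kHz as digitized).
#' @param pre_ms baseline recorded before the first stroke, ms.
#' @param pad_ms recording continued after the last stroke offset, ms.
#' @return An object of class `trial_recording`: fields `vm` (mV),
#'   `spike_times` (ms, on the trial clock whose 0 is sequence start),
#'   `time_ms`, `fs`, `condition`, `configuration`, `trajectory`.
#' @export
simulate_trial <- function(seq, rf, p, seed = 1L, fs = 10000,
                           pre_ms = 100, pad_ms = 300) {
  dt <- 1000 / fs
  ev <- seq$events
  t_end <- if (nrow(ev) == 0) 500 else
    max(ev$onset_ms + ev$duration_ms) + pad_ms
  time_ms <- seq(-pre_ms, t_end, by = dt)
  n <- length(time_ms)

  set.seed(as.integer(seed))
  vm <- p$v_rest + ou_noise(n, dt, p$noise_sigma, p$noise_tau)

  sch <- psp_schedule(seq, p)
  dep <- numeric(n)
  if (nrow(sch) > 0) {
    span <- min(n, ceiling((8 * p$psp_decay) / dt))
    kern <- psp_kernel(seq_len(span) * dt, p$psp_rise, p$psp_decay)
    for (i in seq_len(nrow(sch))) {
      i0 <- findInterval(sch$onset[i], time_ms)
      idx <- i0 + seq_len(min(span, n - i0))
      dep[idx] <- dep[idx] + sch$amp[i] * kern[seq_along(idx)]
    }
  }
  if (isTRUE(p$soft_clip)) {
    dmax <- p$e_rev - p$v_rest
    dep <- dmax * tanh(dep / dmax)
  }
  vm <- vm + dep

  ## threshold crossings with refractory; add stereotyped spike waveforms
  spike_times <- numeric(0)
  above <- vm >= p$spike_threshold
  cross <- which(above & !c(FALSE, above[-n]))
  if (length(cross)) {
    refr <- p$refractory
    last <- -Inf
    keep <- logical(length(cross))
    for (k in seq_along(cross)) {
      tk <- time_ms[cross[k]]
      if (tk - last >= refr) {
        keep[k] <- TRUE
        last <- tk
      }
    }
    cross <- cross[keep]
    spike_times <- time_ms[cross]
    nsp <- ceiling(3 / dt)
    shape <- spike_shape(nsp, dt)
    for (ci in cross) {
      idx <- ci + seq_len(min(nsp, n - ci))
      vm[idx] <- vm[idx] + shape[seq_along(idx)]
    }
  }

  structure(
    list(vm = vm, spike_times = spike_times, time_ms = time_ms, fs = fs,
         condition = seq$condition, configuration = seq$configuration,
         trajectory = seq$trajectory, speed_fraction = seq$speed_fraction,
         seed = as.integer(seed)),
    class = "trial_recording")
}

#' Generate a full synthetic dataset under a protocol
#'
#' Per-cell generator parameters are drawn from uniform priors; each block
#' presents each entry of the condition set exactly once.  All randomness
#' derives from the master seed through named substreams, and the per-cell
#' parameters and seeds are stored with the dataset.
#'
#' @param protocol a `protocol_spec`, or a function `function(rf)` returning
#'   one (to let RF geometry vary across cells).
#' @param n_cells,n_blocks counts.
#' @param param_priors named list of length-2 numeric ranges for
#'   [generator_params()] fields, sampled uniformly per cell (e.g.
#'   `list(ashp_true = c(0.1, 0.3))`); unlisted fields keep their defaults.
#' @param rf_list optional list of [rf_geometry()] per cell; defaults to the
#'   protocol's RF for every cell.
#' @param seed master seed.
#' @param fs,pre_ms,pad_ms forwarded to [simulate_trial()].
#' @return An object of class `lf_dataset`: `cells` (list of
#'   `list(rf, params)`), `recordings` (named list of `trial_recording`),
#'   `index` (data frame), `protocol`, `master_seed`.
#' @export
generate_dataset <- function(protocol, n_cells = 1L, n_blocks = 2L,
                             param_priors = list(), rf_list = NULL,
                             seed = 1L, fs = 10000, pre_ms = 100,
                             pad_ms = 300) {
  proto_fn <- if (is.function(protocol)) protocol else function(rf) protocol
  base_rf <- if (is.function(protocol)) NULL else protocol$rf
  cells <- vector("list", n_cells)
  recordings <- list()
  idx <- list()
  for (ci in seq_len(n_cells)) {
    rf <- if (!is.null(rf_list)) rf_list[[ci]] else base_rf
    proto <- proto_fn(rf)
    if (is.null(rf)) rf <- proto$rf
    args <- list()
    for (nm in names(param_priors)) {
      rng <- param_priors[[nm]]
      set.seed(derive_seed(seed, 1L, ci, match(nm, names(param_priors))))
      args[[nm]] <- stats::runif(1, rng[1], rng[2])
    }
    p <- do.call(generator_params, args)
    p$rng_seed <- derive_seed(seed, 2L, ci)
    cells[[ci]] <- list(rf = rf, params = p, protocol = proto)
    for (b in seq_len(n_blocks)) {
      ord <- block_order(proto, b)
      for (t in seq_along(ord)) {
        e <- ord[t]
        sq <- proto$condition_set[[e]]
        tr <- simulate_trial(sq, rf, p,
                             seed = derive_seed(seed, 3L, ci, b, e),
                             fs = fs, pre_ms = pre_ms, pad_ms = pad_ms)
        key <- sprintf("cell%03d_block%03d_entry%03d", ci, b, e)
        recordings[[key]] <- tr
        idx[[length(idx) + 1]] <- data.frame(
          key = key, cell = ci, block = b, entry = e,
          condition = sq$condition, configuration = sq$configuration,
          trajectory = sq$trajectory, stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(cells = cells, recordings = recordings,
         index = do.call(rbind, idx), master_seed = as.integer(seed),
         fs = fs, pre_ms = pre_ms, pad_ms = pad_ms),
    class = "lf_dataset")
}

#' Retrieve trials of a dataset matching labels
#'
#' @param dataset an `lf_dataset`.
#' @param cell cell id.
#' @param condition,configuration,trajectory optional filters.
#' @return list of `trial_recording`.
#' @export
dataset_trials <- function(dataset, cell, condition = NULL,
                           configuration = NULL, trajectory = NULL) {
  ix <- dataset$index
  sel <- ix$cell == cell
  if (!is.null(condition)) sel <- sel & ix$condition %in% condition
  if (!is.null(configuration)) sel <- sel & ix$configuration %in% configuration
  if (!is.null(trajectory)) sel <- sel & ix$trajectory %in% trajectory
  dataset$recordings[ix$key[sel]]
}
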