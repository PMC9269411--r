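## Raw-trial conditioning: spike removal by alpha-function splicing,
## band-pass filtering, down-sampling, smoothing, and trial averaging into
## PSTWs / PSTHs.

#' Alpha function used to replace spike waveforms
#'
#' `alpha(t) = a * t * exp(-t / tau)`; peaks at `t = tau` with value
#' `a * tau / e`.
#'
#' @param t_ms time from splice onset, ms (vectorized; zero for `t < 0`).
#' @param a slope parameter (mV/ms), taken at the peak of the second
#'   derivative of the spike's rising phase.
#' @param tau spike half-width, ms.
#' @return alpha-function values, mV.
#' @export
alpha_function <- function(t_ms, a, tau) {
  out <- numeric(length(t_ms))
  pos <- t_ms > 0
  out[pos] <- a * t_ms[pos] * exp(-t_ms[pos] / tau)
  out
}

#' Detect spikes on a raw trace
#'
#' Upward crossings of a dV/dt criterion (default) or an absolute voltage
#' threshold, with a minimum inter-spike separation.
#'
#' @param vm raw trace, mV.
#' @param fs sampling rate, Hz.
#' @param rule `"dvdt"` or `"absolute"`.
#' @param threshold mV/ms for `"dvdt"`, mV for `"absolute"`.
#' @param min_isi_ms minimum separation between detections.
#' @return sample indices of spike detections.
#' @export
detect_spikes <- function(vm, fs, rule = c("dvdt", "absolute"),
                          threshold = if (match.arg(rule) == "dvdt") 10
                                      else -20,
                          min_isi_ms = 2) {
  rule <- match.arg(rule)
  crit <- if (rule == "dvdt") {
    dv <- c(0, diff(vm)) * fs / 1000
    dv >= threshold
  } else {
    vm >= threshold
  }
  n <- length(vm)
  cross <- which(crit & !c(FALSE, crit[-n]))
  if (length(cross) < 2) return(cross)
  min_gap <- min_isi_ms * fs / 1000
  keep <- c(TRUE, diff(cross) >= min_gap)
  cross[keep]
}

#' Remove spikes from a membrane-potential trace
#'
#' Each spike waveform is excised and replaced by an alpha function
#' `a * t * exp(-t / tau)`, where `a` is the slope at the peak of the second
#' derivative of the rising phase and `tau` the spike half-width, spliced
#' continuously onto the trace with a linear blend at the closing boundary.
#' Spikes closer than `tau` are merged into one replacement (with a
#' warning).
#'
#' @param vm raw trace, mV.
#' @param fs sampling rate, Hz.
#' @param spike_idx sample indices of spikes; detected with
#'   [detect_spikes()] when `NULL`.
#' @param max_width_ms longest excision per spike, ms.
#' @param blend_ms length of the closing linear blend, ms.
#' @return the despiked trace, with attribute `"splices"`: a data frame of
#'   per-spike `onset_idx`, `end_idx`, `a`, `tau`.
#' @export
remove_spikes <- function(vm, fs, spike_idx = NULL, max_width_ms = 5,
                          blend_ms = 1) {
  if (is.null(spike_idx)) spike_idx <- detect_spikes(vm, fs)
  if (length(spike_idx) == 0) {
    attr(vm, "splices") <- data.frame(onset_idx = integer(0),
                                      end_idx = integer(0),
                                      a = numeric(0), tau = numeric(0))
    return(vm)
  }
  dt <- 1000 / fs
  n <- length(vm)
  back <- round(1.5 / dt)          # search window before detection
  fwd <- round(max_width_ms / dt)

  wins <- lapply(spike_idx, function(si) {
    i0 <- max(1L, si - back)
    seg <- vm[i0:min(n, si + fwd)]
    pk_rel <- which.max(seg)
    pk <- i0 + pk_rel - 1L
    ## onset: spike foot, the last near-minimal sample before the peak
    pre <- vm[i0:pk]
    foot <- which(pre <= min(pre) + 0.1)
    onset <- i0 + max(foot[foot < pk - i0 + 1L]) - 1L
    ## end: return towards pre-spike level after the peak
    base <- vm[onset]
    amp0 <- vm[pk] - base
    post <- vm[pk:min(n, onset + fwd)]
    ret <- which(post <= base + 0.05 * amp0)
    end <- if (length(ret)) pk + ret[1] - 1L else min(n, onset + fwd)
    amp <- vm[pk] - base
    half <- which(vm[onset:end] - base >= amp / 2)
    tau <- max(length(half) * dt, dt)
    ## a: slope at the peak of the second derivative of the rising phase
    rise <- vm[onset:pk]
    a <- if (length(rise) >= 3) {
      d2 <- diff(diff(rise))
      j <- which.max(d2) + 1L
      (rise[min(j + 1L, length(rise))] - rise[max(j - 1L, 1L)]) / (2 * dt)
    } else amp / max(tau, dt)
    list(onset = onset, end = end, a = a, tau = tau)
  })

  ## merge replacements whose windows overlap or are closer than tau
  merged <- list(wins[[1]])
  for (w in wins[-1]) {
    last <- merged[[length(merged)]]
    if (w$onset <= last$end + last$tau / dt) {
      warning("overlapping spikes merged into a single replacement",
              call. = FALSE)
      last$end <- max(last$end, w$end)
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1]] <- w
    }
  }

  out <- vm
  nb <- max(1L, round(blend_ms / dt))
  for (w in merged) {
    idx <- w$onset:w$end
    t_rel <- (seq_along(idx) - 1) * dt
    repl <- vm[w$onset] + alpha_function(t_rel, w$a, w$tau)
    ## close the splice: linear blend onto the recorded trace
    m <- length(idx)
    bl <- min(nb, m)
    wgt <- seq(0, 1, length.out = bl)
    tail_idx <- (m - bl + 1):m
    repl[tail_idx] <- (1 - wgt) * repl[tail_idx] + wgt * vm[idx[tail_idx]]
    out[idx] <- repl
  }
  attr(out, "splices") <- data.frame(
    onset_idx = as.integer(vapply(merged, `[[`, 0, "onset")),
    end_idx = as.integer(vapply(merged, `[[`, 0, "end")),
    a = vapply(merged, `[[`, 0, "a"),
    tau = vapply(merged, `[[`, 0, "tau"))
  out
}

#' Band-pass filter, down-sample and smooth a trace
#'
#' Zero-phase (forward-backward) low-pass filtering at 300 Hz, decimation
#' to 1 kHz, then a 7 ms sliding-average window.  Zero-phase realization is
#' used so that latency measurements downstream are not biased by filter
#' delay.  A 0.1 Hz high-pass branch is available for long continuous
#' recordings but is off by default: on sub-second trial epochs the sub-Hz
#' edge is below the resolvable frequency and a zero-phase realization
#' removes a length-dependent fraction of the DC level, which would corrupt
#' blank subtraction across entries of different durations; slow drifts
#' common to blanks and stimulations are instead removed by the blank
#' subtraction itself.
#'
#' @param x raw trace.
#' @param fs_in input sampling rate, Hz (>= 2 kHz).
#' @param fs_out output rate, Hz (must divide `fs_in`).
#' @param lowpass_hz,highpass_hz band edges, Hz.
#' @param smooth_ms sliding-average width, ms.
#' @param order Butterworth order of the low-pass branch.
#' @return trace at `fs_out`.
#' @export
condition_trace <- function(x, fs_in, fs_out = 1000, lowpass_hz = 300,
                            highpass_hz = NULL, smooth_ms = 7, order = 4) {
  if (fs_in < 2000) stop("condition_trace expects fs_in >= 2 kHz",
                         call. = FALSE)
  if (fs_in %% fs_out != 0) stop("fs_out must divide fs_in", call. = FALSE)
  if (length(x) < 3 * (order + 1) * fs_in / lowpass_hz) {
    stop("trace shorter than filter warm-up", call. = FALSE)
  }
  ## odd-reflection padding suppresses filtfilt edge transients
  n <- length(x)
  np <- min(n - 1, round(3 * fs_in / lowpass_hz) * (order + 1))
  pad <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  lp <- signal::butter(order, lowpass_hz / (fs_in / 2), type = "low")
  y <- signal::filtfilt(lp, pad)
  if (!is.null(highpass_hz) && highpass_hz > 0) {
    hp <- signal::butter(1, highpass_hz / (fs_in / 2), type = "high")
    y <- signal::filtfilt(hp, y)
  }
  y <- y[(np + 1):(np + n)]
  dec <- fs_in / fs_out
  y <- y[seq(1, length(y), by = dec)]
  moving_average(y, max(1L, round(smooth_ms * fs_out / 1000)))
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  pad <- c(rep(x[1], k), x, rep(x[n], k))
  sm <- stats::filter(pad, rep(1 / k, k), sides = 2)
  as.numeric(sm[(k + 1):(k + n)])
}

#' Condition all trials of an entry into a trial matrix
#'
#' Applies [remove_spikes()] and [condition_trace()] to each trial and
#' stacks the conditioned traces.
#'
#' @param trials list of `trial_recording`.
#' @param despike logical; remove spikes first.
#' @param ... forwarded to [condition_trace()].
#' @return list with `time_ms` (1 kHz), `vm` (trials x time matrix),
#'   `spikes` (list of spike-time vectors).
#' @export
condition_trials <- function(trials, despike = TRUE, ...) {
  stopifnot(length(trials) >= 1)
  fs <- trials[[1]]$fs
  rows <- lapply(trials, function(tr) {
    x <- tr$vm
    if (despike && length(tr$spike_times)) {
      idx <- findInterval(tr$spike_times, tr$time_ms)
      x <- remove_spikes(x, fs, spike_idx = idx)
    }
    condition_trace(x, fs_in = fs, ...)
  })
  len <- unique(vapply(rows, length, 0L))
  if (length(len) != 1) stop("trials have mismatched lengths",
                             call. = FALSE)
  dec <- fs / 1000
  time_ms <- trials[[1]]$time_ms[seq(1, length(trials[[1]]$time_ms),
                                     by = dec)]
  list(time_ms = time_ms[seq_len(len)],
       vm = do.call(rbind, rows),
       spikes = lapply(trials, `[[`, "spike_times"))
}

#' Peristimulus-triggered waveform (PSTW): mean and SEM across trials
#'
#' @param vm trials x time matrix of conditioned traces (mV).
#' @param time_ms common time base, ms.
#' @param block_mean optional per-block mean activity (scalar or vector) to
#'   subtract, as when the mean of all conditions of a block is removed.
#' @return a [response_waveform()] of kind `"PSTW"`.
#' @export
build_pstw <- function(vm, time_ms, block_mean = NULL) {
  if (is.list(vm) && !is.matrix(vm)) vm <- do.call(rbind, vm)
  stopifnot(ncol(vm) == length(time_ms))
  if (!is.null(block_mean)) vm <- sweep(vm, 2, block_mean)
  m <- colMeans(vm)
  s <- if (nrow(vm) > 1) apply(vm, 2, stats::sd) / sqrt(nrow(vm))
       else rep(0, ncol(vm))
  response_waveform(time_ms, m, s, nrow(vm), "PSTW")
}

#' Peristimulus time histogram (PSTH) with Gaussian smoothing
#'
#' Spike trains are binned on the output time base and smoothed with a
#' Gaussian window (sigma = 3 ms by default); the rate is in spikes/s and
#' the time integral per trial equals the mean spike count.
#'
#' @param spike_trains list of spike-time vectors, ms.
#' @param time_ms output time base (1 kHz), ms.
#' @param sigma_ms Gaussian smoothing s.d., ms.
#' @param block_mean optional mean rate to subtract.
#' @return a [response_waveform()] of kind `"PSTH"` (spikes/s).
#' @export
build_psth <- function(spike_trains, time_ms, sigma_ms = 3,
                       block_mean = NULL) {
  stopifnot(length(spike_trains) >= 1)
  dt <- stats::median(diff(time_ms))
  breaks <- c(time_ms - dt / 2, max(time_ms) + dt / 2)
  rate <- vapply(spike_trains, function(st) {
    h <- graphics::hist(st[st >= breaks[1] & st <= breaks[length(breaks)]],
                        breaks = breaks, plot = FALSE)$counts
    h / (dt / 1000)
  }, numeric(length(time_ms)))
  rate <- t(rate)
  ## Gaussian smoothing, kernel normalized to unit mass
  half <- ceiling(4 * sigma_ms / dt)
  kt <- (-half:half) * dt
  kern <- exp(-kt^2 / (2 * sigma_ms^2))
  kern <- kern / sum(kern)
  sm <- t(apply(rate, 1, function(r) {
    pad <- c(rep(0, half), r, rep(0, half))
    as.numeric(stats::filter(pad, kern, sides = 2))[(half + 1):(half + length(r))]
  }))
  if (!is.null(block_mean)) sm <- sweep(sm, 2, block_mean)
  m <- colMeans(sm)
  s <- if (nrow(sm) > 1) apply(sm, 2, stats::sd) / sqrt(nrow(sm))
       else rep(0, ncol(sm))
  response_waveform(time_ms, m, s, nrow(sm), "PSTH")
}

#' Point-by-point blank subtraction
#'
#' Subtracts the blank (ongoing-activity) waveform from an evoked waveform
#' on the same time base, so that significance envelopes are centered on
#' zero (and spike rates can go negative).
#'
#' @param resp,blank [response_waveform()]s on the same time base.
#' @return the blank-subtracted `response_waveform`.
#' @export
subtract_blank <- function(resp, blank) {
  check_same_timebase(resp, blank)
  response_waveform(resp$time_ms, resp$mean - blank$mean, resp$sem,
                    resp$n_trials, resp$kind)
}

#' Subtract a blank mean from every row of a trial matrix
#' @param vm trials x time matrix.
#' @param blank_mean vector (time) or scalar.
#' @return matrix of blank-subtracted trials.
#' @export
subtract_blank_trials <- function(vm, blank_mean) {
  sweep(vm, 2, blank_mean)
}
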