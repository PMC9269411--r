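## Shared helpers: seed derivation, run-length masking, waveform container.

#' Derive a reproducible substream seed
#'
#' Mixes a master seed with integer labels (e.g. cell, block, entry) into a
#' new seed below 2^31, so every stochastic stage of a run draws from its own
#' named substream of the master seed.
#'
#' @param master integer master seed.
#' @param ... integer labels.
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  labs <- c(as.numeric(master), as.numeric(unlist(list(...))))
  h <- 0
  for (v in labs) {
    h <- (h * 1000003 + (v %% 2147483647) + 12345) %% 2147483563
  }
  as.integer(h + 1)
}

#' Keep only runs of TRUE of at least a minimum length
#' @param mask logical vector.
#' @param min_len minimum run length in samples.
#' @return logical vector with short runs removed.
#' @keywords internal
filter_runs <- function(mask, min_len) {
  if (min_len <= 1) return(mask)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}

#' Trial-averaged response waveform
#'
#' Container for a peristimulus-triggered waveform (PSTW, mV) or histogram
#' (PSTH, spikes/s): a common time base, the across-trial mean and SEM.
#'
#' @param time_ms time base in ms.
#' @param mean across-trial mean (mV or spikes/s).
#' @param sem standard error of the mean, same length.
#' @param n_trials number of trials averaged.
#' @param kind `"PSTW"` or `"PSTH"`.
#' @return An object of class `response_waveform`.
#' @export
response_waveform <- function(time_ms, mean, sem = rep(0, length(mean)),
                              n_trials = 1L, kind = "PSTW") {
  stopifnot(length(time_ms) == length(mean), length(sem) == length(mean),
            n_trials >= 1)
  structure(list(time_ms = as.numeric(time_ms), mean = as.numeric(mean),
                 sem = as.numeric(sem), n_trials = as.integer(n_trials),
                 kind = kind),
            class = "response_waveform")
}

#' @export
print.response_waveform <- function(x, ...) {
  cat(sprintf("%s: %d samples (%.1f..%.1f ms), n = %d trials, peak %.3g\n",
              x$kind, length(x$time_ms), min(x$time_ms), max(x$time_ms),
              x$n_trials, max(x$mean)))
  invisible(x)
}

check_same_timebase <- function(a, b) {
  if (length(a$time_ms) != length(b$time_ms) ||
      max(abs(a$time_ms - b$time_ms)) > 1e-9) {
    stop("waveforms are not on the same time base", call. = FALSE)
  }
  invisible(TRUE)
}

#' Restrict a waveform (or matrix of trials) to a time window
#' @keywords internal
window_index <- function(time_ms, window) {
  if (window[1] < min(time_ms) - 1e-9 || window[2] > max(time_ms) + 1e-9) {
    stop("analysis window [", window[1], ", ", window[2],
         "] ms lies outside the trace", call. = FALSE)
  }
  which(time_ms >= window[1] - 1e-9 & time_ms <= window[2] + 1e-9)
}
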