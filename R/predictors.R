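## Linear predictors of the Surround contribution and detection of dynamic
## non-linearities.

#' Surround linear predictor (SLP)
#'
#' Sum of the temporally shifted responses to each Gabor patch (or ring)
#' flashed in isolation, reproducing the spatial and temporal ordering of a
#' virtual apparent-motion sequence.  Isolated responses are expected to be
#' blank-subtracted so baselines do not accumulate across the sum; shifts
#' are zero-padded outside the recorded window.
#'
#' @param isolated named list of [response_waveform()], one per node label
#'   (time 0 = isolated stroke onset).
#' @param chronogram an `am_sequence` whose surround strokes define the
#'   shifts (node `D0` strokes are ignored).
#' @param time_ms output time base, ms (0 = sequence start); defaults to the
#'   first isolated response's base.
#' @return a [response_waveform()] with attribute `"provenance"` (data frame
#'   of node labels and shifts).
#' @export
surround_linear_predictor <- function(isolated, chronogram,
                                      time_ms = NULL) {
  ev <- chronogram$events
  ev <- ev[ev$node_label != "D0", , drop = FALSE]
  strokes <- ev[!duplicated(ev$stroke_index), , drop = FALSE]
  missing <- setdiff(unique(strokes$node_label), names(isolated))
  if (length(missing)) {
    stop("missing isolated responses for node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(time_ms)) time_ms <- isolated[[1]]$time_ms
  out <- numeric(length(time_ms))
  for (k in seq_len(nrow(strokes))) {
    r <- isolated[[strokes$node_label[k]]]
    shifted <- stats::approx(r$time_ms + strokes$onset_ms[k], r$mean,
                             xout = time_ms, rule = 1)$y
    shifted[is.na(shifted)] <- 0
    out <- out + shifted
  }
  w <- response_waveform(time_ms, out, kind = "PSTW")
  attr(w, "provenance") <- data.frame(node_label = strokes$node_label,
                                      shift_ms = strokes$onset_ms)
  w
}

#' Center-subtraction predictor of the Surround component
#'
#' Predicted Surround contribution obtained by subtracting the Center-Only
#' response from the complete "Surround-then-Center" response, pointwise.
#'
#' @param full_resp,center_only_resp [response_waveform()]s on the same time
#'   base.
#' @return a [response_waveform()].
#' @export
center_subtraction_predictor <- function(full_resp, center_only_resp) {
  check_same_timebase(full_resp, center_only_resp)
  w <- response_waveform(full_resp$time_ms,
                         full_resp$mean - center_only_resp$mean,
                         kind = full_resp$kind)
  attr(w, "provenance") <- "surround_then_center - center_only"
  w
}

#' Virtual trials of the Surround linear predictor
#'
#' Pairs one isolated trial per node (without replacement while the pool
#' lasts, so virtual trials are independent), shifts each by the chronogram
#' onset and sums, yielding trial-level realizations of the linear predictor
#' that carry the isolated responses' estimation noise.
#'
#' @param isolated_trials named list, one element per node label, each a
#'   list with `time_ms` and `vm` (trials x time matrix, blank-subtracted).
#' @param chronogram an `am_sequence`.
#' @param time_ms output time base.
#' @param n_virtual number of virtual trials.
#' @param seed integer seed.
#' @return matrix `n_virtual` x `length(time_ms)`.
#' @export
slp_virtual_trials <- function(isolated_trials, chronogram, time_ms,
                               n_virtual, seed = 1L) {
  ev <- chronogram$events
  ev <- ev[ev$node_label != "D0", , drop = FALSE]
  strokes <- ev[!duplicated(ev$stroke_index), , drop = FALSE]
  missing <- setdiff(unique(strokes$node_label), names(isolated_trials))
  if (length(missing)) {
    stop("missing isolated trials for node(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- matrix(0, n_virtual, length(time_ms))
  for (k in seq_len(nrow(strokes))) {
    it <- isolated_trials[[strokes$node_label[k]]]
    pick <- sample.int(nrow(it$vm), n_virtual,
                       replace = n_virtual > nrow(it$vm))
    for (j in seq_len(n_virtual)) {
      shifted <- stats::approx(it$time_ms + strokes$onset_ms[k],
                               it$vm[pick[j], ], xout = time_ms,
                               rule = 1)$y
      shifted[is.na(shifted)] <- 0
      out[j, ] <- out[j, ] + shifted
    }
  }
  out
}

#' Test a Surround-Only response against its linear predictor
#'
#' A dynamic non-linearity is declared when the observed Surround-Only mean
#' exceeds the upper permutation bound around the linear predictor for at
#' least `min_consecutive_ms` consecutive milliseconds in the analysis
#' window (one-sample sign-randomization of the trial residuals).
#'
#' When `slp` is a waveform the test is one-sample (sign-randomization of
#' observed-minus-predictor residuals) and treats the predictor as exact;
#' when `slp` is a matrix of [slp_virtual_trials()] the test is the
#' two-sample [permutation_envelope()], which also carries the predictor's
#' estimation noise and is the calibrated default for recorded-style data.
#'
#' @param observed_trials trials x time matrix of blank-subtracted
#'   Surround-Only trials.
#' @param slp the [surround_linear_predictor()] waveform on the same base,
#'   or a matrix of virtual predictor trials.
#' @param time_ms time base, ms.
#' @param window analysis window, ms (default 0-120).
#' @param n_perm permutations.
#' @param alpha level.
#' @param min_consecutive_ms duration criterion (default 7 ms).
#' @param seed integer seed.
#' @return list with `significant`, `mask`, `upper`, `time_ms`, `excess`
#'   (observed minus predictor).
#' @export
nonlinearity_test <- function(observed_trials, slp, time_ms,
                              window = c(0, 120), n_perm = 10000L,
                              alpha = 0.05, min_consecutive_ms = 7,
                              seed = 1L) {
  observed_trials <- as.matrix(observed_trials)
  stopifnot(ncol(observed_trials) == length(time_ms))
  wi <- window_index(time_ms, window)
  if (is.matrix(slp)) {
    env <- permutation_envelope(observed_trials[, wi, drop = FALSE],
                                slp[, wi, drop = FALSE], time_ms[wi],
                                n_perm = n_perm, alpha = alpha,
                                min_consecutive_ms = min_consecutive_ms,
                                seed = seed, calibrate_duration = TRUE)
    return(list(significant = any(env$mask), mask = env$mask,
                upper = env$upper, time_ms = time_ms[wi],
                excess = env$observed, alpha = alpha,
                min_consecutive_ms = min_consecutive_ms))
  }
  resid <- sweep(observed_trials[, wi, drop = FALSE], 2, slp$mean[wi])
  n <- nrow(resid)
  if (1 / n_perm > alpha) {
    stop("n_perm too small for alpha", call. = FALSE)
  }
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  null <- (signs %*% resid) / n
  upper <- apply(null, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  excess <- colMeans(resid)
  dt <- stats::median(diff(time_ms))
  mask <- filter_runs(excess > upper,
                      max(1L, round(min_consecutive_ms / dt)))
  list(significant = any(mask), mask = mask, upper = upper,
       time_ms = time_ms[wi], excess = excess, alpha = alpha,
       min_consecutive_ms = min_consecutive_ms)
}
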