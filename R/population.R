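## Population-level normalization, realignment and averaging; speed-tuning
## summaries.

#' Normalize and realign per-cell waveforms for population averaging
#'
#' Each cell's waveform is divided by the peak of its Center-Only response,
#' then shifted in time so that the Center-Only onset (first departure from
#' the blank mean by more than 3 blank s.d.) sits at relative time 0.  Cells
#' with a non-positive Center-Only peak or an undefined onset are excluded
#' (and listed).  All waveforms are resampled on a common 1 kHz relative
#' time base cropped to the intersection window.
#'
#' @param cell_waveforms list of [response_waveform()], one per cell (the
#'   condition under study).
#' @param center_only_waveforms list of the cells' Center-Only
#'   [response_waveform()]s.
#' @param blank_stats list of per-cell `list(mean, sd)` blank statistics.
#' @param peak_window window in which the Center-Only peak and onset are
#'   searched, ms.
#' @return An object of class `aligned_population`: `rel_time_ms`,
#'   `waveforms` (cells x time matrix), `onsets_ms`, `peaks`, `n_cells`,
#'   `excluded` (indices).
#' @export
normalize_and_realign <- function(cell_waveforms, center_only_waveforms,
                                  blank_stats, peak_window = c(0, 250)) {
  stopifnot(length(cell_waveforms) == length(center_only_waveforms),
            length(cell_waveforms) == length(blank_stats))
  n <- length(cell_waveforms)
  onsets <- peaks <- rep(NA_real_, n)
  shifted <- vector("list", n)
  for (i in seq_len(n)) {
    ctr <- center_only_waveforms[[i]]
    wi <- window_index(ctr$time_ms, peak_window)
    peaks[i] <- max(ctr$mean[wi])
    if (!is.finite(peaks[i]) || peaks[i] <= 0) next
    onsets[i] <- onset_latency(ctr, "three_sigma",
                               blank_stats = blank_stats[[i]],
                               window = peak_window)
    if (is.na(onsets[i])) next
    w <- cell_waveforms[[i]]
    shifted[[i]] <- list(time = w$time_ms - onsets[i],
                         y = w$mean / peaks[i])
  }
  keep <- which(!vapply(shifted, is.null, TRUE))
  if (length(keep) == 0) stop("no cell passed normalization/realignment",
                              call. = FALSE)
  lo <- max(vapply(shifted[keep], function(s) min(s$time), 0))
  hi <- min(vapply(shifted[keep], function(s) max(s$time), 0))
  rel_time <- seq(ceiling(lo), floor(hi), by = 1)
  mat <- t(vapply(shifted[keep], function(s) {
    stats::approx(s$time, s$y, xout = rel_time)$y
  }, numeric(length(rel_time))))
  structure(
    list(rel_time_ms = rel_time, waveforms = mat,
         onsets_ms = onsets[keep], peaks = peaks[keep],
         n_cells = length(keep), excluded = setdiff(seq_len(n), keep)),
    class = "aligned_population")
}

#' Population average of an aligned population
#'
#' Pointwise mean and SEM across cells on the common relative time base.
#'
#' @param pop an [normalize_and_realign()] result.
#' @return a [response_waveform()] (normalized units).
#' @export
population_average <- function(pop) {
  m <- colMeans(pop$waveforms)
  s <- if (pop$n_cells > 1) apply(pop$waveforms, 2, stats::sd) /
         sqrt(pop$n_cells) else rep(0, ncol(pop$waveforms))
  response_waveform(pop$rel_time_ms, m, s, pop$n_cells, "PSTW")
}

#' Speed-tuning summary across replay fractions
#'
#' Summarizes the peak contextual amplitude of a response replayed at
#' fractions of its nominal ("optimal") apparent-motion speed.  Cells
#' missing a fraction are excluded from that row; the ordering statistic
#' (whether the full-speed response is maximal) is computed over cells
#' measured at all fractions.
#'
#' @param responses_by_cell list (one element per cell) of named lists of
#'   [response_waveform()]s keyed by speed fraction (`"1"`, `"0.7"`,
#'   `"0.5"`, `"0.3"`).
#' @param fractions numeric fractions expected (default `c(1, 0.7, 0.5,
#'   0.3)`).
#' @param window window in which the contextual peak is measured, ms.
#' @return data frame with one row per fraction: `fraction`, `n_cells`,
#'   `mean_peak`, `sem_peak`; attribute `"full_speed_maximal"` gives the
#'   proportion of complete cells whose peak is maximal at fraction 1.
#' @export
speed_tuning_profile <- function(responses_by_cell,
                                 fractions = c(1, 0.7, 0.5, 0.3),
                                 window = NULL) {
  keys <- as.character(fractions)
  pk <- function(w) {
    y <- w$mean
    if (!is.null(window)) y <- y[window_index(w$time_ms, window)]
    max(y)
  }
  peak_tab <- t(vapply(responses_by_cell, function(cell) {
    vapply(keys, function(k) {
      if (is.null(cell[[k]])) NA_real_ else pk(cell[[k]])
    }, 0)
  }, numeric(length(keys))))
  if (length(responses_by_cell) == 1) {
    peak_tab <- matrix(peak_tab, nrow = 1,
                       dimnames = list(NULL, keys))
  }
  out <- data.frame(
    fraction = fractions,
    n_cells = colSums(is.finite(peak_tab)),
    mean_peak = colMeans(peak_tab, na.rm = TRUE),
    sem_peak = apply(peak_tab, 2, function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    }),
    row.names = NULL)
  complete <- stats::complete.cases(peak_tab)
  attr(out, "full_speed_maximal") <- if (any(complete)) {
    mean(apply(peak_tab[complete, , drop = FALSE], 1,
               function(v) which.max(v) == 1L))
  } else NA_real_
  out
}
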