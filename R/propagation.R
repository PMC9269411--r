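## Horizontal-propagation analyses: latency-basin regression (ASHP), input
## phase, bilinear phase regression, KDE summaries, unit conversions.

#' Fit the latency basin and infer the apparent speed of horizontal
#' propagation (ASHP)
#'
#' Ordinary least squares of Surround-Only onset latency against
#' eccentricity from the RF center.  The slope (ms/degree) converts to a
#' cortical propagation speed through the magnification factor:
#' `ashp = magnification / slope` (mm/ms).  A non-positive slope carries no
#' propagation signature and yields an `NA` ASHP.
#'
#' @param eccentricity degrees (>= 3 distinct values).
#' @param latency onset latencies, ms.
#' @param magnification cortical magnification, mm/degree (default 1, the
#'   value consistent with the printed speed equivalences for cat area 17).
#' @return An object of class `ashp_fit`: `slope`, `intercept`, `ashp`,
#'   `r2`, `magnification`, `points`.
#' @export
fit_latency_basin <- function(eccentricity, latency, magnification = 1) {
  ok <- is.finite(eccentricity) & is.finite(latency)
  eccentricity <- eccentricity[ok]; latency <- latency[ok]
  if (length(unique(eccentricity)) < 3) {
    stop("fit_latency_basin needs >= 3 distinct eccentricities",
         call. = FALSE)
  }
  fit <- stats::lm(latency ~ eccentricity)
  slope <- unname(stats::coef(fit)[2])
  ashp <- if (is.finite(slope) && slope > 0) magnification / slope
          else NA_real_
  ss_tot <- sum((latency - mean(latency))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         ashp = ashp, r2 = r2,
         magnification = magnification,
         points = data.frame(eccentricity = eccentricity,
                             latency = latency)),
    class = "ashp_fit")
}

#' @export
print.ashp_fit <- function(x, ...) {
  cat(sprintf("latency basin: slope %.3g ms/deg, ASHP %.3g mm/ms, r2 %.3f\n",
              x$slope, x$ashp, x$r2))
  invisible(x)
}

#' Input phase between horizontal and feedforward input waves
#'
#' Onset latencies of the Surround-Only and Center-Only responses, measured
#' after realignment to a common reference (the time at which the center
#' stimulus would have appeared), are subtracted:
#' `phase = center_only_onset - surround_only_onset`, positive when the
#' lateral input leads the feedforward drive.
#'
#' @param surround_only_onset,center_only_onset onset latencies, ms
#'   (vectorized); `NA` onsets propagate.
#' @return phase in ms.
#' @export
input_phase <- function(surround_only_onset, center_only_onset) {
  center_only_onset - surround_only_onset
}

#' Bilinear (two connex segments) regression of latency change on phase
#'
#' Fits a continuous piecewise-linear model with one breakpoint, chosen by
#' exhaustive search over candidate abscissae (observed phases and their
#' midpoints) to maximize explained variance.  Per-segment r-squared and
#' point counts are reported.  With `connex = FALSE` the two half-lines are
#' fitted independently on each side of the best candidate.
#'
#' @param phase input phases, ms.
#' @param delta_latency latency changes, ms (positive = advance).
#' @param connex enforce equality of the two segments at the breakpoint.
#' @return An object of class `bilinear_fit`: `breakpoint`, `left_slope`,
#'   `right_slope`, `value_at_break` (or per-side intercepts), `r2_left`,
#'   `r2_right`, `n_left`, `n_right`, `sse`, `single_segment` flag.
#' @export
fit_bilinear <- function(phase, delta_latency, connex = TRUE) {
  ok <- is.finite(phase) & is.finite(delta_latency)
  x <- phase[ok]; y <- delta_latency[ok]
  if (length(x) < 6) stop("fit_bilinear needs >= 6 points", call. = FALSE)
  xs <- sort(unique(x))
  cand <- sort(unique(c(xs, xs[-length(xs)] + diff(xs) / 2)))
  ## interior candidates only: at least 2 points strictly on each side
  cand <- cand[vapply(cand, function(b) sum(x < b) >= 2 && sum(x > b) >= 2,
                      TRUE)]
  if (length(cand) == 0) {
    fit <- stats::lm(y ~ x)
    return(structure(
      list(breakpoint = NA_real_,
           left_slope = unname(stats::coef(fit)[2]),
           right_slope = unname(stats::coef(fit)[2]),
           value_at_break = NA_real_,
           r2_left = summary(fit)$r.squared,
           r2_right = summary(fit)$r.squared,
           n_left = length(x), n_right = length(x),
           sse = sum(stats::resid(fit)^2), single_segment = TRUE,
           connex = connex),
      class = "bilinear_fit"))
  }
  best <- NULL
  for (b in cand) {
    if (connex) {
      xl <- pmin(x - b, 0); xr <- pmax(x - b, 0)
      fit <- stats::lm(y ~ xl + xr)
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) {
        cf <- stats::coef(fit)
        best <- list(b = b, sse = sse, left = unname(cf[2]),
                     right = unname(cf[3]), v0 = unname(cf[1]),
                     fitted = stats::fitted(fit))
      }
    } else {
      li <- x <= b; ri <- x > b
      fl <- stats::lm(y[li] ~ x[li]); fr <- stats::lm(y[ri] ~ x[ri])
      sse <- sum(stats::resid(fl)^2) + sum(stats::resid(fr)^2)
      if (is.null(best) || sse < best$sse) {
        fitted <- numeric(length(x))
        fitted[li] <- stats::fitted(fl); fitted[ri] <- stats::fitted(fr)
        best <- list(b = b, sse = sse,
                     left = unname(stats::coef(fl)[2]),
                     right = unname(stats::coef(fr)[2]),
                     v0 = NA_real_, fitted = fitted)
      }
    }
  }
  side_r2 <- function(sel) {
    if (sum(sel) < 2) return(NA_real_)
    ss_tot <- sum((y[sel] - mean(y[sel]))^2)
    if (ss_tot == 0) return(1)
    1 - sum((y[sel] - best$fitted[sel])^2) / ss_tot
  }
  li <- x <= best$b
  structure(
    list(breakpoint = best$b, left_slope = best$left,
         right_slope = best$right, value_at_break = best$v0,
         r2_left = side_r2(li), r2_right = side_r2(!li),
         n_left = sum(li), n_right = sum(!li), sse = best$sse,
         single_segment = FALSE, connex = connex),
    class = "bilinear_fit")
}

#' @export
print.bilinear_fit <- function(x, ...) {
  cat(sprintf(paste0("bilinear fit: breakpoint %.2f ms; left slope %.3g ",
                     "(r2 %.3f, n %d); right slope %.3g (r2 %.3f, n %d)\n"),
              x$breakpoint, x$left_slope, x$r2_left, x$n_left,
              x$right_slope, x$r2_right, x$n_right))
  invisible(x)
}

#' Gaussian kernel density estimate
#'
#' Thin wrapper over [stats::density()] with a Gaussian kernel and
#' Silverman's rule-of-thumb bandwidth by default; the returned curve
#' integrates to 1.
#'
#' @param values numeric sample (>= 2 values).
#' @param bandwidth bandwidth or rule name (see [stats::bw.nrd0()]).
#' @return data frame with `x` and `density`.
#' @export
kde_density <- function(values, bandwidth = "nrd0") {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("kde_density needs >= 2 values",
                               call. = FALSE)
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian")
  data.frame(x = d$x, density = d$y)
}

#' Convert a retinal speed to a cortical propagation speed
#'
#' `speed_mm_per_ms = speed_deg_per_s * magnification / 1000`; the inverse
#' mapping is [cortical_to_retinal_speed()].  With the default cat
#' magnification of 1 mm/degree, 150-250 degrees/s correspond to
#' 0.15-0.25 mm/ms.
#'
#' @param deg_per_s retinal speed, degrees/s.
#' @param magnification mm of cortex per degree.
#' @return speed in mm/ms.
#' @export
retinal_to_cortical_speed <- function(deg_per_s, magnification = 1) {
  deg_per_s * magnification / 1000
}

#' @rdname retinal_to_cortical_speed
#' @param mm_per_ms cortical speed, mm/ms.
#' @export
cortical_to_retinal_speed <- function(mm_per_ms, magnification = 1) {
  mm_per_ms * 1000 / magnification
}

#' Scale a retinal speed across species by the magnification-factor ratio
#'
#' A human parafoveal speed maps onto the cat retina through the ratio of
#' retino-cortical magnification factors (about 3 between human and cat), so
#' the human psychophysical optimum of 64 degrees/s corresponds to
#' 192 degrees/s in cat.
#'
#' @param deg_per_s speed in the source species, degrees/s.
#' @param magnification_ratio source-to-target magnification ratio.
#' @return equivalent speed in the target species, degrees/s.
#' @export
species_equivalent_speed <- function(deg_per_s, magnification_ratio = 3) {
  deg_per_s * magnification_ratio
}
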