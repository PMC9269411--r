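#' Receptive-field geometry of a recorded cell
#'
#' Bundles the receptive-field (RF) parameters that anchor all stimulus
#' geometry: the RF center in visual-field coordinates, the preferred
#' orientation, the extents of the minimal discharge field (MDF, the spiking
#' RF) and of the subthreshold depolarizing receptive field (SRF, the broader
#' region where impulse stimuli evoke PSPs without spikes).
#'
#' @param center_position numeric length-2, RF center (x, y) in degrees of
#'   visual angle (x rightward, y upward).
#' @param preferred_orientation degrees in `[0, 180)`.
#' @param mdf_length,mdf_width MDF extent along the preferred-orientation axis
#'   and the width axis, degrees, strictly positive.
#' @param srf_extent SRF extent, degrees; must contain the MDF
#'   (`srf_extent >= max(mdf_length, mdf_width)`).
#' @param eccentricity_from_area_centralis degrees, non-negative.
#' @return An object of class `rf_geometry`.
#' @export
rf_geometry <- function(center_position = c(0, 0),
                        preferred_orientation = 0,
                        mdf_length = 2,
                        mdf_width = 1,
                        srf_extent = 5,
                        eccentricity_from_area_centralis = 5) {
  stopifnot(length(center_position) == 2, is.finite(center_position))
  if (!is.finite(mdf_length) || mdf_length <= 0 ||
      !is.finite(mdf_width) || mdf_width <= 0 ||
      !is.finite(srf_extent) || srf_extent <= 0) {
    stop("invalid RF geometry: all field extents must be strictly positive",
         call. = FALSE)
  }
  if (srf_extent < max(mdf_length, mdf_width)) {
    stop("invalid RF geometry: srf_extent must contain the MDF ",
         "(srf_extent >= max(mdf_length, mdf_width))", call. = FALSE)
  }
  if (eccentricity_from_area_centralis < 0) {
    stop("invalid RF geometry: eccentricity must be >= 0", call. = FALSE)
  }
  structure(
    list(center_position = as.numeric(center_position),
         preferred_orientation = preferred_orientation %% 180,
         mdf_length = mdf_length,
         mdf_width = mdf_width,
         srf_extent = srf_extent,
         eccentricity_from_area_centralis = eccentricity_from_area_centralis),
    class = "rf_geometry")
}

#' Gabor patch specification
#'
#' The local inducer used at every node of an apparent-motion sequence: an
#' oriented sinusoidal grating under a Gaussian envelope, flashed for a fixed
#' duration.
#'
#' @param orientation degrees, measured counterclockwise from the cell's
#'   preferred orientation (so 0 means iso-oriented with the RF).
#' @param spatial_frequency cycles per degree.
#' @param phase degrees.
#' @param contrast Michelson contrast, in `(0, 1]`.
#' @param mask_length patch mask size, degrees.
#' @param envelope_sigma Gaussian envelope s.d., degrees.
#' @param duration_ms flash duration, ms (> 0).
#' @return An object of class `gabor_spec`.
#' @export
gabor_spec <- function(orientation = 0,
                       spatial_frequency = 0.5,
                       phase = 0,
                       contrast = 0.925,
                       mask_length = 3,
                       envelope_sigma = 0.2 * mask_length,
                       duration_ms = 16.6) {
  if (!is.finite(contrast) || contrast <= 0 || contrast > 1) {
    stop("contrast must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(duration_ms) || duration_ms <= 0) {
    stop("duration_ms must be > 0", call. = FALSE)
  }
  structure(
    list(orientation = orientation,
         spatial_frequency = spatial_frequency,
         phase = phase,
         contrast = contrast,
         mask_length = mask_length,
         envelope_sigma = envelope_sigma,
         duration_ms = duration_ms),
    class = "gabor_spec")
}

#' @export
print.rf_geometry <- function(x, ...) {
  cat("RF geometry: center (", x$center_position[1], ",",
      x$center_position[2], ") deg, preferred orientation",
      x$preferred_orientation, "deg\n")
  cat("  MDF", x$mdf_length, "x", x$mdf_width,
      "deg; SRF extent", x$srf_extent, "deg\n")
  invisible(x)
}
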