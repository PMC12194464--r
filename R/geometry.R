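# Detector geometry and the pixel -> momentum-transfer (q) mapping.
#
# Convention: pixel indices are 1-based (row, col) as in R matrices; radial
# distances are computed at pixel centers; the beam center is given in
# fractional 1-based pixel coordinates and may lie outside the detector.

#' Detector geometry for WAXS reduction
#'
#' Bundles the quantities needed to map detector pixels to momentum transfer
#' q: sample-to-detector distance, pixel pitch (square pixels), beam-center
#' position and photon energy. The wavelength is derived from the energy via
#' \eqn{\lambda = hc/E} with \eqn{hc = 1.2398420} keV nm.
#'
#' Defaults correspond to a synchrotron WAXS setup: 12.4 keV monochromatic
#' beam, 170.21 mm calibrated sample-to-detector distance, and the 172 um
#' pixel pitch of a Pilatus-class photon-counting detector.
#'
#' @param distance_mm sample-to-detector distance in mm (> 0).
#' @param pixel_mm pixel pitch in mm (> 0, square pixels).
#' @param beam_center numeric length-2, beam center as fractional (row, col)
#'   pixel coordinates (1-based); may lie outside the detector bounds.
#' @param energy_kev photon energy in keV (> 0).
#' @return an object of class `detector_geometry`: a list with fields
#'   `distance_mm`, `pixel_mm`, `beam_center`, `energy_kev`, `wavelength_nm`.
#' @examples
#' geom <- detector_geometry(beam_center = c(64.5, 64.5))
#' geom$wavelength_nm # ~0.1 nm at 12.4 keV
#' @export
detector_geometry <- function(distance_mm = 170.21, pixel_mm = 0.172,
                              beam_center = c(0.5, 0.5), energy_kev = 12.4) {
  stop_if_not_scalar_pos(distance_mm, "distance_mm")
  stop_if_not_scalar_pos(pixel_mm, "pixel_mm")
  stop_if_not_scalar_pos(energy_kev, "energy_kev")
  if (!is.numeric(beam_center) || length(beam_center) != 2L ||
      !all(is.finite(beam_center)))
    stop("`beam_center` must be two finite numbers (row, col)", call. = FALSE)
  structure(list(distance_mm = distance_mm,
                 pixel_mm = pixel_mm,
                 beam_center = as.numeric(beam_center),
                 energy_kev = energy_kev,
                 wavelength_nm = energy_to_wavelength(energy_kev)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("<detector_geometry>\n")
  cat(sprintf("  distance   : %.4g mm\n", x$distance_mm))
  cat(sprintf("  pixel pitch: %.4g mm\n", x$pixel_mm))
  cat(sprintf("  beam center: (%.3f, %.3f) px\n",
              x$beam_center[1], x$beam_center[2]))
  cat(sprintf("  energy     : %.4g keV (lambda = %.6g nm)\n",
              x$energy_kev, x$wavelength_nm))
  invisible(x)
}

#' Convert photon energy to wavelength
#'
#' \eqn{\lambda = hc/E} with \eqn{hc = 1.2398420} keV nm.
#'
#' @param energy_kev photon energy in keV (> 0); vectorized.
#' @return wavelength in nm.
#' @examples
#' energy_to_wavelength(12.4)
#' @export
energy_to_wavelength <- function(energy_kev) {
  if (!is.numeric(energy_kev) || any(!is.finite(energy_kev)) ||
      any(energy_kev <= 0))
    stop("`energy_kev` must be positive and finite", call. = FALSE)
  1.2398420 / energy_kev
}

#' Map radial detector distance to momentum transfer q
#'
#' For a pixel at radial distance r from the beam center, the scattering
#' angle satisfies \eqn{\tan 2\theta = r / L} (L the sample-to-detector
#' distance) and \eqn{q = 4\pi \sin\theta / \lambda}. Strictly increasing
#' in r.
#'
#' @param radial_mm radial distance(s) from beam center in mm (>= 0).
#' @param geometry a [detector_geometry()].
#' @return q in inverse nm, same length as `radial_mm`.
#' @seealso [q_to_pixel()] for the inverse mapping.
#' @examples
#' pixel_to_q(17.021, detector_geometry())
#' @export
pixel_to_q <- function(radial_mm, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (any(radial_mm < 0, na.rm = TRUE))
    stop("radial distance must be non-negative", call. = FALSE)
  two_theta <- atan(radial_mm / geometry$distance_mm)
  4 * pi * sin(two_theta / 2) / geometry$wavelength_nm
}

#' Map momentum transfer q back to radial detector distance
#'
#' Inverse of [pixel_to_q()]: \eqn{r = L \tan(2 \arcsin(q\lambda/4\pi))}.
#'
#' @param q momentum transfer in inverse nm (>= 0, below the back-scattering
#'   limit).
#' @param geometry a [detector_geometry()].
#' @return radial distance in mm.
#' @export
q_to_pixel <- function(q, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (any(q < 0, na.rm = TRUE)) stop("q must be non-negative", call. = FALSE)
  s <- q * geometry$wavelength_nm / (4 * pi)
  if (any(s >= sin(pi / 4), na.rm = TRUE))
    stop("q beyond the forward-scattering range of a flat detector",
         call. = FALSE)
  geometry$distance_mm * tan(2 * asin(s))
}

# Radial distance (mm) of every pixel center of an nr x nc detector from the
# beam center; returns a matrix.
pixel_radii_mm <- function(shape, geometry) {
  nr <- shape[1]; nc <- shape[2]
  dr <- (seq_len(nr) - geometry$beam_center[1])
  dc <- (seq_len(nc) - geometry$beam_center[2])
  geometry$pixel_mm * sqrt(outer(dr^2, dc^2, `+`))
}

# q (inverse nm) of every pixel center; matrix of same shape.
pixel_q_map <- function(shape, geometry) {
  r <- pixel_radii_mm(shape, geometry)
  q <- pixel_to_q(as.vector(r), geometry)
  matrix(q, nrow = shape[1], ncol = shape[2])
}
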