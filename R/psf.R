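#' Gaussian illumination profile of the microscope
#'
#' Constructs the point-spread-function model used throughout the package: a
#' two-dimensional Gaussian beam profile \eqn{g(r) = \exp(-2 r^2/\omega_0^2)}
#' evaluated in the focal (membrane) plane, where \eqn{\omega_0} is the radius
#' at which the profile falls to \eqn{e^{-2}} of its peak. The axial dimension
#' is collapsed because the samples of interest are two-dimensional membranes.
#'
#' The beam area is defined as the integral of the peak-normalized profile
#' over the plane, \eqn{BA = \int g \, dA = \pi \omega_0^2 / 2}. With this
#' convention a field of point emitters of per-entity brightness \eqn{\epsilon}
#' and density \eqn{N} entities per beam area has mean pixel intensity exactly
#' \eqn{\langle I \rangle = N \epsilon}.
#'
#' @param e2_radius Beam \eqn{e^{-2}} radius \eqn{\omega_0} in micrometres.
#' @param pixel_size Image pixel size in micrometres. Must be smaller than
#'   `e2_radius`: the analysis requires an oversampled PSF.
#' @return An object of class `psf_model` with elements `e2_radius`,
#'   `pixel_size` and the derived `beam_area` (\eqn{\mu m^2}).
#' @examples
#' psf <- psf_model(e2_radius = 0.2, pixel_size = 0.046)
#' psf$beam_area            # pi * 0.2^2 / 2
#' shape_factor(psf, 2)     # 1/2 for the 2D Gaussian
#' @export
psf_model <- function(e2_radius, pixel_size) {
  if (!is.numeric(e2_radius) || length(e2_radius) != 1L || e2_radius <= 0)
    stop_invalid("`e2_radius` must be a single positive number (micrometres)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_invalid("`pixel_size` must be a single positive number (micrometres)")
  if (pixel_size >= e2_radius)
    stop_invalid("`pixel_size` must be smaller than `e2_radius`: ",
                 "the PSF must be oversampled")
  structure(
    list(e2_radius = e2_radius,
         pixel_size = pixel_size,
         beam_area = pi * e2_radius^2 / 2),
    class = "psf_model"
  )
}

#' @export
print.psf_model <- function(x, ...) {
  cat("Gaussian PSF model\n")
  cat(sprintf("  e^-2 radius (omega0): %.4g um\n", x$e2_radius))
  cat(sprintf("  pixel size:           %.4g um\n", x$pixel_size))
  cat(sprintf("  beam area:            %.4g um^2\n", x$beam_area))
  invisible(x)
}

#' PSF shape factor for moment analysis
#'
#' Returns the dimensionless shape factor
#' \eqn{\gamma_n = \int g^n dA / \int g \, dA} of the peak-normalized beam
#' profile, which relates the n-th spatial cumulant of the intensity field to
#' the population parameters: \eqn{\kappa_n = \gamma_n \sum_i N_i
#' \epsilon_i^n}. For the 2D Gaussian profile \eqn{\gamma_n = 1/n}.
#'
#' @param psf A [psf_model()].
#' @param n Moment order, integer \eqn{\ge 1}.
#' @return \eqn{\gamma_n}, with \eqn{\gamma_1 = 1}.
#' @export
shape_factor <- function(psf, n) {
  stopifnot(inherits(psf, "psf_model"))
  if (!is.numeric(n) || any(n < 1) || any(n != round(n)))
    stop_invalid("moment order `n` must be a positive integer")
  1 / n
}
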