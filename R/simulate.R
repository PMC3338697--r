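#' Specify one population of fluorescent oligomers
#'
#' A population is a set of identical fluorescent entities (n-mers) scattered
#' over the membrane as a spatial Poisson process. An n-mer carries
#' `oligomer_order` subunits; each subunit independently carries a fluorophore
#' with probability `label_fraction`, so the entity brightness is
#' `per_subunit_brightness * Binomial(oligomer_order, label_fraction)`.
#'
#' @param surface_density Entities (not subunits) per square micrometre.
#' @param oligomer_order Subunits per entity (1 = monomer, 2 = dimer, ...).
#' @param per_subunit_brightness Monomeric quantal brightness epsilon in
#'   detector intensity units (iu): the peak pixel intensity contributed by a
#'   single fluorophore centered on a pixel.
#' @param label_fraction Probability that a subunit carries a fluorophore.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(surface_density, oligomer_order = 1L,
                            per_subunit_brightness = 44,
                            label_fraction = 1) {
  if (surface_density < 0) stop_invalid("`surface_density` must be >= 0")
  if (oligomer_order < 1 || oligomer_order != round(oligomer_order))
    stop_invalid("`oligomer_order` must be a positive integer")
  if (per_subunit_brightness < 0)
    stop_invalid("`per_subunit_brightness` must be >= 0")
  if (label_fraction < 0 || label_fraction > 1)
    stop_invalid("`label_fraction` must be in [0, 1]")
  structure(
    list(surface_density = surface_density,
         oligomer_order = as.integer(oligomer_order),
         per_subunit_brightness = per_subunit_brightness,
         label_fraction = label_fraction),
    class = "population_spec"
  )
}

#' Specify a synthetic confocal image
#'
#' Bundles everything needed to generate one synthetic single-channel CLSM
#' image of fluorophore-tagged membrane proteins: field geometry, PSF,
#' oligomer populations, a uniform background offset, an optional analog
#' detector model and a seed. Defaults emulate the imaging conditions of a
#' 60x/1.4NA confocal with 488 nm excitation: omega0 = 0.2 um, pixel
#' 0.046 um, monomeric brightness 44 iu, detector slope 0.5 iu with 2 iu^2
#' dark variance and 16-bit full scale.
#'
#' @param image_shape Integer vector (rows, cols); at least 64 x 64. A single
#'   number gives a square image.
#' @param psf A [psf_model()].
#' @param populations A `population_spec` or list of them.
#' @param pixel_size Pixel size in micrometres (defaults to `psf$pixel_size`).
#' @param background Uniform background offset in iu.
#' @param detector A [detector_model()] or `NULL` for a noiseless detector.
#' @param seed Integer seed; simulation output is bit-identical for equal
#'   specs and seeds.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(image_shape = c(256L, 256L),
                            psf = psf_model(0.2, 0.046),
                            populations = population_spec(10),
                            pixel_size = psf$pixel_size,
                            background = 10,
                            detector = detector_model(slope = 0.5,
                                                      intercept = 2),
                            seed = NULL) {
  if (length(image_shape) == 1L) image_shape <- rep(image_shape, 2L)
  image_shape <- as.integer(image_shape)
  if (any(image_shape < 64L)) stop_invalid("image must be at least 64 x 64")
  if (inherits(populations, "population_spec")) populations <- list(populations)
  stopifnot(all(vapply(populations, inherits, TRUE, "population_spec")))
  stopifnot(inherits(psf, "psf_model"))
  if (background < 0) stop_invalid("`background` must be >= 0")
  if (!is.null(detector)) stopifnot(inherits(detector, "detector_model"))
  structure(
    list(image_shape = image_shape, pixel_size = pixel_size, psf = psf,
         populations = populations, background = background,
         detector = detector, seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Place fluorescent entities over the guarded field
#'
#' Realizes the spatial Poisson process of each population: a Poisson count
#' with mean density x area over the field extended by a guard margin of
#' 3 omega0 on every side (so edge pixels have unbiased statistics), positions
#' uniform, and per-entity brightness
#' `per_subunit_brightness * Binomial(order, label_fraction)`.
#'
#' @param spec A [simulation_spec()]. The spec seed is *not* consumed here;
#'   [simulate_image()] owns the seed so composed draws stay reproducible.
#' @return Data frame with columns `x`, `y` (micrometres, relative to the
#'   top-left image corner; guard positions may be negative), `n_labels`,
#'   `brightness` (iu) and `population`.
#' @export
place_particles <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  guard <- 3 * spec$psf$e2_radius
  h <- spec$image_shape[1] * spec$pixel_size
  w <- spec$image_shape[2] * spec$pixel_size
  area <- (h + 2 * guard) * (w + 2 * guard)
  out <- vector("list", length(spec$populations))
  for (i in seq_along(spec$populations)) {
    p <- spec$populations[[i]]
    lambda <- p$surface_density * area
    if (lambda > 1e8)
      stop_invalid("expected particle count ", format(lambda),
                   " exceeds the 1e8 resource limit")
    n <- rpois(1L, lambda)
    nl <- rbinom(n, p$oligomer_order, p$label_fraction)
    out[[i]] <- data.frame(
      x = runif(n, -guard, w + guard),
      y = runif(n, -guard, h + guard),
      n_labels = nl,
      brightness = p$per_subunit_brightness * nl,
      population = rep(i, n)
    )
  }
  do.call(rbind, out)
}

#' Render the noise-free image of a particle set
#'
#' Forward model of PSF-convolved point emitters: each pixel value is the sum
#' over particles of `brightness * exp(-2 d^2 / omega0^2)` where `d` is the
#' distance from the pixel center to the particle. Linear in brightness.
#'
#' @param particles Data frame as returned by [place_particles()] (columns
#'   `x`, `y`, `brightness`).
#' @param psf A [psf_model()].
#' @param shape Integer (rows, cols) of the output image.
#' @param pixel_size Pixel size in micrometres.
#' @param cutoff Per-particle evaluation radius in micrometres; contributions
#'   beyond it (< 2e-8 of peak at the default 3 omega0) are dropped.
#' @return Numeric matrix of ideal intensities (iu), no background, no noise.
#' @export
render_image <- function(particles, psf, shape, pixel_size = psf$pixel_size,
                         cutoff = 3 * psf$e2_radius) {
  stopifnot(inherits(psf, "psf_model"))
  if (length(shape) == 1L) shape <- rep(shape, 2L)
  if (is.null(particles) || nrow(particles) == 0L)
    return(matrix(0, shape[1], shape[2]))
  render_particles_cpp(particles$x, particles$y, particles$brightness,
                       as.integer(shape[1]), as.integer(shape[2]),
                       pixel_size, psf$e2_radius, cutoff)
}

#' Apply analog detector noise to an ideal image
#'
#' Per pixel, draws a Gaussian with mean `ideal + background` and variance
#' `intercept + slope * (ideal + background)` (the calibrated analog-PMT
#' noise law), clamps to `[0, saturation]` and rounds to the nearest integer
#' intensity bin.
#'
#' @param ideal Numeric matrix of noise-free intensities (iu).
#' @param detector A [detector_model()] or `NULL` (then only background,
#'   clamping and rounding are applied).
#' @param background Uniform offset added before the noise draw (iu).
#' @param seed Optional integer seed.
#' @return Integer-valued matrix of detected intensities.
#' @export
apply_detector <- function(ideal, detector = NULL, background = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- ideal + background
  sat <- Inf
  if (!is.null(detector)) {
    stopifnot(inherits(detector, "detector_model"))
    v <- predict_variance(detector, m)
    noisy <- m + rnorm(length(m), 0, sqrt(v))
    m <- matrix(noisy, nrow(ideal), ncol(ideal))
    sat <- detector$saturation
  }
  matrix(round(pmin(pmax(m, 0), sat)), nrow(ideal), ncol(ideal))
}

#' Simulate one synthetic confocal image
#'
#' Composes [place_particles()], [render_image()] and [apply_detector()]
#' under the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `simulated_image` with elements `image` (integer
#'   matrix), `ideal` (noise-free matrix, no background), `particles` and
#'   `spec` (the ground truth).
#' @export
simulate_image <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  particles <- place_particles(spec)
  ideal <- render_image(particles, spec$psf, spec$image_shape, spec$pixel_size)
  image <- apply_detector(ideal, spec$detector, spec$background)
  structure(list(image = image, ideal = ideal, particles = particles,
                 spec = spec),
            class = "simulated_image")
}

#' Simulate a photobleaching image series
#'
#' Generates a stack of frames from one particle realization, removing each
#' fluorophore independently with probability `1 - survival_per_frame` before
#' every frame. The surviving label count of each entity decays, so the
#' recovered density decays geometrically across frames while the quantal
#' brightness per fluorophore is unchanged.
#'
#' @param spec A [simulation_spec()].
#' @param n_frames Number of frames.
#' @param survival_per_frame Per-fluorophore per-frame survival probability,
#'   in (0, 1].
#' @return List with `frames` (list of integer matrices), `n_labels` (matrix,
#'   entities x frames, surviving labels per entity) and `spec`.
#' @export
simulate_bleach_series <- function(spec, n_frames, survival_per_frame) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (survival_per_frame <= 0 || survival_per_frame > 1)
    stop_invalid("`survival_per_frame` must be in (0, 1]")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  particles <- place_particles(spec)
  eps <- vapply(seq_len(nrow(particles)), function(i)
    spec$populations[[particles$population[i]]]$per_subunit_brightness,
    numeric(1))
  nl <- particles$n_labels
  frames <- vector("list", n_frames)
  labels <- matrix(0L, nrow(particles), n_frames)
  for (f in seq_len(n_frames)) {
    nl <- rbinom(length(nl), nl, survival_per_frame)
    labels[, f] <- nl
    particles$brightness <- eps * nl
    ideal <- render_image(particles, spec$psf, spec$image_shape,
                          spec$pixel_size)
    frames[[f]] <- apply_detector(ideal, spec$detector, spec$background)
  }
  list(frames = frames, n_labels = labels, spec = spec)
}

#' Write a simulated image (or stack) to a 16-bit TIFF with a JSON sidecar
#'
#' The sidecar records the full simulation spec and seed so the ground truth
#' travels with the fixture.
#'
#' @param sim A `simulated_image` from [simulate_image()].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_simulation_tiff <- function(sim, path) {
  stopifnot(inherits(sim, "simulated_image"))
  write_image_tiff(sim$image, path, bits = 16L)
  spec <- sim$spec
  side <- list(
    image_shape = spec$image_shape, pixel_size = spec$pixel_size,
    psf = list(e2_radius = spec$psf$e2_radius,
               pixel_size = spec$psf$pixel_size),
    populations = lapply(spec$populations, unclass),
    background = spec$background,
    detector = if (is.null(spec$detector)) NULL else
      lapply(unclass(spec$detector),
             function(v) if (is.numeric(v) && is.infinite(v)) NULL else v),
    seed = spec$seed
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
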