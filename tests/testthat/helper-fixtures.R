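# Shared fixtures: the package's reference imaging conditions
# (60x/1.4NA confocal, 488 nm: omega0 = 0.2 um, pixel 0.046 um;
# analog PMT with variance 2 + 0.5 * mean; monomer brightness 44 iu).

test_psf <- function() psf_model(e2_radius = 0.2, pixel_size = 0.046)

test_detector <- function() detector_model(slope = 0.5, intercept = 2)

# one-population simulation at `n_per_ba` entities per beam area
mono_spec <- function(n_per_ba, shape = 256, eps = 44, order = 1,
                      seed = 1, detector = test_detector(),
                      background = 10, psf = test_psf()) {
  simulation_spec(
    image_shape = shape, psf = psf,
    populations = population_spec(n_per_ba / psf$beam_area, order, eps),
    background = background, detector = detector, seed = seed)
}

# SpIDA one-population fit of a simulated image, returning (N, eps)
fit_sim_one_pop <- function(sim) {
  spec <- sim$spec
  obs <- image_to_histogram(sim$image, background = spec$background)
  fit <- fit_histogram(obs, "one_pop", spec$psf, spec$detector,
                       background_offset = spec$background)
  expect_true(fit$converged)
  fit$estimates
}

# total-variation distance between an observed histogram and a model
tv_distance <- function(obs, model) {
  K <- max(length(obs$counts), length(model$mass))
  emp <- c(obs$counts / obs$total_pixels, numeric(K - length(obs$counts)))
  mod <- c(model$mass, numeric(K - length(model$mass)))
  0.5 * sum(abs(emp - mod))
}
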