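test_that("particle counts follow Poisson statistics over the guarded field", {
  psf <- psf_model(0.2, 0.1)
  spec <- simulation_spec(100, psf,
                          populations = population_spec(10),
                          detector = NULL, background = 0)
  guard <- 3 * psf$e2_radius
  lambda <- 10 * (100 * 0.1 + 2 * guard)^2
  set.seed(31)
  counts <- replicate(200, nrow(place_particles(spec)))
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 200))
  expect_gt(var(counts) / mean(counts), 0.7)   # Poisson: variance = mean
  expect_lt(var(counts) / mean(counts), 1.4)
})

test_that("zero density yields no particles; full labeling forces 2 eps for dimers", {
  psf <- test_psf()
  set.seed(32)
  empty <- place_particles(simulation_spec(64, psf,
                                           population_spec(0)))
  expect_equal(nrow(empty), 0)
  dimers <- place_particles(simulation_spec(
    64, psf, population_spec(20, oligomer_order = 2,
                             per_subunit_brightness = 44,
                             label_fraction = 1)))
  expect_true(all(dimers$brightness == 88))
  partial <- place_particles(simulation_spec(
    64, psf, population_spec(200, oligomer_order = 2,
                             per_subunit_brightness = 44,
                             label_fraction = 0.5)))
  expect_true(all(partial$n_labels %in% 0:2))
  expect_gt(sum(partial$n_labels == 1), 0)
})

test_that("rendering matches the Gaussian profile at and around a particle", {
  psf <- test_psf()
  px <- psf$pixel_size
  p <- data.frame(x = 10.5 * px, y = 20.5 * px, brightness = 44)
  img <- render_image(p, psf, c(64, 64))
  expect_equal(img[21, 11], 44, tolerance = 1e-12)
  expect_equal(img[21, 12], 44 * exp(-2 * px^2 / psf$e2_radius^2),
               tolerance = 1e-12)
  expect_equal(img[22, 12], 44 * exp(-2 * 2 * px^2 / psf$e2_radius^2),
               tolerance = 1e-12)
  # linearity in brightness is exact
  p2 <- p; p2$brightness <- 88
  expect_equal(render_image(p2, psf, c(64, 64)), 2 * img, tolerance = 1e-14)
})

test_that("mean rendered intensity equals N * eps (Campbell's theorem)", {
  means <- vapply(1:10, function(s) {
    sim <- simulate_image(mono_spec(2, shape = 128, eps = 30, seed = 400 + s,
                                    detector = NULL, background = 0))
    mean(sim$ideal)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 60), 3 * se + 0.01)
})

test_that("rendered spatial cumulants match the compound-process values", {
  # kappa_n = gamma_n * N * eps^n for a one-population Poisson field
  psf <- test_psf()
  truth <- forward_cumulants(2, 30, 0, 0, psf)
  ks <- vapply(1:12, function(s) {
    sim <- simulate_image(mono_spec(2, shape = 256, eps = 30, seed = 500 + s,
                                    detector = NULL, background = 0))
    raw <- compute_raw_moments(as.numeric(sim$ideal))
    m <- correct_moments(raw, NULL)
    c(m$mean, m$kappa2, m$kappa3, m$kappa4)
  }, numeric(4))
  est <- rowMeans(ks)
  se <- apply(ks, 1, sd) / sqrt(ncol(ks))
  for (i in 1:4)
    expect_lt(abs(est[i] - truth[i]), 4 * se[i])
})

test_that("simulation is bit-identical for a fixed seed", {
  s1 <- simulate_image(mono_spec(1, seed = 77))
  s2 <- simulate_image(mono_spec(1, seed = 77))
  expect_identical(s1$image, s2$image)
  s3 <- simulate_image(mono_spec(1, seed = 78))
  expect_false(identical(s1$image, s3$image))
})

test_that("the detector stage adds the calibrated noise and clamps", {
  flat <- matrix(100, 128, 128)
  # zero detector: pure rounding
  expect_equal(apply_detector(flat, NULL, background = 10),
               matrix(110, 128, 128))
  d <- test_detector()
  out <- apply_detector(flat, d, background = 0, seed = 61)
  expect_lt(abs(mean(out) - 100), 1)
  expect_lt(abs(var(as.numeric(out)) - 52), 5)   # 2 + 0.5*100, +1/12 rounding
  # clamping at saturation
  d8 <- detector_model(slope = 0, intercept = 0, saturation = 255)
  expect_true(all(apply_detector(matrix(300, 64, 64), d8) == 255))
})

test_that("bleaching thins fluorophores geometrically at constant brightness", {
  spec <- mono_spec(3, shape = 64, seed = 91, detector = NULL, background = 0)
  s1 <- simulate_bleach_series(spec, n_frames = 3, survival_per_frame = 1)
  expect_identical(s1$frames[[1]], s1$frames[[3]])

  spec2 <- simulation_spec(64, test_psf(),
                           populations = population_spec(300, 1, 44),
                           detector = NULL, background = 0, seed = 92)
  s2 <- simulate_bleach_series(spec2, n_frames = 20,
                               survival_per_frame = 0.9)
  # frame-20 expectation is 0.9^20 of the initial label count
  exp20 <- nrow(s2$n_labels) * 0.9^20
  expect_lt(abs(sum(s2$n_labels[, 20]) - exp20), 4 * sqrt(exp20))
  expect_lt(sum(s2$n_labels[, 20]), sum(s2$n_labels[, 1]))
})
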