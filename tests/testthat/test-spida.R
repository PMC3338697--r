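test_that("the single-particle distribution follows the Gaussian profile", {
  psf <- test_psf()
  rho <- single_particle_distribution(psf, 100)
  expect_equal(sum(rho$mass), 1, tolerance = 1e-12)
  # a particle at r = omega0 contributes round(100 * e^-2) = 14 iu
  expect_equal(round(100 * exp(-2)), 14)
  expect_gt(rho$mass[14 + 1], 0)
  # mean contribution scaled by disc area / beam area returns eps
  m1 <- sum((seq_along(rho$mass) - 1) * rho$mass)
  expect_lt(abs(m1 * rho$lambda_per_N - 100), 1)
  expect_error(single_particle_distribution(psf, 100, cutoff_radius = 0.3),
               "cutoff")
})

test_that("the analytic distribution matches the grid-sampled oracle", {
  psf <- test_psf()
  for (eps in c(20, 100)) {
    a <- single_particle_distribution(psf, eps, method = "analytic")
    g <- single_particle_distribution(psf, eps, method = "grid",
                                      subsample = 80L)
    expect_lt(0.5 * sum(abs(a$mass - g$mass)), 0.01)
  }
})

test_that("compound histograms are normalized with mean N * eps", {
  psf <- test_psf()
  h0 <- compound_histogram(0, 50, psf)
  expect_equal(h0$mass, 1)              # empty field: point mass at zero
  for (N in c(0.5, 5)) for (eps in c(10, 50)) {
    h <- compound_histogram(N, eps, psf)
    expect_lt(abs(sum(h$mass) - 1), 1e-9)
    expect_lt(abs(sum(h$k * h$mass) - N * eps), 0.1)
  }
})

test_that("characteristic-function and direct Poisson sums agree", {
  psf <- test_psf()
  for (N in c(0.3, 1.5)) {
    hf <- compound_histogram(N, 40, psf, method = "fft")
    hd <- compound_histogram(N, 40, psf, method = "direct")
    L <- min(length(hf$mass), length(hd$mass))
    expect_lt(max(abs(hf$mass[1:L] - hd$mass[1:L])), 1e-8)
  }
})

test_that("Poisson superposition: densities add under convolution", {
  psf <- test_psf()
  h1 <- compound_histogram(1.3, 40, psf)
  h2 <- compound_histogram(2.4, 40, psf)
  hs <- compound_histogram(3.7, 40, psf)
  hc <- convolve_histograms(h1, h2)
  L <- max(length(hs$mass), length(hc$mass))
  pad <- function(h) c(h$mass, numeric(L - length(h$mass)))
  expect_lt(max(abs(pad(hs) - pad(hc))), 1e-8)
})

test_that("histogram convolution has the point mass at zero as identity", {
  psf <- test_psf()
  h <- compound_histogram(2, 30, psf)
  id <- compound_histogram(0, 30, psf)
  hc <- convolve_histograms(h, id)
  L <- min(length(h$mass), length(hc$mass))
  expect_lt(max(abs(h$mass[1:L] - hc$mass[1:L])), 1e-10)
  # two point masses convolve to a shifted point mass
  pa <- oligofluct:::new_histogram_model(c(numeric(5), 1))   # at 5
  pb <- oligofluct:::new_histogram_model(c(numeric(7), 1))   # at 7
  pc <- convolve_histograms(pa, pb)
  expect_equal(which(pc$mass > 0.5) - 1, 12)
})

test_that("detector broadening is a mean-preserving discretized Gaussian", {
  d0 <- detector_model(slope = 0, intercept = 0)
  psf <- test_psf()
  h <- compound_histogram(2, 30, psf)
  expect_identical(broaden_histogram(h, d0), h)

  # point mass at 100 iu broadens to variance slope * 100 (+1/12 binning)
  p <- oligofluct:::new_histogram_model(c(numeric(100), 1))
  pb <- broaden_histogram(p, detector_model(slope = 0.5, intercept = 0))
  mu <- sum(pb$k * pb$mass)
  v <- sum((pb$k - mu)^2 * pb$mass)
  expect_equal(mu, 100, tolerance = 1e-9)
  expect_equal(v, 50 + 1 / 12, tolerance = 1e-3)
  expect_lt(abs(sum(pb$mass) - 1), 1e-9)

  # law of total variance on an interior compound distribution
  d <- test_detector()
  hb <- broaden_histogram(h, d)
  mu0 <- sum(h$k * h$mass); v0 <- sum((h$k - mu0)^2 * h$mass)
  mu1 <- sum(hb$k * hb$mass); v1 <- sum((hb$k - mu1)^2 * hb$mass)
  expect_equal(mu1, mu0, tolerance = 1e-4)   # bin-0 folding shifts ~1e-5
  expect_equal(v1 - v0, d$intercept + d$slope * mu0 + 1 / 12,
               tolerance = 0.02)
})

test_that("image histograms conserve pixels and subtract background", {
  img <- matrix(10, 64, 64)
  h <- image_to_histogram(img, background = 10)
  expect_equal(h$counts[1], 64^2)
  expect_equal(h$total_pixels, 64^2)

  img2 <- matrix(rep(c(5, 15), 2048), 64, 64)
  h2 <- image_to_histogram(img2, background = 5)
  expect_equal(h2$counts[c(1, 11)], c(2048, 2048))
  expect_equal(sum(h2$counts), h2$total_pixels)
})

test_that("fitting an exact model histogram is a fixed point", {
  psf <- test_psf()
  h <- compound_histogram(2, 30, psf)
  obs <- intensity_histogram(h$mass * 1e6)
  fit <- fit_histogram(obs, "one_pop", psf)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["N"]], 2, tolerance = 1e-4)
  expect_equal(fit$estimates[["eps"]], 30, tolerance = 1e-4)
  expect_lt(fit$residual, 1e-9)
})

test_that("a monomer-dimer mixture model recovers both densities", {
  psf <- test_psf()
  h <- convolve_histograms(compound_histogram(1.5, 25, psf),
                           compound_histogram(0.8, 50, psf))
  obs <- intensity_histogram(h$mass * 1e6)
  fit <- fit_histogram(obs, spida_fit_options("monomer_dimer",
                                              fixed_monomer_eps = 25), psf)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["N1"]], 1.5, tolerance = 1e-3)
  expect_equal(fit$estimates[["N2"]], 0.8, tolerance = 1e-3)
  expect_equal(fit$estimates[["eps2"]], 50)
})

test_that("model histograms match simulated images (Monte-Carlo oracle)", {
  psf <- test_psf()
  sim <- simulate_image(mono_spec(1, shape = 1024, eps = 50, seed = 51,
                                  detector = NULL, background = 0))
  obs <- image_to_histogram(sim$image)
  h <- compound_histogram(1, 50, psf)
  expect_lt(tv_distance(obs, h), 0.01)
})

test_that("saturated histograms trigger the top-bin exclusion", {
  psf <- test_psf()
  h <- compound_histogram(2, 30, psf)
  obs <- intensity_histogram(h$mass * 2e4, n_saturated = 500)
  expect_warning(fit <- fit_histogram(obs, "one_pop", psf), "saturated")
  expect_true("saturation" %in% fit$flags)
})

test_that("undersized histograms are rejected", {
  psf <- test_psf()
  h <- compound_histogram(2, 30, psf)
  expect_error(fit_histogram(intensity_histogram(h$mass * 100), "one_pop",
                             psf), "1e4")
})
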