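test_that("raw central moments match closed-form values", {
  px <- rep(c(0, 2), 32)                 # two-point distribution
  m <- compute_raw_moments(px)
  expect_equal(m$mean, 1)
  expect_equal(m$mu2, 1)
  expect_equal(m$mu3, 0)
  expect_equal(m$mu4, 1)

  m2 <- compute_raw_moments(rep(c(0, 0, 3), 22))
  expect_equal(m2$mean, 1)
  expect_equal(m2$mu2, 2)
  expect_equal(m2$mu3, 2)
  expect_equal(m2$mu4, 6)

  m3 <- compute_raw_moments(rep(5, 64))
  expect_equal(c(m3$mu2, m3$mu3, m3$mu4), c(0, 0, 0))
  expect_error(compute_raw_moments(c(0, 2)), "64 pixels")
})

test_that("a zero detector leaves cumulants untouched", {
  set.seed(41)
  px <- rpois(500, 9)
  raw <- compute_raw_moments(px)
  m <- correct_moments(raw, detector_model(slope = 0, intercept = 0))
  expect_equal(m$kappa2, raw$mu2)
  expect_equal(m$kappa3, raw$mu3)
  expect_equal(m$kappa4, raw$mu4 - 3 * raw$mu2^2)
})

test_that("pure detector noise corrects to zero cumulants", {
  d <- test_detector()
  img <- apply_detector(matrix(0, 256, 256), d, background = 100, seed = 42)
  m <- image_moments(img, d, background = 100)
  n <- m$n_pixels
  noise_var <- predict_variance(d, 100)
  expect_lt(abs(m$kappa2), 5 * noise_var * sqrt(2 / n))
  expect_lt(abs(m$kappa3) / noise_var^1.5, 5 * sqrt(15 / n))
  expect_lt(abs(m$kappa4) / noise_var^2, 5 * sqrt(96 / n))
})

test_that("detector correction recovers the noise-free kappa2 on a simulated field", {
  psf <- test_psf()
  sim <- simulate_image(mono_spec(2, shape = 512, eps = 30, seed = 43))
  m <- image_moments(sim$image, sim$spec$detector,
                     background = sim$spec$background)
  truth <- forward_cumulants(2, 30, 0, 0, psf)
  expect_equal(m$kappa2, unname(truth["kappa2"]), tolerance = 0.1)
  expect_equal(m$mean, unname(truth["mean"]), tolerance = 0.05)
})

test_that("one-population inversion satisfies its defining relations", {
  psf <- test_psf()
  sol <- solve_one_population(list(mean = 70, kappa2 = 175), psf)
  expect_equal(sol$eps, 5)
  expect_equal(sol$N, 14)
  # fixed point: kappa2 = gamma2 * mean^2 gives one entity per beam area
  sol2 <- solve_one_population(list(mean = 33, kappa2 = 0.5 * 33^2), psf)
  expect_equal(sol2$N, 1)
  expect_equal(sol2$eps, 33)
  expect_error(solve_one_population(list(mean = 10, kappa2 = -1), psf),
               "no signal")
})

test_that("simulated monomers are recovered within 5% (eps) and 10% (N)", {
  psf <- test_psf()
  sim <- simulate_image(mono_spec(2, shape = 512, eps = 30, seed = 44))
  m <- image_moments(sim$image, sim$spec$detector,
                     background = sim$spec$background)
  sol <- solve_one_population(m, psf)
  expect_lt(abs(sol$eps - 30) / 30, 0.05)
  expect_lt(abs(sol$N - 2) / 2, 0.10)
})

test_that("two-population inversion reproduces the worked cumulant example", {
  psf <- test_psf()
  # forward: (N1=5, eps1=10, N2=1, eps2=20) with gamma_n = 1/n
  k <- forward_cumulants(5, 10, 1, 20, psf)
  expect_equal(unname(k), c(70, 450, 13000 / 3, 52500))
  sol <- solve_two_populations(list(mean = k[1], kappa2 = k[2],
                                    kappa3 = k[3], kappa4 = k[4]), psf)
  expect_equal(sol$model, "two_pop")
  expect_equal(sol$N1, 5, tolerance = 1e-8)
  expect_equal(sol$eps1, 10, tolerance = 1e-8)
  expect_equal(sol$N2, 1, tolerance = 1e-8)
  expect_equal(sol$eps2, 20, tolerance = 1e-8)
  expect_equal(sol$alpha, 2, tolerance = 1e-8)
})

test_that("noise-free round trips invert exactly across parameter space", {
  psf <- test_psf()
  set.seed(45)
  for (i in 1:20) {
    N1 <- runif(1, 0.5, 10); N2 <- runif(1, 0.5, 10)
    e1 <- runif(1, 5, 40); alpha <- runif(1, 1.5, 6)
    k <- forward_cumulants(N1, e1, N2, alpha * e1, psf)
    sol <- solve_two_populations(list(mean = k[1], kappa2 = k[2],
                                      kappa3 = k[3], kappa4 = k[4]), psf)
    expect_equal(sol$model, "two_pop")
    expect_equal(c(sol$N1, sol$eps1, sol$N2, sol$eps2),
                 c(N1, e1, N2, alpha * e1), tolerance = 1e-6)
  }
})

test_that("a fixed brightness ratio needs only the first three cumulants", {
  psf <- test_psf()
  k <- forward_cumulants(3, 25, 1.5, 50, psf)
  # kappa4 is not needed (and may be unavailable) in fixed-ratio mode
  solf <- solve_two_populations(list(mean = k[1], kappa2 = k[2],
                                     kappa3 = k[3], kappa4 = NA), psf,
                                fix_alpha = 2)
  expect_equal(c(solf$N1, solf$eps1, solf$N2, solf$eps2),
               c(3, 25, 1.5, 50), tolerance = 1e-6)
})

test_that("single-population cumulants collapse to the one-population answer", {
  psf <- test_psf()
  k <- forward_cumulants(4, 18, 0, 0, psf)
  sol <- solve_two_populations(list(mean = k[1], kappa2 = k[2],
                                    kappa3 = k[3], kappa4 = k[4]), psf)
  expect_equal(sol$model, "one_pop")
  expect_equal(sol$N1, 4, tolerance = 1e-8)
  expect_equal(sol$eps1, 18, tolerance = 1e-8)
  expect_equal(sol$N2, 0)
})

test_that("background estimation uses dark ROIs or the darkest pixels", {
  flat <- matrix(7, 64, 64)
  expect_equal(estimate_background(flat, roi_spec(0, 0, 8, 8, "background")), 7)
  half <- cbind(matrix(5, 64, 32), matrix(100, 64, 32))
  expect_equal(estimate_background(half), 5)
  expect_error(estimate_background(flat, list()), "empty")
})

test_that("tile averaging agrees with whole-ROI moments on homogeneous fields", {
  sim <- simulate_image(mono_spec(2, shape = 256, seed = 46))
  bg <- sim$spec$background
  m_all <- image_moments(sim$image, sim$spec$detector, background = bg)
  m_tile <- tile_moments(sim$image, sim$spec$detector, background = bg,
                         tile = 128L)
  expect_equal(m_tile$mean, m_all$mean, tolerance = 0.02)
  expect_equal(m_tile$kappa2, m_all$kappa2, tolerance = 0.1)
  expect_gte(attr(m_tile, "n_tiles")[["used"]], 1)
})
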