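#' Observed pixel-intensity histogram
#'
#' Counts of background-subtracted pixel intensities over integer bins
#' `0 .. k_max` (bin width 1 iu).
#'
#' @param counts Non-negative counts; element `i` is the count for intensity
#'   `i - 1`.
#' @param background_subtracted Whether a background was removed.
#' @param n_saturated Number of saturated pixels among the counts.
#' @return An object of class `intensity_histogram` with fields `counts`,
#'   `k` (0-based bin intensities), `total_pixels`, `background_subtracted`,
#'   `n_saturated`.
#' @export
intensity_histogram <- function(counts, background_subtracted = FALSE,
                                n_saturated = 0L) {
  if (any(counts < 0)) stop_invalid("histogram counts must be >= 0")
  structure(list(counts = as.numeric(counts),
                 k = seq_along(counts) - 1,
                 total_pixels = sum(counts),
                 background_subtracted = background_subtracted,
                 n_saturated = as.integer(n_saturated)),
            class = "intensity_histogram")
}

#' Histogram of an image's signal pixels
#'
#' Builds the background-subtracted pixel-intensity histogram over the given
#' signal ROIs. Negative background-subtracted values clamp to bin 0; pixels
#' at or above `saturation` are counted but flagged.
#'
#' @param image Integer-valued matrix.
#' @param rois A [roi_spec()], list of them, or `NULL` for the whole image.
#' @param background Background level (iu) to subtract.
#' @param saturation Detector full scale (iu).
#' @return An [intensity_histogram()].
#' @export
image_to_histogram <- function(image, rois = NULL, background = 0,
                               saturation = Inf) {
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  px <- if (is.null(rois)) as.numeric(image)
        else unlist(lapply(rois, function(r) roi_pixels(image, r)))
  if (length(px) == 0L) stop_invalid("empty ROI")
  n_sat <- sum(px >= saturation)
  v <- pmax(round(px - background), 0)
  counts <- tabulate(v + 1L, nbins = max(v) + 1L)
  intensity_histogram(counts, background_subtracted = background != 0,
                      n_saturated = n_sat)
}

# -- model histograms --------------------------------------------------------

# A histogram model carries its integer-bin mass and, until detector
# broadening, an internal fine-grid representation (bin width `delta` iu,
# mass `fine`, real-valued intensity offset `offset` iu) so that population
# convolution stays exact (Poisson superposition) before the final
# aggregation to integer bins.
new_histogram_model <- function(mass, params = list(), broadened = FALSE,
                                fine = NULL, delta = NA_real_, offset = 0) {
  structure(list(mass = as.numeric(mass), k = seq_along(mass) - 1,
                 params = params, broadened = broadened,
                 fine = fine, delta = delta, offset = offset),
            class = "histogram_model")
}

# collapse a fine-grid mass (bin width delta, shifted by offset iu) onto
# integer intensity bins by rounding the represented intensity of each bin
aggregate_fine <- function(fine, delta, offset) {
  kv <- pmax(round((seq_along(fine) - 1) * delta + offset), 0)
  mass <- numeric(max(kv) + 1L)
  agg <- rowsum(fine, kv)
  mass[as.numeric(rownames(agg)) + 1L] <- agg[, 1L]
  mass
}

#' @export
print.histogram_model <- function(x, ...) {
  mu <- sum(x$k * x$mass)
  cat(sprintf("Model intensity histogram: %d bins, mean %.4g iu%s\n",
              length(x$mass), mu, if (x$broadened) ", broadened" else ""))
  invisible(x)
}

#' Intensity distribution of a single particle at a random position
#'
#' The probability mass, over integer intensity bins, of the contribution a
#' single particle at a uniformly random position within a disc of radius
#' `cutoff_radius` makes to the pixel at the disc center. The Gaussian beam
#' profile is analytically invertible, so the default method computes each
#' bin's mass as an exact area fraction of the disc:
#' the region contributing at least `x` iu has area
#' \eqn{\pi \omega_0^2 \ln(\epsilon/x) / 2}. A numeric `"grid"` method
#' (uniform subsampling of the disc) is provided as an independent
#' cross-check.
#'
#' @param psf A [psf_model()].
#' @param eps Quantal brightness (iu), > 0.
#' @param cutoff_radius Disc radius in micrometres, at least 3 omega0 (the
#'   single-particle mass beyond that is < 0.1% of a bin).
#' @param method `"analytic"` (exact) or `"grid"`.
#' @param subsample Grid points per omega0 for `method = "grid"`.
#' @param bin_width Intensity bin width in iu (default 1, the detector's
#'   output quantization; [compound_histogram()] uses a finer internal grid).
#' @return List with `mass` (bins `0, bin_width, 2 bin_width, ...` up to
#'   `eps`), `bin_width`, `lambda_per_N` (expected particles in the disc per
#'   unit density-per-beam-area, i.e. disc area / beam area), `tail_mean`
#'   (mean intensity carried by contributions below half a bin, folded into
#'   bin 0; in iu) and `cutoff_radius`.
#' @export
single_particle_distribution <- function(psf, eps,
                                         cutoff_radius = 3 * psf$e2_radius,
                                         method = c("analytic", "grid"),
                                         subsample = 40L, bin_width = 1) {
  stopifnot(inherits(psf, "psf_model"))
  method <- match.arg(method)
  if (eps <= 0) stop_invalid("`eps` must be > 0")
  if (bin_width <= 0) stop_invalid("`bin_width` must be > 0")
  if (cutoff_radius < 3 * psf$e2_radius)
    stop_invalid("`cutoff_radius` must be at least 3 omega0 ",
                 "(truncated single-particle mass would exceed 0.1%)")
  w2 <- psf$e2_radius^2
  a <- 2 * cutoff_radius^2 / w2          # disc area / beam area
  kmax <- floor(eps / bin_width + 0.5)
  # P(contribution >= x) = min(1, ln(eps/x) / a) for 0 < x <= eps
  upper <- function(x) {
    out <- numeric(length(x))
    pos <- x > 0 & x <= eps
    out[pos] <- pmin(1, log(eps / x[pos]) / a)
    out[x <= 0] <- 1
    out
  }
  if (method == "analytic") {
    mass <- numeric(kmax + 1L)
    if (kmax >= 1L) {
      kk <- seq_len(kmax)
      mass[kk + 1L] <- upper((kk - 0.5) * bin_width) -
        upper((kk + 0.5) * bin_width)
    }
    mass[1L] <- 1 - sum(mass[-1L])
  } else {
    h <- psf$e2_radius / subsample
    g <- seq(-cutoff_radius, cutoff_radius, by = h)
    xy <- expand.grid(x = g, y = g)
    r2 <- xy$x^2 + xy$y^2
    r2 <- r2[r2 <= cutoff_radius^2]
    kv <- pmin(round(eps * exp(-2 * r2 / w2) / bin_width), kmax)
    mass <- tabulate(kv + 1L, nbins = kmax + 1L) / length(r2)
  }
  # intensity carried by the sub-half-bin tail: integrating q over the disc
  # area where q < t gives exactly t * BA, i.e. t per unit density-per-BA
  list(mass = mass, bin_width = bin_width, lambda_per_N = a,
       tail_mean = bin_width / 2, cutoff_radius = cutoff_radius)
}

#' Super-Poissonian model histogram of a one-species field
#'
#' The pixel-intensity distribution of a spatial Poisson field of identical
#' particles: with n the (Poisson) number of particles inside the evaluation
#' disc and rho the single-particle intensity distribution, the histogram is
#' \deqn{H(k) = \sum_n \mathrm{Pois}(n; \lambda)\, \rho^{*n}(k),}
#' the compound Poisson distribution. It is computed either by
#' characteristic-function multiplication on an FFT grid (`"fft"`, exact up
#' to grid truncation below 1e-12 mass) or by direct Poisson-weighted
#' iterative convolution truncated at cumulative probability 1 - 1e-9
#' (`"direct"`); `"auto"` uses the direct sum for small expected counts and
#' the FFT otherwise. Both agree to better than 1e-8.
#'
#' @param N Mean number of entities per beam area, >= 0.
#' @param eps Quantal brightness per entity (iu), >= 0.
#' @param psf A [psf_model()].
#' @param method `"auto"`, `"fft"` or `"direct"`.
#' @param cutoff_radius Evaluation disc radius (micrometres).
#' @param k_max Optional number of intensity bins - 1; chosen automatically
#'   to cover the mean plus 12 standard deviations.
#' @param refine Internal sub-binning factor: the compound distribution is
#'   built on an intensity grid of `1/refine` iu so that the many sub-unit
#'   contributions of distant particles accumulate before the final rounding
#'   to integer bins, exactly as they do on the detector.
#' @return A `histogram_model` whose mass sums to 1 within 1e-9 and whose
#'   mean is `N * eps` up to quantization.
#' @export
compound_histogram <- function(N, eps, psf, method = c("auto", "fft", "direct"),
                               cutoff_radius = 3 * psf$e2_radius,
                               k_max = NULL, refine = 8L) {
  method <- match.arg(method)
  if (N < 0 || eps < 0) stop_invalid("`N` and `eps` must be >= 0")
  params <- list(N = N, eps = eps)
  if (N == 0 || eps == 0)
    return(new_histogram_model(1, params = params,
                               fine = 1, delta = 1 / refine, offset = 0))
  delta <- 1 / refine
  rho <- single_particle_distribution(psf, eps, cutoff_radius,
                                      bin_width = delta)
  lambda <- N * rho$lambda_per_N
  jj <- seq_along(rho$mass) - 1
  m1 <- sum(rho$mass * jj)
  m2 <- sum(rho$mass * jj^2)
  # Quantizing the single-particle profile to the fine grid biases its mean
  # (sub-half-bin tail contributions fold into bin 0; the 1/q-skewed density
  # biases low bins upward). Across the Poisson field these per-particle
  # errors, each below delta/2, sum to a near-deterministic intensity
  # (variance <= lambda delta^2/4), restored exactly as the mean deficit
  # N*eps - lambda*m1*delta. Linear in N, so Poisson superposition is kept.
  offset <- N * eps - lambda * m1 * delta
  if (is.null(k_max))
    k_max <- ceiling((lambda * m1 + offset / delta +
                        12 * sqrt(max(lambda * m2, 1))) * delta + eps + 16)
  nfine <- ceiling((k_max + 1) / delta)
  if (nfine > 2^22)
    stop_invalid("required intensity range (", nfine, " fine bins) exceeds ",
                 "the resource limit; N * eps is too large")
  if (method == "auto") method <- if (lambda <= 30) "direct" else "fft"

  if (method == "fft") {
    L <- 2^ceiling(log2(nfine))
    rpad <- numeric(L)
    rpad[seq_along(rho$mass)] <- rho$mass
    phi <- fft(rpad)
    F <- Re(fft(exp(lambda * (phi - 1)), inverse = TRUE)) / L
    F <- pmax(F[seq_len(nfine)], 0)
  } else {
    nmax <- qpois(1 - 1e-9, lambda)
    F <- numeric(nfine)
    conv <- numeric(nfine); conv[1L] <- 1     # rho^{*0} = point mass at 0
    F <- F + exp(-lambda) * conv
    for (n in seq_len(nmax)) {
      full <- convolve_mass(conv, rho$mass)
      conv <- full[seq_len(min(length(full), nfine))]
      if (length(conv) < nfine) conv <- c(conv, numeric(nfine - length(conv)))
      F <- F + stats::dpois(n, lambda) * conv
    }
  }
  F <- F / sum(F)
  mass <- aggregate_fine(F, delta, offset)
  new_histogram_model(mass, params = params,
                      fine = F, delta = delta, offset = offset)
}

# plain discrete convolution of two mass vectors (0-based support)
convolve_mass <- function(a, b) {
  la <- length(a); lb <- length(b)
  L <- 2^ceiling(log2(la + lb - 1))
  re <- Re(fft(fft(c(a, numeric(L - la))) * fft(c(b, numeric(L - lb))),
               inverse = TRUE)) / L
  pmax(re[seq_len(la + lb - 1)], 0)
}

#' Convolve two model histograms (two-population mixture)
#'
#' When two independent populations coexist in the field, the total pixel
#' histogram is the discrete convolution of the two single-population
#' histograms. The result is renormalized to unit mass.
#'
#' @param h1,h2 `histogram_model` objects on 1-iu bins.
#' @return A `histogram_model`; its mean is the sum of the input means.
#' @export
convolve_histograms <- function(h1, h2) {
  stopifnot(inherits(h1, "histogram_model"), inherits(h2, "histogram_model"))
  params <- list(pop1 = h1$params, pop2 = h2$params)
  if (!is.null(h1$fine) && !is.null(h2$fine) &&
      isTRUE(all.equal(h1$delta, h2$delta))) {
    # exact Poisson superposition: convolve on the shared fine grid and
    # carry the intensity offsets additively before integer aggregation
    F <- convolve_mass(h1$fine, h2$fine)
    F <- F / sum(F)
    offset <- h1$offset + h2$offset
    return(new_histogram_model(aggregate_fine(F, h1$delta, offset),
                               params = params, fine = F, delta = h1$delta,
                               offset = offset))
  }
  m <- convolve_mass(h1$mass, h2$mass)
  new_histogram_model(m / sum(m), params = params,
                      broadened = h1$broadened || h2$broadened)
}

#' Detector broadening of a model histogram
#'
#' Each histogram value at intensity k is substituted by a discretized
#' normalized Gaussian centered at k with variance
#' `intercept + slope * (k + offset)`, the calibrated analog-PMT noise law.
#' Mass falling at or below zero accumulates in bin 0; total mass is
#' preserved to better than 1e-9.
#'
#' @param h A `histogram_model`.
#' @param detector A [detector_model()]; a zero detector returns the input.
#' @param offset Intensity offset (iu) added inside the variance law only —
#'   use the background level when the histogram is background-subtracted but
#'   the detector saw signal plus background.
#' @return A broadened `histogram_model`.
#' @export
broaden_histogram <- function(h, detector, offset = 0) {
  stopifnot(inherits(h, "histogram_model"),
            inherits(detector, "detector_model"))
  if (offset < 0) stop_invalid("`offset` must be >= 0")
  if (detector$slope == 0 && detector$intercept == 0) return(h)
  out <- broaden_cpp(h$mass, detector$slope, detector$intercept, offset, 8)
  new_histogram_model(out / sum(out), params = h$params, broadened = TRUE)
}

# -- fitting -----------------------------------------------------------------

#' Fit options for SpIDA histogram analysis
#'
#' @param model `"one_pop"` (free N, eps), `"two_pop_free"` (free N1, eps1,
#'   N2, eps2) or `"monomer_dimer"` (free N1, N2 with eps2 = 2 eps1; eps1
#'   fixed to `fixed_monomer_eps` when given, jointly fitted otherwise).
#' @param fixed_monomer_eps Monomeric brightness (iu) from an independent
#'   control, or `NULL`.
#' @param k_range Fit window `c(lo, hi)` in iu; `NULL` for 0 to the 99.9th
#'   percentile of the observed histogram.
#' @param weighting `"none"` (unweighted least squares, default) or
#'   `"poisson"` (residuals scaled by the expected sampling error of each
#'   observed bin).
#' @return An object of class `spida_fit_options`.
#' @export
spida_fit_options <- function(model = c("one_pop", "two_pop_free",
                                        "monomer_dimer"),
                              fixed_monomer_eps = NULL, k_range = NULL,
                              weighting = c("none", "poisson")) {
  structure(list(model = match.arg(model),
                 fixed_monomer_eps = fixed_monomer_eps,
                 k_range = k_range,
                 weighting = match.arg(weighting)),
            class = "spida_fit_options")
}

#' Fit a super-Poissonian model to an observed intensity histogram (SpIDA)
#'
#' Least-squares fit of the (detector-broadened) compound-Poisson model
#' histogram to the normalized observed pixel-intensity histogram, recovering
#' density per beam area and quantal brightness for one population, or the
#' two densities (and brightnesses) of a mixture. Parameters are optimized in
#' log space, which enforces positivity; the fit is deterministic given its
#' initialization (taken from one-population moment analysis of the histogram
#' unless supplied).
#'
#' @param observed An [intensity_histogram()] with at least 1e4 pixels.
#' @param options A [spida_fit_options()], or a model name.
#' @param psf A [psf_model()].
#' @param detector A [detector_model()] or `NULL` (no broadening).
#' @param background_offset Background level (iu) entering the broadening
#'   variance law, see [broaden_histogram()].
#' @param init Optional list with starting values (`N`, `eps` or `N1`,
#'   `eps1`, `N2`, `eps2`).
#' @return An object of class `spida_fit`: `estimates` (named vector),
#'   `stderr`, `residual` (root mean squared residual of the normalized
#'   histogram), `fitted` (`histogram_model`), `converged`, `flags`,
#'   `n_pixels`.
#' @export
fit_histogram <- function(observed, options = spida_fit_options(), psf,
                          detector = NULL, background_offset = 0,
                          init = NULL) {
  stopifnot(inherits(observed, "intensity_histogram"))
  if (is.character(options)) options <- spida_fit_options(options)
  stopifnot(inherits(options, "spida_fit_options"))
  if (observed$total_pixels < 1e4)
    stop_invalid("SpIDA needs at least 1e4 pixels in the histogram")

  flags <- character(0)
  counts <- observed$counts
  if (observed$n_saturated > 0.01 * observed$total_pixels) {
    warning("more than 1% saturated pixels; excluding the top bin")
    counts[length(counts)] <- 0
    flags <- c(flags, "saturation")
  }
  A <- sum(counts)
  freq <- counts / A

  kr <- options$k_range
  if (is.null(kr)) {
    cum <- cumsum(freq)
    kr <- c(0, observed$k[min(which(cum >= 0.999))])
  }
  sel <- observed$k >= kr[1] & observed$k <= kr[2]
  wts <- if (options$weighting == "poisson")
    1 / sqrt(pmax(freq[sel], 1 / A) / A) else rep(1, sum(sel))
  wts <- wts / max(wts)

  # initialization from one-population moment inversion of the histogram
  if (is.null(init)) {
    mu <- sum(observed$k * freq)
    v <- sum((observed$k - mu)^2 * freq)
    k2 <- v - if (is.null(detector)) 0 else
      predict_variance(detector, mu + background_offset)
    if (k2 <= 0 || mu <= 0) {
      eps0 <- max(mu, 1)
      N0 <- 1
    } else {
      eps0 <- k2 / (shape_factor(psf, 2) * mu)
      N0 <- mu / eps0
    }
    init <- list(N = N0, eps = eps0)
  }

  model_mass <- function(pars) {
    h <- switch(options$model,
      one_pop = compound_histogram(pars[["N"]], pars[["eps"]], psf),
      two_pop_free = convolve_histograms(
        compound_histogram(pars[["N1"]], pars[["eps1"]], psf),
        compound_histogram(pars[["N2"]], pars[["eps2"]], psf)),
      monomer_dimer = {
        e1 <- if (!is.null(options$fixed_monomer_eps))
          options$fixed_monomer_eps else pars[["eps1"]]
        convolve_histograms(
          compound_histogram(pars[["N1"]], e1, psf),
          compound_histogram(pars[["N2"]], 2 * e1, psf))
      })
    if (!is.null(detector)) h <- broaden_histogram(h, detector,
                                                   offset = background_offset)
    h
  }

  par_names <- switch(options$model,
    one_pop = c("N", "eps"),
    two_pop_free = c("N1", "eps1", "N2", "eps2"),
    monomer_dimer = if (!is.null(options$fixed_monomer_eps))
      c("N1", "N2") else c("N1", "N2", "eps1"))
  start <- switch(options$model,
    one_pop = c(N = init$N, eps = init$eps),
    two_pop_free = c(N1 = init$N1 %||% (0.7 * init$N),
                     eps1 = init$eps1 %||% (0.8 * init$eps),
                     N2 = init$N2 %||% (0.3 * init$N),
                     eps2 = init$eps2 %||% (1.6 * init$eps)),
    monomer_dimer = {
      e1 <- options$fixed_monomer_eps %||% init$eps1 %||% (0.8 * init$eps)
      mu_tot <- init$N * init$eps
      s <- c(N1 = init$N1 %||% (0.5 * mu_tot / e1),
             N2 = init$N2 %||% (0.25 * mu_tot / e1))
      if (is.null(options$fixed_monomer_eps)) s <- c(s, eps1 = e1)
      s
    })
  start <- log(pmax(start[par_names], 1e-8))

  resid_fun <- function(logp) {
    pars <- exp(logp); names(pars) <- par_names
    h <- model_mass(pars)
    mod <- numeric(sum(sel))
    kk <- observed$k[sel]
    inside <- kk < length(h$mass)
    mod[inside] <- h$mass[kk[inside] + 1L]
    wts * (mod - freq[sel])
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 150, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(estimates = NULL, stderr = NULL, residual = NA_real_,
                          fitted = NULL, converged = FALSE,
                          flags = c(flags, "non-convergence"),
                          n_pixels = A, options = options),
                     class = "spida_fit"))
  }
  pars <- exp(fit$par); names(pars) <- par_names

  # asymptotic standard errors: delta method through the log transform
  se <- rep(NA_real_, length(pars))
  cv <- tryCatch({
    dof <- max(1, sum(sel) - length(pars))
    sigma2 <- fit$deviance / dof
    jtj <- fit$hessian
    diag(solve(jtj)) * sigma2
  }, error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(cv)) && all(cv >= 0))
    se <- pars * sqrt(cv)
  names(se) <- par_names

  fitted <- model_mass(pars)
  if (options$model == "monomer_dimer") {
    e1 <- options$fixed_monomer_eps %||% pars[["eps1"]]
    pars <- c(pars, eps = unname(e1), eps2 = unname(2 * e1))
  }
  structure(list(estimates = pars, stderr = se,
                 residual = sqrt(mean((resid_fun(fit$par) / wts)^2)),
                 fitted = fitted,
                 converged = fit$info %in% 1:4,
                 flags = flags, n_pixels = A, options = options),
            class = "spida_fit")
}

#' @export
print.spida_fit <- function(x, ...) {
  cat(sprintf("SpIDA histogram fit (%s, %s)\n", x$options$model,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$estimates)) {
    for (nm in names(x$estimates))
      cat(sprintf("  %-5s %.5g (se %.3g)\n", nm, x$estimates[[nm]],
                  if (nm %in% names(x$stderr)) x$stderr[[nm]] else NA))
    cat(sprintf("  rms residual %.3g over %d pixels\n", x$residual,
                as.integer(x$n_pixels)))
  }
  invisible(x)
}

#' Plot an observed histogram against a SpIDA fit
#'
#' @param x A `spida_fit`.
#' @param observed The [intensity_histogram()] that was fitted.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_spida_fit <- function(x, observed, ...) {
  stopifnot(inherits(x, "spida_fit"), inherits(observed, "intensity_histogram"))
  freq <- observed$counts / observed$total_pixels
  graphics::plot(observed$k, freq, type = "h", col = "grey60",
                 xlab = "intensity (iu)", ylab = "frequency", ...)
  if (!is.null(x$fitted))
    graphics::lines(x$fitted$k, x$fitted$mass, col = "firebrick", lwd = 2)
  invisible(x)
}
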