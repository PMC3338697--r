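#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based, half-open, row-major: the ROI covers rows
#' `row0 .. row0 + height - 1` and columns `col0 .. col0 + width - 1`.
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels.
#' @param role `"signal"` or `"background"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(row0, col0, height, width, role = c("signal", "background")) {
  role <- match.arg(role)
  if (height < 1 || width < 1) stop_invalid("ROI must have positive extent")
  if (row0 < 0 || col0 < 0) stop_invalid("ROI coordinates are 0-based, >= 0")
  if (role == "signal" && height * width < 64)
    stop_invalid("signal ROIs must cover at least 64 pixels")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width),
                 role = role),
            class = "roi_spec")
}

#' Extract the pixels of an ROI
#'
#' @param image Numeric matrix.
#' @param roi A [roi_spec()], or `NULL` for the whole image.
#' @return Numeric vector of pixel values.
#' @export
roi_pixels <- function(image, roi = NULL) {
  if (is.null(roi)) return(as.numeric(image))
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$row0 + roi$height > nrow(image) ||
      roi$col0 + roi$width > ncol(image))
    stop_invalid("ROI exceeds image bounds")
  as.numeric(image[roi$row0 + seq_len(roi$height),
                   roi$col0 + seq_len(roi$width)])
}

#' Estimate the image background level
#'
#' The mean intensity of the background is taken from empty dark regions of
#' the image: either explicit background ROIs, or, in automatic mode, the
#' darkest 5% of all pixels.
#'
#' @param image Numeric matrix.
#' @param background_rois List of [roi_spec()] with role `"background"`, or
#'   `NULL` for automatic mode.
#' @param dark_fraction Fraction of darkest pixels used in automatic mode.
#' @return Background level in iu.
#' @export
estimate_background <- function(image, background_rois = NULL,
                                dark_fraction = 0.05) {
  if (is.null(background_rois)) {
    v <- sort(as.numeric(image))
    n <- max(1L, floor(length(v) * dark_fraction))
    return(mean(v[seq_len(n)]))
  }
  if (length(background_rois) == 0L)
    stop_invalid("empty background ROI list; use NULL for automatic mode")
  if (inherits(background_rois, "roi_spec"))
    background_rois <- list(background_rois)
  mean(unlist(lapply(background_rois, function(r) roi_pixels(image, r))))
}

#' Raw spatial moments of an ROI
#'
#' Sample mean and plain (biased, divide-by-n) central moments of orders 2-4
#' of the background-corrected pixel values. No small-sample bias correction
#' is applied; analysis regions are required to be large enough that it is
#' negligible.
#'
#' @param pixels Numeric vector of background-corrected pixel values,
#'   at least 64 of them.
#' @return List with `mean`, `mu2`, `mu3`, `mu4`, `n_pixels`.
#' @export
compute_raw_moments <- function(pixels) {
  if (length(pixels) < 64)
    stop_invalid("need at least 64 pixels for moment estimation")
  m <- mean(pixels)
  d <- pixels - m
  list(mean = m,
       mu2 = mean(d^2),
       mu3 = mean(d^3),
       mu4 = mean(d^4),
       n_pixels = length(pixels))
}

#' Correct spatial moments for analog detector noise
#'
#' The detector adds, conditionally on the true intensity I of each pixel, a
#' Gaussian read-out fluctuation of variance `intercept + slope * I`. Writing
#' `s` for the slope and `c` for the intercept, the cumulant generating
#' function of the measured value M = I + eta is
#' \eqn{K_M(t) = c t^2/2 + K_I(t + s t^2/2)}, from which the cumulants of the
#' noise-free field follow:
#' \deqn{\kappa_2 = \mu_2 - (c + s\langle I\rangle)}
#' \deqn{\kappa_3 = \mu_3 - 3 s \kappa_2}
#' \deqn{\kappa_4 = (\mu_4 - 3\mu_2^2) - 6 s \kappa_3 - 3 s^2 \kappa_2}
#' where \eqn{\mu_n} are the measured central moments. With a zero detector
#' this reduces to the identity on cumulants
#' (\eqn{\kappa_4 = \mu_4 - 3\mu_2^2}).
#'
#' @param raw List from [compute_raw_moments()].
#' @param detector A [detector_model()] or `NULL` (identity correction).
#' @param background Background level subtracted from the pixels before the
#'   moments were computed; the detector saw `mean + background`, so the noise
#'   variance is evaluated there.
#' @return An object of class `moment_set` with fields `mean`, `kappa2`,
#'   `kappa3`, `kappa4`, the raw central moments, `n_pixels` and a `flag`
#'   (`"ok"` or `"overcorrected"` when kappa2 came out negative, which signals
#'   a mean outside the detector's linear range).
#' @export
correct_moments <- function(raw, detector = NULL, background = 0) {
  s <- 0; cc <- 0
  if (!is.null(detector)) {
    stopifnot(inherits(detector, "detector_model"))
    s <- detector$slope
    cc <- detector$intercept
    if (raw$mean + background > detector$linear_max)
      warning("mean intensity above the detector's validated linear range")
  }
  noise_var <- cc + s * (raw$mean + background)
  k2 <- raw$mu2 - noise_var
  k3 <- raw$mu3 - 3 * s * k2
  k4 <- (raw$mu4 - 3 * raw$mu2^2) - 6 * s * k3 - 3 * s^2 * k2
  flag <- if (k2 < 0) "overcorrected" else "ok"
  structure(
    list(mean = raw$mean, kappa2 = k2, kappa3 = k3, kappa4 = k4,
         raw_mu2 = raw$mu2, raw_mu3 = raw$mu3, raw_mu4 = raw$mu4,
         n_pixels = raw$n_pixels, flag = flag),
    class = "moment_set"
  )
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf(
    "Noise-corrected spatial cumulants (%d pixels, %s)\n  mean %.4g  k2 %.4g  k3 %.4g  k4 %.4g\n",
    x$n_pixels, x$flag, x$mean, x$kappa2, x$kappa3, x$kappa4))
  invisible(x)
}

#' Convenience: corrected moments of an image ROI
#'
#' Subtracts the background, computes raw moments over the signal ROI and
#' corrects them for detector noise.
#'
#' @param image Numeric matrix.
#' @param detector A [detector_model()] or `NULL`.
#' @param background Background level (iu); `NULL` to estimate automatically.
#' @param roi Signal [roi_spec()] or `NULL` for the whole image.
#' @return A `moment_set`.
#' @export
image_moments <- function(image, detector = NULL, background = NULL,
                          roi = NULL) {
  if (is.null(background)) background <- estimate_background(image)
  px <- roi_pixels(image, roi) - background
  correct_moments(compute_raw_moments(px), detector, background = background)
}

#' One-population moment inversion
#'
#' For a single species the mean and second cumulant determine brightness and
#' density: `eps = kappa2 / (gamma2 * mean)` and `N = mean / eps` (entities
#' per beam area), so that `mean = N * eps` and `kappa2 = gamma2 * N * eps^2`
#' hold exactly.
#'
#' @param m A `moment_set` (or any list with `mean` and `kappa2`).
#' @param psf A [psf_model()].
#' @return List with `N` (entities per beam area), `eps` (iu) and
#'   `density_um2` (entities per square micrometre).
#' @export
solve_one_population <- function(m, psf) {
  if (m$kappa2 <= 0)
    stop_invalid("no signal: corrected kappa2 <= 0")
  if (m$mean <= 0)
    stop_invalid("mean intensity must be positive")
  g2 <- shape_factor(psf, 2)
  eps <- unname(m$kappa2 / (g2 * m$mean))
  N <- unname(m$mean / eps)
  list(N = N, eps = eps, density_um2 = N / psf$beam_area)
}

# Forward cumulants of a two-population compound field: kappa_n =
# gamma_n (N1 eps1^n + N2 eps2^n). Used by the solver and by tests.
#' Forward cumulants of a one- or two-population field
#'
#' @param N1,eps1,N2,eps2 Densities (per beam area) and brightnesses (iu).
#' @param psf A [psf_model()].
#' @return Named vector `c(mean, kappa2, kappa3, kappa4)`.
#' @export
forward_cumulants <- function(N1, eps1, N2 = 0, eps2 = 0, psf) {
  n <- 1:4
  g <- shape_factor(psf, n)
  k <- g * (N1 * eps1^n + N2 * eps2^n)
  names(k) <- c("mean", "kappa2", "kappa3", "kappa4")
  k
}

#' Two-population moment inversion
#'
#' Solves the four cumulant relations
#' \eqn{\kappa_n = \gamma_n (N_1\epsilon_1^n + N_2\epsilon_2^n)}, n = 1..4,
#' for the densities and brightnesses of a two-species mixture.
#'
#' The reduced moments \eqn{a_n = \kappa_n/\gamma_n} are the power sums of a
#' two-point mass distribution, so the system is first solved exactly by the
#' classical method of moments (Prony): \eqn{\epsilon_{1,2}} are the roots of
#' the quadratic built from the 2x2 Hankel system, and the densities follow
#' from a linear solve. On noisy cumulants, or whenever the algebraic solve is
#' invalid (complex roots, negative densities), a damped least-squares refit
#' of the four relative residuals in log-parameter space is run from a
#' multistart grid (brightness ratios 1.5, 2, 4, 8 crossed with monomer-heavy
#' and oligomer-heavy splits) and the lowest-residual solution is kept.
#'
#' When the two-population fit does not reduce the residual to below
#' `accept_ratio` times the one-population residual, the result falls back to
#' the one-population solution with `N2 = 0`.
#'
#' @param m A `moment_set`.
#' @param psf A [psf_model()].
#' @param fix_alpha Optional fixed brightness ratio `eps2/eps1` (e.g. 2 for a
#'   monomer-dimer mixture); then only the first three cumulants are used.
#' @param accept_ratio Residual ratio below which the two-population model is
#'   preferred over the one-population fallback.
#' @return An object of class `two_population_result`: `N1`, `eps1`, `N2`,
#'   `eps2` (ordered `eps1 <= eps2`), `alpha = eps2/eps1`, `converged`,
#'   `residual`, `model` (`"two_pop"` or `"one_pop"`).
#' @export
solve_two_populations <- function(m, psf, fix_alpha = NULL,
                                  accept_ratio = 0.25) {
  k <- unname(c(m$mean, m$kappa2, m$kappa3, m$kappa4))
  need <- if (is.null(fix_alpha)) 4L else 3L   # fixed ratio: 3 equations
  if (!all(is.finite(k[seq_len(need)])))
    stop_invalid("cumulants must all be finite")
  if (m$kappa2 <= 0) stop_invalid("no signal: corrected kappa2 <= 0")
  g <- shape_factor(psf, 1:4)
  a <- k / g

  one <- solve_one_population(m, psf)
  resid_of <- function(N1, e1, N2, e2, nord = 4L) {
    kk <- forward_cumulants(N1, e1, N2, e2, psf)[seq_len(nord)]
    sqrt(mean(((kk - k[seq_len(nord)]) / pmax(abs(k[seq_len(nord)]), 1e-12))^2))
  }
  one_res <- resid_of(one$N, one$eps, 0, 0)

  result <- function(N1, e1, N2, e2, res, converged, model) {
    # order populations by brightness; an empty second population stays second
    if (e2 < e1 && N2 > 0) {
      tmp <- c(N1, e1); N1 <- N2; e1 <- e2; N2 <- tmp[1]; e2 <- tmp[2]
    }
    structure(list(N1 = N1, eps1 = e1, N2 = N2, eps2 = e2,
                   alpha = if (e1 > 0) e2 / e1 else NA_real_,
                   converged = converged, residual = res, model = model,
                   density1_um2 = N1 / psf$beam_area,
                   density2_um2 = N2 / psf$beam_area),
              class = "two_population_result")
  }

  if (!is.null(fix_alpha)) {
    sol <- fit_two_pop_ls(k[1:3], psf, alpha = fix_alpha, init = one,
                          nord = 3L)
    res2 <- resid_of(sol$N1, sol$eps1, sol$N2, sol$eps2, nord = 3L)
    one_res3 <- resid_of(one$N, one$eps, 0, 0, nord = 3L)
    if (!sol$converged || res2 > accept_ratio * max(one_res3, 1e-12))
      return(result(one$N, one$eps, 0, 0, one_res3, TRUE, "one_pop"))
    return(result(sol$N1, sol$eps1, sol$N2, sol$eps2, res2, TRUE, "two_pop"))
  }

  # exact algebraic (Prony) inversion of the power sums
  prony <- NULL
  D <- a[2]^2 - a[1] * a[3]
  if (abs(D) > 1e-10 * max(a[2]^2, abs(a[1] * a[3]))) {
    p <- (a[3] * a[2] - a[1] * a[4]) / D
    q <- (a[2] * a[4] - a[3]^2) / D
    disc <- p^2 + 4 * q
    if (disc > 0) {
      e1 <- (p - sqrt(disc)) / 2
      e2 <- (p + sqrt(disc)) / 2
      if (e1 > 0 && e2 > 0 && e2 > e1) {
        det <- e1 * e2^2 - e2 * e1^2
        N1 <- (a[1] * e2^2 - a[2] * e2) / det
        N2 <- (a[2] * e1 - a[1] * e1^2) / det
        if (N1 >= 0 && N2 >= 0) prony <- list(N1 = N1, eps1 = e1,
                                              N2 = N2, eps2 = e2)
      }
    }
  }

  best <- NULL
  if (!is.null(prony)) {
    best <- prony
    best$res <- resid_of(prony$N1, prony$eps1, prony$N2, prony$eps2)
  }
  if (is.null(best) || best$res > 1e-8) {
    starts <- list()
    for (alpha0 in c(1.5, 2, 4, 8))
      for (split in c(0.8, 0.2)) {
        e1 <- one$eps / (split + (1 - split) * alpha0)
        starts[[length(starts) + 1L]] <-
          list(N1 = split * one$N, eps1 = e1,
               N2 = (1 - split) * one$N, eps2 = alpha0 * e1)
      }
    if (!is.null(prony)) starts[[length(starts) + 1L]] <- prony
    for (st in starts) {
      sol <- fit_two_pop_ls(k, psf, alpha = NULL, init = st, nord = 4L)
      if (!sol$converged) next
      res <- resid_of(sol$N1, sol$eps1, sol$N2, sol$eps2)
      if (is.null(best) || res < best$res)
        best <- list(N1 = sol$N1, eps1 = sol$eps1, N2 = sol$N2,
                     eps2 = sol$eps2, res = res)
    }
  }

  if (is.null(best))
    return(result(one$N, one$eps, 0, 0, one_res, FALSE, "one_pop"))
  # degenerate two-population solutions collapse to one population
  distinct <- best$N2 > 1e-6 * best$N1 && best$N1 > 1e-6 * best$N2 &&
    abs(best$eps2 - best$eps1) > 1e-4 * best$eps2
  if (!distinct || best$res > accept_ratio * max(one_res, 1e-12))
    return(result(one$N, one$eps, 0, 0, one_res, TRUE, "one_pop"))
  result(best$N1, best$eps1, best$N2, best$eps2, best$res, TRUE, "two_pop")
}

# Damped least squares on the cumulant residuals in log-parameter space.
# With `alpha` fixed the parameters are (N1, N2, eps1); free otherwise.
fit_two_pop_ls <- function(k, psf, alpha = NULL, init, nord = 4L) {
  g <- shape_factor(psf, seq_len(nord))
  scale <- pmax(abs(k), 1e-12)
  resid_fun <- function(par) {
    p <- exp(par)
    if (is.null(alpha)) {
      N1 <- p[1]; e1 <- p[2]; N2 <- p[3]; e2 <- p[4]
    } else {
      N1 <- p[1]; N2 <- p[2]; e1 <- p[3]; e2 <- alpha * e1
    }
    n <- seq_len(nord)
    (g * (N1 * e1^n + N2 * e2^n) - k) / scale
  }
  start <- if (is.null(alpha))
    log(pmax(c(init$N1 %||% init$N, init$eps1 %||% init$eps,
               init$N2 %||% (0.1 * init$N), init$eps2 %||% (2 * init$eps)),
             1e-8))
  else
    log(pmax(c(0.7 * (init$N1 %||% init$N), 0.3 * (init$N1 %||% init$N),
               (init$eps1 %||% init$eps) / (0.7 + 0.3 * alpha)), 1e-8))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(converged = FALSE))
  p <- exp(fit$par)
  if (is.null(alpha))
    list(N1 = p[1], eps1 = p[2], N2 = p[3], eps2 = p[4], converged = TRUE)
  else
    list(N1 = p[1], eps1 = p[3], N2 = p[2], eps2 = alpha * p[3],
         converged = TRUE)
}

#' @export
print.two_population_result <- function(x, ...) {
  cat(sprintf("Two-population moment solution (%s, residual %.3g)\n",
              x$model, x$residual))
  cat(sprintf("  pop 1: N = %.4g per BA, eps = %.4g iu\n", x$N1, x$eps1))
  cat(sprintf("  pop 2: N = %.4g per BA, eps = %.4g iu (alpha = %.3g)\n",
              x$N2, x$eps2, x$alpha))
  invisible(x)
}

#' Tile-averaged moments for heterogeneous images
#'
#' Subdivides a signal ROI into overlapping square tiles, computes per-tile
#' moments, discards tiles whose mean deviates more than `max_dev` from the
#' median tile mean (bright aggregates, vesicles, dark voids), and averages
#' the surviving tiles' raw moments before the detector correction.
#'
#' @param image Numeric matrix.
#' @param detector A [detector_model()] or `NULL`.
#' @param background Background level (iu); `NULL` to estimate automatically.
#' @param tile Tile edge in pixels.
#' @param step Tile step (defaults to half a tile: 50% overlap).
#' @param max_dev Maximum relative deviation of a tile mean from the median.
#' @return A `moment_set` averaged over retained tiles, with attribute
#'   `n_tiles` = c(used, total).
#' @export
tile_moments <- function(image, detector = NULL, background = NULL,
                         tile = 128L, step = tile %/% 2L, max_dev = 0.5) {
  if (is.null(background)) background <- estimate_background(image)
  nr <- nrow(image); nc <- ncol(image)
  tile <- min(tile, nr, nc)
  r0s <- unique(pmin(seq(0L, nr - tile, by = step), nr - tile))
  c0s <- unique(pmin(seq(0L, nc - tile, by = step), nc - tile))
  raws <- list()
  for (r0 in r0s) for (c0 in c0s) {
    px <- as.numeric(image[r0 + seq_len(tile), c0 + seq_len(tile)]) - background
    raws[[length(raws) + 1L]] <- compute_raw_moments(px)
  }
  means <- vapply(raws, `[[`, numeric(1), "mean")
  med <- median(means)
  keep <- abs(means - med) <= max_dev * abs(med)
  if (!any(keep)) keep <- rep(TRUE, length(raws))
  avg <- function(f) mean(vapply(raws[keep], `[[`, numeric(1), f))
  raw <- list(mean = avg("mean"), mu2 = avg("mu2"), mu3 = avg("mu3"),
              mu4 = avg("mu4"),
              n_pixels = sum(vapply(raws[keep], `[[`, numeric(1), "n_pixels")))
  out <- correct_moments(raw, detector, background = background)
  attr(out, "n_tiles") <- c(used = sum(keep), total = length(raws))
  out
}
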