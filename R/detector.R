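#' Analog PMT detector noise model
#'
#' An analog photomultiplier converts photon flux to an intensity reading
#' whose variance grows linearly with the mean signal. The model is the
#' straight line `variance = intercept + slope * mean`, valid for means up to
#' `linear_max`; `intercept` is the dark-noise variance.
#'
#' @param slope Variance gained per intensity unit of mean signal (iu).
#' @param intercept Dark-noise variance (iu^2).
#' @param linear_max Upper bound of the validated linear range (iu).
#' @param saturation Detector full scale (iu), e.g. 65535 for 16-bit output.
#' @param stderr_slope,stderr_intercept Standard errors from the calibration
#'   fit, if known.
#' @return An object of class `detector_model`.
#' @seealso [fit_detector_noise()] to calibrate the model from data,
#'   [predict_variance()] for the fitted line.
#' @export
detector_model <- function(slope, intercept = 0, linear_max = saturation,
                           saturation = 65535,
                           stderr_slope = NA_real_,
                           stderr_intercept = NA_real_) {
  if (slope < 0) stop_invalid("detector `slope` must be >= 0")
  if (intercept < 0) stop_invalid("detector `intercept` must be >= 0")
  if (linear_max <= 0 || linear_max > saturation)
    stop_invalid("need 0 < linear_max <= saturation")
  structure(
    list(slope = slope, intercept = intercept, linear_max = linear_max,
         saturation = saturation, stderr_slope = stderr_slope,
         stderr_intercept = stderr_intercept),
    class = "detector_model"
  )
}

#' @export
print.detector_model <- function(x, ...) {
  cat("Analog detector noise model: variance = intercept + slope * mean\n")
  cat(sprintf("  slope:      %.5g (se %.3g)\n", x$slope, x$stderr_slope))
  cat(sprintf("  intercept:  %.5g (se %.3g)\n", x$intercept, x$stderr_intercept))
  cat(sprintf("  linear up to %.5g iu, saturation %.5g iu\n",
              x$linear_max, x$saturation))
  invisible(x)
}

#' Predicted detector variance at a given mean intensity
#'
#' @param detector A [detector_model()].
#' @param mean_iu Mean intensity (iu); vectorized.
#' @return Predicted variance `intercept + slope * mean_iu` (iu^2).
#' @export
predict_variance <- function(detector, mean_iu) {
  stopifnot(inherits(detector, "detector_model"))
  detector$intercept + detector$slope * pmax(mean_iu, 0)
}

#' Calibrate the detector noise law from mean/variance pairs
#'
#' Fits the linear variance-versus-mean law of an analog PMT from a uniform
#' illumination control recording. Only the initial (linear) part of the curve
#' is used: starting from the lowest 20% of means (at least three points),
#' the fitted range is extended
#' one point at a time for as long as the fit stays essentially linear
#' (R^2 >= `r2_min`) and the newly added point is not an outlier (absolute
#' residual below 3 residual standard errors of the previous fit). `linear_max`
#' is set to the largest mean retained.
#'
#' @param pairs A data frame (or two-column matrix) with columns `mean` and
#'   `variance`, one row per illumination level.
#' @param r2_min Minimum R^2 for accepting an extended range (default 0.99).
#' @param saturation Detector full scale recorded in the returned model.
#' @return A [detector_model()] with `slope`, `intercept`, their standard
#'   errors, and `linear_max` set to the detected cutoff.
#' @examples
#' d <- data.frame(mean = 0:20 * 5, variance = 2 + 0.5 * (0:20 * 5))
#' fit_detector_noise(d)
#' @export
fit_detector_noise <- function(pairs, r2_min = 0.99, saturation = 65535) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2) stop_invalid("`pairs` needs columns mean and variance")
  names(pairs)[1:2] <- c("mean", "variance")
  if (any(!is.finite(pairs$mean)) || any(!is.finite(pairs$variance)))
    stop_invalid("non-finite values in calibration pairs")
  if (any(pairs$variance < 0))
    stop_invalid("negative variance in calibration input")
  if (any(pairs$mean < 0))
    stop_invalid("negative mean in calibration input")
  pairs <- pairs[order(pairs$mean), , drop = FALSE]
  if (length(unique(pairs$mean)) < 3)
    stop_invalid("need >= 3 pairs with distinct means")
  if (length(unique(pairs$mean)) == 1L)
    stop_invalid("degenerate fit: all means identical")

  n <- nrow(pairs)
  scale_v <- max(abs(pairs$variance), 1)

  fit_range <- function(k) lm(variance ~ mean, data = pairs[seq_len(k), ])
  r2_of <- function(fit) {
    tss <- sum((fit$model$variance - mean(fit$model$variance))^2)
    rss <- sum(fit$residuals^2)
    if (rss <= 1e-10 * scale_v^2) return(1)     # exact line (incl. flat zero)
    if (tss == 0) return(0)
    1 - rss / tss
  }

  k <- max(3L, as.integer(ceiling(0.2 * n)))
  fit <- fit_range(k)
  while (k < n) {
    prev <- fit
    sigma <- sqrt(sum(prev$residuals^2) / max(1, prev$df.residual))
    cand <- fit_range(k + 1L)
    new_resid <- abs(cand$residuals[k + 1L])
    tol <- if (sigma > 1e-8 * scale_v) 3 * sigma else 1e-6 * scale_v
    if (r2_of(cand) >= r2_min && new_resid < tol) {
      k <- k + 1L
      fit <- cand
    } else break
  }

  # summary.lm warns on an exactly collinear (noise-free) fit; harmless here
  cf <- suppressWarnings(summary(fit)$coefficients)
  slope <- unname(cf["mean", "Estimate"])
  intercept <- unname(cf["(Intercept)", "Estimate"])
  # tiny negative estimates from noise are clipped to the physical range
  detector_model(
    slope = max(slope, 0),
    intercept = max(intercept, 0),
    linear_max = pairs$mean[k],
    saturation = saturation,
    stderr_slope = unname(cf["mean", "Std. Error"]),
    stderr_intercept = unname(cf["(Intercept)", "Std. Error"])
  )
}

#' Reduce a uniform-illumination point-scan trace to mean/variance pairs
#'
#' Splits an intensity time trace recorded under uniform illumination into
#' non-overlapping windows and reduces each window to its sample mean and
#' variance, the input expected by [fit_detector_noise()].
#'
#' @param trace Numeric vector of intensity samples (iu).
#' @param window Window length in samples; at least 16, at most `length(trace)`.
#' @return Data frame with columns `mean` and `variance`, one row per window.
#' @export
variance_trace_from_pointscan <- function(trace, window) {
  if (!is.numeric(trace)) stop_invalid("`trace` must be numeric")
  window <- as.integer(window)
  if (window < 16L) stop_invalid("`window` must be >= 16 samples")
  if (window > length(trace))
    stop_invalid("`window` longer than the trace")
  nw <- length(trace) %/% window
  idx <- rep(seq_len(nw), each = window)
  x <- trace[seq_len(nw * window)]
  data.frame(
    mean = as.numeric(tapply(x, idx, mean)),
    variance = as.numeric(tapply(x, idx, var))
  )
}

#' Read or write a detector model as JSON
#'
#' @param detector A [detector_model()].
#' @param path File path.
#' @return `read_detector_json()` returns a [detector_model()];
#'   `write_detector_json()` invisibly returns `path`.
#' @export
write_detector_json <- function(detector, path) {
  stopifnot(inherits(detector, "detector_model"))
  x <- unclass(detector)
  x <- lapply(x, function(v) if (is.numeric(v) && is.infinite(v)) NULL else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_detector_json
#' @export
read_detector_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm_max <- x$linear_max %||% Inf
  if (is.na(lm_max)) lm_max <- Inf
  detector_model(
    slope = x$slope, intercept = x$intercept,
    linear_max = lm_max,
    saturation = x$saturation %||% 65535,
    stderr_slope = x$stderr_slope %||% NA_real_,
    stderr_intercept = x$stderr_intercept %||% NA_real_
  )
}
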