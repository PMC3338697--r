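#' Load a single-channel grayscale image from TIFF
#'
#' Reads integer pixel data as stored (no rescaling) and records the bit
#' depth and the corresponding saturation level `2^depth - 1`.
#'
#' @param path TIFF file path.
#' @param bit_depth Optional hint overriding the container's bit depth, e.g.
#'   12 for 12-bit data stored in a 16-bit container.
#' @return List with `image` (integer matrix), `bit_depth`, `saturation`.
#' @export
load_image <- function(path, bit_depth = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = FALSE,
                                 info = TRUE),
                  error = function(e)
                    stop_invalid("unsupported image format: ",
                                 conditionMessage(e)))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop_invalid("multi-channel image; extract one channel first")
  }
  depth <- attr(img, "bits.per.sample") %||%
    (if (max(img) > 255) 16L else 8L)
  if (!is.null(bit_depth)) depth <- bit_depth
  list(image = matrix(as.numeric(img), nrow(img), ncol(img)),
       bit_depth = as.integer(depth),
       saturation = 2^as.integer(depth) - 1)
}

#' Write an integer image to TIFF
#'
#' @param image Integer-valued matrix.
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @export
write_image_tiff <- function(image, path, bits = 16L) {
  scale <- 2^bits - 1
  if (max(image) > scale) stop_invalid("pixel values exceed ", bits, "-bit range")
  tiff::writeTIFF(image / scale, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Batch analysis of an image set
#'
#' Runs the same analysis (moment inversion or SpIDA histogram fit) on every
#' image of a set acquired under one shared configuration, one row per
#' image/cell. A failure on one image is recorded in its row and never aborts
#' the batch. Inputs are processed in sorted name order, so results are
#' invariant to the ordering of `images`.
#'
#' @param images Named list of integer matrices, or a character vector of
#'   TIFF paths.
#' @param method `"moments"` or `"spida"`.
#' @param psf A [psf_model()].
#' @param detector A [detector_model()] or `NULL`.
#' @param background Background level (iu), or `NULL` to estimate per image.
#' @param options A [spida_fit_options()] for `method = "spida"`.
#' @return Data frame with one row per image: `id`, `mean`, `kappa2`, `N`,
#'   `eps`, `density_um2`, `error` (NA or the failure message).
#' @export
batch_analyze <- function(images, method = c("moments", "spida"), psf,
                          detector = NULL, background = NULL,
                          options = spida_fit_options()) {
  method <- match.arg(method)
  from_paths <- is.character(images)
  ids <- if (from_paths) images else
    (names(images) %||% sprintf("image_%03d", seq_along(images)))
  ord <- order(ids)
  rows <- lapply(ord, function(i) {
    id <- ids[i]
    tryCatch({
      img <- if (from_paths) load_image(images[i])$image else images[[i]]
      bg <- background %||% estimate_background(img)
      if (method == "moments") {
        m <- image_moments(img, detector, background = bg)
        sol <- solve_one_population(m, psf)
        data.frame(id = id, mean = m$mean, kappa2 = m$kappa2, N = sol$N,
                   eps = sol$eps, density_um2 = sol$density_um2,
                   error = NA_character_)
      } else {
        obs <- image_to_histogram(img, background = bg)
        fit <- fit_histogram(obs, options, psf, detector,
                             background_offset = bg)
        if (!fit$converged) stop("SpIDA fit did not converge")
        est <- fit$estimates
        getv <- function(nm) if (nm %in% names(est)) est[[nm]] else NULL
        N <- getv("N") %||% (getv("N1") + getv("N2"))
        eps <- getv("eps") %||% getv("eps1")
        data.frame(id = id, mean = sum(obs$k * obs$counts) / obs$total_pixels,
                   kappa2 = NA_real_, N = N, eps = eps,
                   density_um2 = N / psf$beam_area, error = NA_character_)
      }
    }, error = function(e)
      data.frame(id = id, mean = NA_real_, kappa2 = NA_real_, N = NA_real_,
                 eps = NA_real_, density_um2 = NA_real_,
                 error = conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a group of per-cell values
#'
#' @param values Numeric vector (MEU or density), one value per cell.
#' @param label Group label.
#' @return An object of class `group_summary`: `label`, `values`, `mean`,
#'   `sem` (NA for a single cell — the SEM is undefined at n = 1), `n_cells`.
#' @export
summarize_group <- function(values, label = "group") {
  values <- as.numeric(values)
  if (length(values) < 1) stop_invalid("need at least one value")
  structure(list(label = label, values = values, mean = mean(values),
                 sem = if (length(values) > 1)
                   sd(values) / sqrt(length(values)) else NA_real_,
                 n_cells = length(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: mean %.4g +/- %.3g (SEM), n = %d cells\n",
              x$label, x$mean, x$sem, x$n_cells))
  invisible(x)
}

#' Percent-occurrence histogram of per-cell values
#'
#' Bins values into intervals of width `bin_width` centered on integer
#' multiples of the width (so MEU values near 1, 2, ... fall into the 1, 2,
#' ... bins) and reports percent occurrence summing to 100.
#'
#' @param values Numeric vector (e.g. MEU).
#' @param bin_width Bin width in the same units.
#' @return Data frame with columns `center` and `percent`.
#' @export
occurrence_histogram <- function(values, bin_width = 0.5) {
  if (length(values) < 1) stop_invalid("need at least one value")
  idx <- round(values / bin_width)
  tab <- table(idx)
  data.frame(center = as.numeric(names(tab)) * bin_width,
             percent = 100 * as.numeric(tab) / length(values))
}

#' Nonparametric two-group comparison
#'
#' Two-sided Mann-Whitney rank-sum test between two groups of per-cell
#' values: exact for group sizes up to 20 without ties, normal approximation
#' with tie correction otherwise. Significance stars follow the conventional
#' thresholds (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns`
#' otherwise); a p-value exactly at a threshold gets the weaker label.
#'
#' @param a,b Numeric vectors, each with at least 3 values.
#' @return An object of class `comparison_result`: `statistic` (Mann-Whitney
#'   U), `p_value`, `stars`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop_invalid("need at least 3 values per group")
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact))
  p <- min(wt$p.value, 1)
  structure(list(statistic = unname(wt$statistic), p_value = p,
                 stars = star_label(p), n = c(length(a), length(b)),
                 exact = exact),
            class = "comparison_result")
}

#' @rdname compare_groups
#' @param p A p-value.
#' @export
star_label <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney test (%s): U = %g, p = %.4g  [%s]\n",
              if (x$exact) "exact" else "normal approx.",
              x$statistic, x$p_value, x$stars))
  invisible(x)
}
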