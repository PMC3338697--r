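#' Build the monomeric brightness control
#'
#' Aggregates per-cell quantal brightness estimates of a known-monomeric
#' control sample (e.g. membrane-targeted monomeric EGFP, or a single-dye
#' monolayer) into the yardstick that defines 1 monomeric equivalent unit
#' (MEU). The control mean is the unweighted mean across cells and its error
#' the standard error of that mean. Cells deviating more than 3 standard
#' deviations from the mean are flagged as possible aggregates but retained.
#'
#' @param per_cell_eps Numeric vector of per-cell brightness estimates (iu),
#'   or a data frame with columns `eps` and optionally `err`.
#' @param acquisition_tag Identifier of the imaging-condition set (controls
#'   and samples are only comparable within one set).
#' @return An object of class `calibration_result`: `eps_monomer`, `sem`,
#'   `n_cells`, `acquisition_tag`, `flagged` (indices of outlier cells).
#' @export
build_monomer_control <- function(per_cell_eps, acquisition_tag = "default") {
  eps <- if (is.data.frame(per_cell_eps)) per_cell_eps$eps else
    as.numeric(per_cell_eps)
  if (length(eps) < 3)
    stop_invalid("need at least 3 cells for a monomeric control")
  m <- mean(eps)
  s <- sd(eps)
  flagged <- if (s > 0) which(abs(eps - m) > 3 * s) else integer(0)
  structure(list(eps_monomer = m, sem = s / sqrt(length(eps)),
                 n_cells = length(eps), acquisition_tag = acquisition_tag,
                 flagged = flagged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Monomeric control [%s]: eps = %.4g +/- %.3g iu (n = %d cells)\n",
              x$acquisition_tag, x$eps_monomer, x$sem, x$n_cells))
  if (length(x$flagged))
    cat("  flagged possible aggregates: cells", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Normalize a brightness to monomeric equivalent units (MEU)
#'
#' Expresses a quantal brightness as a multiple of the monomeric control:
#' `value = eps / eps_monomer`, with first-order error propagation in
#' quadrature, `err = value * sqrt((err_eps/eps)^2 + (sem/eps_monomer)^2)`.
#' A dimer without quenching reads ~2 MEU.
#'
#' @param eps Brightness to normalize (iu).
#' @param err Its standard error (iu).
#' @param cal A [build_monomer_control()] result.
#' @param acquisition_tag Tag of the measurement; must match the calibration.
#' @return List with `value` (MEU) and `err` (MEU).
#' @export
normalize_to_meu <- function(eps, err = 0, cal,
                             acquisition_tag = cal$acquisition_tag) {
  stopifnot(inherits(cal, "calibration_result"))
  if (!identical(acquisition_tag, cal$acquisition_tag))
    stop_invalid("acquisition tag mismatch: calibration is for '",
                 cal$acquisition_tag, "', measurement is '",
                 acquisition_tag, "'")
  value <- eps / cal$eps_monomer
  rel2 <- (err / eps)^2 + (cal$sem / cal$eps_monomer)^2
  list(value = value, err = abs(value) * sqrt(rel2))
}

#' Surface-density versus solution-concentration calibration curve
#'
#' For dye-monolayer control samples, fits the saturating single-exponential
#' relation between the 2D surface density bound to the glass and the bulk
#' dye concentration in solution,
#' \deqn{D(c) = D_{max} (1 - e^{-c/c_0}),}
#' which is linear (`D ~ (D_max/c0) c`) at low concentration and saturates
#' sterically at high concentration.
#'
#' @param pairs Data frame with columns `concentration` (ug/mL, > 0) and
#'   `density` (per square micrometre), at least 4 rows.
#' @return List with `D_max`, `c0`, their standard errors, `fitted` values
#'   and `converged`.
#' @export
fit_density_concentration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("concentration", "density")
  if (nrow(pairs) < 4) stop_invalid("need at least 4 concentration points")
  if (any(pairs$concentration <= 0))
    stop_invalid("concentrations must be > 0")
  d_max0 <- max(pairs$density)
  c00 <- median(pairs$concentration)
  fit <- tryCatch(
    minpack.lm::nlsLM(density ~ D_max * (1 - exp(-concentration / c0)),
                      data = pairs,
                      start = list(D_max = d_max0, c0 = c00),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(D_max = NA_real_, c0 = NA_real_, stderr = c(NA, NA),
                fitted = NULL, converged = FALSE))
  cf <- summary(fit)$coefficients
  list(D_max = cf["D_max", "Estimate"], c0 = cf["c0", "Estimate"],
       stderr = c(D_max = cf["D_max", "Std. Error"],
                  c0 = cf["c0", "Std. Error"]),
       fitted = stats::fitted(fit), converged = TRUE)
}

#' Read or write a monomeric calibration as JSON
#'
#' @param cal A `calibration_result`.
#' @param path File path.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_result"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(eps_monomer = x$eps_monomer, sem = x$sem,
                 n_cells = x$n_cells, acquisition_tag = x$acquisition_tag,
                 flagged = as.integer(x$flagged %||% integer(0))),
            class = "calibration_result")
}
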