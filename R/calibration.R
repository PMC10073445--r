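#' Construct a counts-to-concentration calibration model
#'
#' Linear map between reconstructed counts per cc and activity concentration
#' in uCi/cc: `counts/cc = slope * conc + intercept`. A fitted model carries
#' the Pearson r, its two-sided p value, and the number of calibration
#' points; models built directly from known coefficients leave those fields
#' `NA`.
#'
#' @param slope counts per cc per (uCi/cc); must be positive for a usable
#'   model.
#' @param intercept counts per cc at zero concentration (background plateau).
#' @param fit_r,fit_p,n_points fit diagnostics (optional).
#' @param threshold_pct iso-contour threshold (% of maximum) used when
#'   extracting the calibration counts, recorded for provenance.
#' @return A `calibration_model` object.
#' @examples
#' m <- calibration_model(6807.3, 39.0)
#' counts_to_concentration(m, 6846.3)  # 1 uCi/cc
#' @export
calibration_model <- function(slope, intercept, fit_r = NA_real_,
                              fit_p = NA_real_, n_points = NA_integer_,
                              threshold_pct = NA_real_) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (!is.na(fit_r) && abs(fit_r) > 1 + 1e-12) stop("fit_r must lie in [-1, 1]")
  structure(list(slope = slope, intercept = intercept, fit_r = fit_r,
                 fit_p = fit_p, n_points = as.integer(n_points),
                 threshold_pct = threshold_pct,
                 units = "counts/cc = slope * uCi/cc + intercept"),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: counts/cc = %.6g x uCi/cc + %.6g\n",
              x$slope, x$intercept))
  if (!is.na(x$fit_r))
    cat(sprintf("  fit: r = %.4f, p = %.3g, n = %d\n", x$fit_r, x$fit_p,
                x$n_points))
  if (!is.na(x$threshold_pct))
    cat(sprintf("  extraction threshold: %.1f%%\n", x$threshold_pct))
  invisible(x)
}

#' Fit the calibration regression from phantom measurements
#'
#' Ordinary least squares of mean counts per cc on known activity
#' concentration, the standardization regression used to convert
#' reconstructed counts into uCi/cc.
#'
#' @param counts_per_cc numeric vector, mean reconstructed counts per cc for
#'   each calibration phantom.
#' @param concentration numeric vector, true concentration in uCi/cc.
#' @param threshold_pct optional iso-contour threshold recorded as provenance.
#' @return A [calibration_model()] with `fit_r`, `fit_p` and `n_points` set.
#' @examples
#' conc <- c(0.77, 1.5, 2.4, 3.2, 4.09)
#' cts <- 6807.3 * conc + 39.0
#' fit_calibration(cts, conc)
#' @export
fit_calibration <- function(counts_per_cc, concentration,
                            threshold_pct = NA_real_) {
  if (length(counts_per_cc) != length(concentration))
    stop("counts_per_cc and concentration must have equal length")
  if (length(concentration) < 2L)
    stop("need at least 2 calibration points")
  if (any(!is.finite(counts_per_cc)) || any(!is.finite(concentration)) ||
      any(concentration < 0))
    stop("calibration points must be finite with non-negative concentrations")
  if (length(unique(concentration)) < 2L)
    stop("degenerate design: all concentrations identical")
  fit <- stats::lm(counts_per_cc ~ concentration)
  b <- unname(coef(fit))
  n <- length(concentration)
  r <- stats::cor(concentration, counts_per_cc)
  if (n > 2L && abs(r) < 1) {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  } else {
    p <- if (n == 2L || abs(r) >= 1) 0 else NA_real_
  }
  calibration_model(slope = b[2], intercept = b[1], fit_r = r, fit_p = p,
                    n_points = n, threshold_pct = threshold_pct)
}

#' Convert counts per cc to activity concentration
#'
#' Inverts the calibration line: `conc = (counts/cc - intercept) / slope`.
#' Values that would invert below zero (counts under the background
#' intercept) are clamped to 0; the number of clamped entries is attached as
#' the `"n_clamped"` attribute and reported once via a warning.
#'
#' @param model a [calibration_model()] with positive slope.
#' @param counts_per_cc numeric vector of counts per cc.
#' @param warn warn when clamping occurs (default TRUE).
#' @return concentrations in uCi/cc, attribute `n_clamped`.
#' @export
counts_to_concentration <- function(model, counts_per_cc, warn = TRUE) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.finite(model$slope) || model$slope <= 0)
    stop("calibration slope must be positive")
  conc <- (counts_per_cc - model$intercept) / model$slope
  n_clamped <- sum(conc < 0)
  if (n_clamped > 0) {
    if (warn)
      warning(sprintf("%d value(s) below the calibration intercept clamped to 0",
                      n_clamped))
    conc[conc < 0] <- 0
  }
  attr(conc, "n_clamped") <- n_clamped
  conc
}

#' Forward-map a concentration to counts per cc
#'
#' Applies the calibration line in the forward direction,
#' `counts/cc = slope * conc + intercept`; used by the phantom simulator so
#' that simulated reconstructions carry the background plateau implied by the
#' intercept.
#'
#' @param model a [calibration_model()].
#' @param concentration uCi/cc (non-negative).
#' @return counts per cc.
#' @export
concentration_to_counts <- function(model, concentration) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(concentration < 0)) stop("concentration must be non-negative")
  model$slope * concentration + model$intercept
}

#' Read/write calibration models as JSON
#'
#' @param model a [calibration_model()].
#' @param path file path.
#' @return `write_calibration_json` returns `path` invisibly;
#'   `read_calibration_json` returns a [calibration_model()].
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  calibration_model(slope = num(x$slope), intercept = num(x$intercept),
                    fit_r = num(x$fit_r), fit_p = num(x$fit_p),
                    n_points = if (is.null(x$n_points)) NA_integer_ else x$n_points,
                    threshold_pct = num(x$threshold_pct))
}
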