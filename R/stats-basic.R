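#' Pearson correlation with confidence interval
#'
#' Standard Pearson r with the t-transform p value (n - 2 df) and a 95%
#' Fisher-z confidence interval, as used to relate uptake metrics to severity
#' scores and the ICG reference test.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant.
#' @param conf_level confidence level (default 0.95).
#' @return list with `r`, `p`, `ci95` (length 2), `n`.
#' @export
pearson <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci95 = as.numeric(ct$conf.int), n = length(x))
}

#' Compare two groups of numeric measurements
#'
#' Unpaired comparisons use the Welch t-test (or the rank-sum test); paired
#' comparisons use the paired t-test (or the signed-rank test). All p values
#' are two-sided.
#'
#' @param a,b numeric vectors (equal length when `paired = TRUE`).
#' @param paired paired comparison (default FALSE).
#' @param method `"t"` (default) or `"rank"` for the non-parametric
#'   alternative.
#' @return list with `statistic`, `p`, `method`, `mean_a`, `mean_b`,
#'   `mean_diff` (paired only).
#' @export
compare_groups <- function(a, b, paired = FALSE, method = c("t", "rank")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal lengths")
  if (identical(a, b) && paired && stats::sd(a - b) == 0) {
    # zero-variance differences: no evidence of change
    return(list(statistic = 0, p = 1, method = paste0(method, if (paired) "_paired"),
                mean_a = mean(a), mean_b = mean(b), mean_diff = 0))
  }
  ht <- if (method == "t") {
    stats::t.test(a, b, paired = paired, var.equal = FALSE)
  } else {
    stats::wilcox.test(a, b, paired = paired, exact = FALSE)
  }
  out <- list(statistic = unname(ht$statistic), p = ht$p.value,
              method = paste0(method, if (paired) "_paired" else ""),
              mean_a = mean(a), mean_b = mean(b))
  if (paired) out$mean_diff <- mean(b - a)
  out
}
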