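#' Severity-stratified cohort report
#'
#' Reproduces the prognostic-category analysis on a cohort table: marker
#' means +/- SD per CTP class and per MELD group (<=15 vs >15), one-way
#' ANOVA across the three CTP classes for each marker, and ROC analyses of
#' %QLU, liver volume and ICG-R15 for each severity dichotomy
#' (CTP A vs B, CTP B vs C, MELD <=15 vs >15).
#'
#' @param cohort data.frame with columns `ctp_class`, `meld`, and the marker
#'   columns (default `qlu_pct`, `lv_mL`, `idml_liver`, `qsu_pct`, `sv_mL`,
#'   `idml_spleen`, `icg_r15`).
#' @param markers marker column names to summarise.
#' @param meld_cut MELD dichotomy cut (default 15: <=15 vs >15).
#' @return A `strata_report`: `group_stats` (data.frame stratum x marker
#'   mean/sd/n), `anova_p` (named vector per marker), `roc` (nested list
#'   dichotomy -> marker -> [roc_with_youden()] result).
#' @export
severity_strata_report <- function(cohort,
                                   markers = c("qlu_pct", "lv_mL",
                                               "idml_liver", "qsu_pct",
                                               "sv_mL", "idml_spleen",
                                               "icg_r15"),
                                   meld_cut = 15) {
  need <- c("ctp_class", "meld", markers)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop(sprintf("cohort lacks columns: %s", paste(missing_cols, collapse = ", ")))
  present <- unique(cohort$ctp_class)
  absent <- setdiff(c("A", "B", "C"), present)
  if (length(absent))
    stop(sprintf("missing CTP stratum: %s", paste(absent, collapse = ", ")))
  if (!any(cohort$meld <= meld_cut) || !any(cohort$meld > meld_cut))
    stop(sprintf("missing MELD stratum at cut %g", meld_cut))

  strata <- c(lapply(c(A = "A", B = "B", C = "C"),
                     function(cl) cohort$ctp_class == cl),
              list(MELD_low = cohort$meld <= meld_cut,
                   MELD_high = cohort$meld > meld_cut))
  group_stats <- do.call(rbind, lapply(names(strata), function(st) {
    idx <- strata[[st]]
    do.call(rbind, lapply(markers, function(m)
      data.frame(stratum = st, marker = m, n = sum(idx),
                 mean = mean(cohort[[m]][idx]), sd = stats::sd(cohort[[m]][idx]))))
  }))
  row.names(group_stats) <- NULL

  anova_p <- vapply(markers, function(m) {
    fit <- stats::aov(cohort[[m]] ~ factor(cohort$ctp_class))
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, numeric(1))

  dichotomies <- list(
    ctp_A_vs_B = cohort$ctp_class %in% c("A", "B"),
    ctp_B_vs_C = cohort$ctp_class %in% c("B", "C"),
    meld = rep(TRUE, nrow(cohort))
  )
  pos_label <- list(
    ctp_A_vs_B = cohort$ctp_class == "B",   # positive = worse class
    ctp_B_vs_C = cohort$ctp_class == "C",
    meld = cohort$meld > meld_cut
  )
  roc_markers <- intersect(c("qlu_pct", "lv_mL", "icg_r15"), markers)
  roc <- lapply(names(dichotomies), function(d) {
    idx <- dichotomies[[d]]
    lab <- pos_label[[d]][idx]
    res <- lapply(roc_markers, function(m)
      roc_with_youden(cohort[[m]][idx], as.integer(lab)))
    names(res) <- roc_markers
    res
  })
  names(roc) <- names(dichotomies)

  structure(list(group_stats = group_stats, anova_p = anova_p, roc = roc,
                 meld_cut = meld_cut, n = nrow(cohort)),
            class = "strata_report")
}

#' @export
print.strata_report <- function(x, ...) {
  cat(sprintf("Severity-strata report (n = %d, MELD cut %g)\n", x$n, x$meld_cut))
  cat("ANOVA across CTP classes (p):\n")
  for (m in names(x$anova_p))
    cat(sprintf("  %s: %.4g\n", m, x$anova_p[m]))
  cat("ROC AUCs:\n")
  for (d in names(x$roc))
    for (m in names(x$roc[[d]]))
      cat(sprintf("  %s / %s: AUC = %.3f, cutoff = %.4g\n",
                  d, m, x$roc[[d]][[m]]$auc, x$roc[[d]][[m]]$cutoff))
  invisible(x)
}
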