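test_that("pearson matches the covariance-formula oracle", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  y <- c(10.1, 14.2, 11.9, 22.3, 17.0)
  res <- pearson(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_true(res$ci95[1] <= res$r && res$r <= res$ci95[2])
  expect_equal(res$n, 5)

  anti <- pearson(x, -x + 3)
  expect_equal(anti$r, -1)
  expect_error(pearson(x, rep(2, 5)), "zero variance")
  expect_error(pearson(x[1:2], y[1:2]), "at least 3")
})

test_that("group comparisons match closed-form oracles", {
  a <- c(5.1, 4.8, 6.2, 5.5, 4.9, 5.8)
  b <- c(6.4, 7.1, 6.8, 7.5, 6.0, 7.2)
  res <- compare_groups(a, b)
  # Welch t statistic by hand
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(res$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  df <- se^4 / ((var(a) / length(a))^2 / (length(a) - 1) +
                  (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(res$p, 2 * pt(-abs(res$statistic), df), tolerance = 1e-12)

  same <- compare_groups(a, a, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  rk <- compare_groups(a, b, method = "rank")
  expect_equal(rk$p, wilcox.test(a, b, exact = FALSE)$p.value)
  expect_error(compare_groups(1, b), "n >= 2")
  expect_error(compare_groups(a, b[1:3], paired = TRUE), "equal lengths")
})

test_that("paired %QLU shifts of Table-3 size are detected reliably", {
  # +5.1 mean shift, SD 8, n = 68: the paired t-test should reject at 5%
  # in nearly every replicate
  hits <- with_seed(31, vapply(1:40, function(i) {
    base <- rnorm(68, 26.1, 10.6)
    fu <- base + 5.1 + rnorm(68, 0, 8)
    compare_groups(base, fu, paired = TRUE)$p < 0.05
  }, logical(1)))
  expect_gte(mean(hits), 0.95)
})

test_that("ROC equals exhaustive enumeration on all small datasets", {
  cases <- with_seed(17, lapply(1:25, function(i) {
    n <- sample(6:12, 1)
    npos <- sample(2:(n - 2), 1)
    list(scores = round(rnorm(n), if (i %% 3 == 0) 0 else 2),  # force ties sometimes
         labels = sample(c(rep(1, npos), rep(0, n - npos))))
  }))
  for (cs in cases) {
    res <- roc_with_youden(cs$scores, cs$labels, direction = "higher")
    expect_equal(res$auc, auc_bruteforce(cs$scores, cs$labels),
                 tolerance = 1e-12)
    oracle <- youden_bruteforce(cs$scores, cs$labels)
    expect_equal(res$youden_j, oracle$j, tolerance = 1e-12)
    expect_equal(res$cutoff, oracle$cutoff, tolerance = 1e-12)
    expect_equal(res$youden_j,
                 res$sensitivity / 100 + res$specificity / 100 - 1,
                 tolerance = 1e-12)
  }
})

test_that("ROC handles separation, null scores, and direction detection", {
  sep <- roc_with_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)
  expect_true(sep$cutoff > 3 && sep$cutoff < 10)

  null <- with_seed(9, roc_with_youden(rnorm(4000), rbinom(4000, 1, 0.5)))
  expect_lt(abs(null$auc - 0.5), 0.05)

  # severity markers that fall with disease: direction flips, AUC >= 0.5
  flipped <- roc_with_youden(c(40, 35, 30, 15, 12, 10), c(0, 0, 0, 1, 1, 1))
  expect_equal(flipped$direction, "lower")
  expect_equal(flipped$auc, 1.0)
  expect_error(roc_with_youden(1:5, rep(1, 5)), "both classes")
})

test_that("ROC AUC agrees with an independent implementation", {
  dat <- with_seed(13, list(s = rnorm(200), y = rbinom(200, 1, 0.4)))
  ours <- roc_with_youden(dat$s, dat$y, direction = "higher")
  ref <- suppressMessages(pROC::roc(dat$y, dat$s, direction = "<"))
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("rank AUC equals the trapezoidal area under the empirical curve", {
  dat <- with_seed(23, list(s = round(rnorm(150), 1), y = rbinom(150, 1, 0.5)))
  res <- roc_with_youden(dat$s, dat$y, direction = "higher")
  cv <- res$curve[order(res$curve$cutoff, decreasing = TRUE), ]
  fpr <- 1 - cv$specificity / 100
  tpr <- cv$sensitivity / 100
  trap <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  expect_equal(res$auc, trap, tolerance = 1e-12)
})

test_that("Youden cutoffs are invariant under monotone score transforms", {
  dat <- with_seed(3, list(s = rnorm(80, 20, 5), y = rbinom(80, 1, 0.45)))
  a <- roc_with_youden(dat$s, dat$y, direction = "higher")
  b <- roc_with_youden(exp(dat$s / 10), dat$y, direction = "higher")
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)
  # same classification of every subject
  expect_identical(dat$s > a$cutoff, exp(dat$s / 10) > b$cutoff)
})
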