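# Independent oracles and small fixture builders shared across tests.

# identity forward model: counts/cc equals uCi/cc
identity_model <- function() calibration_model(1, 0)

# the standardized regression line used throughout
reference_model <- function() calibration_model(6807.3, 39.0)

# brute-force AUC: concordant pairs / (n_pos * n_neg), half credit for ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exhaustive Youden search over every midpoint cutoff (oriented so positives
# have higher scores); returns max J and the best (max-sens, then lowest)
# cutoff among ties
youden_bruteforce <- function(scores, labels) {
  us <- sort(unique(scores))
  cand <- c(min(us) - 1, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2,
            max(us) + 1)
  best <- list(j = -Inf, sens = -Inf, cutoff = NA)
  for (c in cand) {
    sens <- mean(scores[labels == 1] > c)
    spec <- mean(scores[labels == 0] <= c)
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(j = j, sens = sens, cutoff = c)
    }
  }
  best
}

# closed-form OLS slope/intercept via the normal equations
ols_bruteforce <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Cox partial log-likelihood (Breslow) by direct risk-set enumeration
cox_loglik_bruteforce <- function(beta, x, times, events) {
  eta <- as.matrix(x) %*% beta
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# small two-level phantom: hot box of known voxel count inside a quiet grid
two_level_volume <- function(shape = c(20, 20, 20), spacing = 2,
                             hot = 1000, background = 10,
                             lo = c(6, 6, 6), hi = c(12, 14, 10)) {
  g <- grid_spec(shape, spacing)
  v <- array(background, dim = shape)
  v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- hot
  list(vol = activity_volume(v, g),
       n_hot = as.integer(prod(hi - lo + 1)), grid = g)
}

# restore RNG state around seeded helpers
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
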