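# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force grids, exhaustive definitions and
# all-pairs counting.

# coarse-to-fine grid maximizer of the Bernoulli log-likelihood for a
# 2-column design; final precision well below 1e-4 per coefficient
oracle_logistic_grid <- function(x, y, offset = NULL, lower = -5, upper = 5) {
  stopifnot(ncol(x) == 2)
  if (is.null(offset)) offset <- numeric(length(y))
  ll <- function(b) {
    eta <- offset + drop(x %*% b)
    sum(ifelse(y == 1, plogis(eta, log.p = TRUE),
               plogis(-eta, log.p = TRUE)))
  }
  b1 <- seq(lower, upper, length.out = 41)
  b2 <- b1
  best <- c(0, 0); bestll <- -Inf
  for (pass in 1:6) {
    for (i in seq_along(b1)) for (j in seq_along(b2)) {
      v <- ll(c(b1[i], b2[j]))
      if (v > bestll) { bestll <- v; best <- c(b1[i], b2[j]) }
    }
    w1 <- max(diff(range(b1)) / 8, 1e-6)
    w2 <- max(diff(range(b2)) / 8, 1e-6)
    b1 <- seq(best[1] - w1, best[1] + w1, length.out = 21)
    b2 <- seq(best[2] - w2, best[2] + w2, length.out = 21)
  }
  list(coefficients = best, log_likelihood = bestll)
}

# literal min_{j >= i} p_(j) * m / j definition of BH step-up adjustment
oracle_bh <- function(p, m) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(ps[i:n] * m / (i:n)))
  }, numeric(1))
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# all-pairs concordance count (ties worth 1/2)
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# simulate one randomized-trial component and return cases (and optionally
# the full cohort): logistic outcome with treatment main effect, SNP main
# effect and SNP-by-treatment interaction
sim_trial <- function(n, maf, q, baseline, b_trt, b_g, b_int, seed) {
  set.seed(seed)
  g <- rbinom(n, 2, maf)
  z <- rbinom(n, 1, q)
  lp <- baseline + b_trt * z + b_g * g + b_int * g * z
  y <- runif(n) < plogis(lp)
  list(g = g, z = z, y = y)
}
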