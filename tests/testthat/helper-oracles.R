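# Independent brute-force oracles used to verify the implementation.

# Maximum ECDF gap between two samples, by direct enumeration over the pooled
# support (two-sample KS D).
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(grid, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# Closed-form simple OLS: slope, intercept, R^2, F on (1, n-2) df.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- sxy^2 / (sxx * syy)
  f <- (n - 2) * r2 / (1 - r2)
  list(slope = slope, intercept = intercept, r_squared = r2, f_stat = f,
       p = pf(f, 1, n - 2, lower.tail = FALSE))
}

# Pooled-variance two-sample t statistic, hand formula.
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Gaussian-mixture log-likelihood for arbitrary parameters.
oracle_mix_logL <- function(values, w, mu, sd) {
  dens <- rowSums(vapply(seq_along(w), function(k) {
    w[k] * dnorm(values, mu[k], sd[k])
  }, numeric(length(values))))
  sum(log(dens))
}

# Dense grid search for the best 2-component mixture with both SDs fixed:
# an independent lower bound on the attainable log-likelihood.
oracle_grid_logL_K2 <- function(values, sd_fixed,
                                pi_grid = seq(0.05, 0.95, by = 0.05),
                                mu_grid = seq(0, 1, by = 0.02)) {
  best <- -Inf
  for (p in pi_grid) {
    for (m1 in mu_grid) {
      for (m2 in mu_grid) {
        if (m2 <= m1) next
        ll <- oracle_mix_logL(values, c(p, 1 - p), c(m1, m2),
                              rep(sd_fixed, 2))
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# Category counting by explicit comparison chain (independent of
# classify_ratio's implementation).
oracle_category_counts <- function(r) {
  c(
    monoallelic_129 = sum(r < 0.15),
    biased_129 = sum(r >= 0.15 & r <= 0.35),
    biallelic = sum(r > 0.35 & r < 0.65),
    biased_cast = sum(r >= 0.65 & r <= 0.85),
    monoallelic_cast = sum(r > 0.85)
  )
}
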