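#' Fit a univariate Gaussian mixture to clonal allelic ratios by EM
#'
#' Decomposes the distribution of a gene's allelic ratios across clones into
#' `K` Gaussian components, each an allelic "modality" (a stable allelic state
#' shared by a subpopulation of clones). Plain (untruncated) Gaussians are
#' fitted even though ratios are bounded; densities are not renormalised to
#' \[0,1\].
#'
#' For `K = 1` the maximum-likelihood estimate is closed form (sample mean and
#' biased variance) and EM is skipped. For `K > 1`, EM runs from a
#' deterministic quantile-based initialisation (sorted values cut into `K`
#' blocks) plus `n_restarts` randomly perturbed restarts; the best
#' log-likelihood wins. The log-likelihood is non-decreasing across iterations
#' by construction and the trace is retained for verification.
#'
#' @param values Numeric vector of ratios; must be finite, `NA`s not allowed.
#' @param K Number of components (>= 1). Requires `length(values) >= 2 * K`.
#' @param variance_family `"unequal"` (component-specific variances, the
#'   default) or `"equal"` (one shared variance).
#' @param n_restarts Number of randomly perturbed initialisations tried in
#'   addition to the deterministic quantile start.
#' @param seed Integer seed making the restarts reproducible.
#' @param max_iter,tol EM stopping rule: stop when the relative log-likelihood
#'   change falls below `tol` or after `max_iter` iterations.
#' @param var_floor Lower bound on component variances (ratio^2 units),
#'   preventing singular components on replicated values.
#' @return A `mixture_fit` object: list with `K`, `weights`, `means` (sorted
#'   ascending), `variances`, `variance_family`, `logL`, `bic`
#'   (`2*logL - k_free*log(n)`), `n`, `converged`, `n_iter`, `logL_trace`.
#' @export
em_fit <- function(values, K, variance_family = c("unequal", "equal"),
                   n_restarts = 10L, seed = 1L,
                   max_iter = 1000L, tol = 1e-8, var_floor = 1e-6) {
  variance_family <- match.arg(variance_family)
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (K < 1) stop("K must be >= 1")
  if (n < 2 * K) {
    stop(sprintf("insufficient data: n = %d < 2K = %d", n, 2 * K))
  }

  if (K == 1L) {
    mu <- mean(values)
    sigma2 <- max(mean((values - mu)^2), var_floor)
    logL <- sum(dnorm(values, mu, sqrt(sigma2), log = TRUE))
    return(new_mixture_fit(
      K = 1L, weights = 1, means = mu, variances = sigma2,
      variance_family = variance_family, logL = logL, n = n,
      converged = TRUE, n_iter = 0L, logL_trace = logL,
      var_floor = var_floor
    ))
  }

  set.seed(as.integer(seed))
  best <- NULL
  for (restart in 0:n_restarts) {
    init <- em_init(values, K, perturb = restart > 0)
    run <- .em_run_cpp(values, init$weights, init$means,
                       pmax(init$variances, var_floor),
                       if (variance_family == "equal") 1L else 0L,
                       max_iter, tol, var_floor)
    ord <- order(run$means)
    fit <- list(weights = run$weights[ord], means = run$means[ord],
                variances = run$variances[ord], logL = run$logL,
                converged = run$converged, n_iter = run$n_iter,
                logL_trace = run$logL_trace)
    if (is.null(best) || fit$logL > best$logL) best <- fit
  }
  new_mixture_fit(
    K = K, weights = best$weights, means = best$means,
    variances = best$variances, variance_family = variance_family,
    logL = best$logL, n = n, converged = best$converged,
    n_iter = best$n_iter, logL_trace = best$logL_trace,
    var_floor = var_floor
  )
}

# Quantile-block initialisation: cut the sorted sample into K equal blocks and
# use each block's mean/variance; optionally jitter for random restarts.
em_init <- function(values, K, perturb) {
  n <- length(values)
  sorted <- sort(values)
  block <- split(sorted, cut(seq_len(n), K, labels = FALSE))
  means <- vapply(block, mean, numeric(1))
  vars <- vapply(block, function(b) stats::var(b) * (length(b) - 1) / max(1, length(b)),
                 numeric(1))
  vars[!is.finite(vars) | vars <= 0] <- stats::var(values) / K^2
  weights <- vapply(block, length, numeric(1)) / n
  if (perturb) {
    spread <- max(diff(range(values)), 1e-3)
    means <- means + rnorm(K, 0, spread / (2 * K))
    weights <- weights * exp(rnorm(K, 0, 0.3))
    weights <- weights / sum(weights)
  }
  list(weights = weights, means = means, variances = vars)
}

# Pure-R reference EM, mirroring the compiled inner loop step for step.
# Kept as an independent implementation for verification; the fitting path
# uses .em_run_cpp.
em_run <- function(values, K, init, variance_family, max_iter, tol, var_floor) {
  n <- length(values)
  w <- init$weights
  mu <- init$means
  s2 <- pmax(init$variances, var_floor)
  if (variance_family == "equal") s2 <- rep(mean(s2), K)
  logL_trace <- numeric(0)
  logL_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step
    lp <- vapply(seq_len(K), function(k) {
      log(w[k]) + dnorm(values, mu[k], sqrt(s2[k]), log = TRUE)
    }, numeric(n))                      # n x K
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    logL <- sum(lse)
    logL_trace <- c(logL_trace, logL)
    resp <- exp(lp - lse)               # n x K responsibilities
    # M-step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-300)
    w <- nk / n
    mu <- colSums(resp * values) / nk
    dev2 <- (matrix(values, n, K) - matrix(mu, n, K, byrow = TRUE))^2
    if (variance_family == "equal") {
      s2 <- rep(max(sum(resp * dev2) / n, var_floor), K)
    } else {
      s2 <- pmax(colSums(resp * dev2) / nk, var_floor)
    }
    if (is.finite(logL_old) &&
        abs(logL - logL_old) <= tol * (abs(logL_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    logL_old <- logL
  }
  # final logL with the last M-step parameters
  lp <- vapply(seq_len(K), function(k) {
    log(w[k]) + dnorm(values, mu[k], sqrt(s2[k]), log = TRUE)
  }, numeric(n))
  m <- apply(lp, 1, max)
  logL <- sum(m + log(rowSums(exp(lp - m))))
  logL_trace <- c(logL_trace, logL)
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], variances = s2[ord],
       logL = logL, converged = converged, n_iter = iter,
       logL_trace = logL_trace)
}

# free-parameter count: K-1 weights + K means + K (or 1) variances
mixture_k_free <- function(K, variance_family) {
  if (variance_family == "equal") 2L * K else 3L * K - 1L
}

new_mixture_fit <- function(K, weights, means, variances, variance_family,
                            logL, n, converged, n_iter, logL_trace, var_floor) {
  ord <- order(means)
  k_free <- mixture_k_free(K, variance_family)
  structure(
    list(
      K = as.integer(K),
      weights = unname(weights[ord]),
      means = unname(means[ord]),
      variances = unname(variances[ord]),
      variance_family = variance_family,
      logL = logL,
      bic = 2 * logL - k_free * log(n),
      k_free = k_free,
      n = as.integer(n),
      converged = converged,
      n_iter = as.integer(n_iter),
      logL_trace = logL_trace,
      var_floor = var_floor
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian mixture fit: K = %d (%s variance), n = %d, logL = %.3f, BIC = %.3f\n",
    x$K, x$variance_family, x$n, x$logL, x$bic
  ))
  print(data.frame(
    component = seq_len(x$K), weight = x$weights,
    mean = x$means, variance = x$variances
  ), row.names = FALSE)
  invisible(x)
}

#' Mixture log-likelihood of a sample under a fitted model
#' @param fit A `mixture_fit`.
#' @param values Numeric vector.
#' @return Total log-likelihood.
#' @keywords internal
mixture_logL <- function(fit, values) {
  lp <- vapply(seq_len(fit$K), function(k) {
    log(fit$weights[k]) +
      dnorm(values, fit$means[k], sqrt(fit$variances[k]), log = TRUE)
  }, numeric(length(values)))
  if (fit$K == 1L) return(sum(lp))
  m <- apply(lp, 1, max)
  sum(m + log(rowSums(exp(lp - m))))
}

#' Select the number of allelic modalities by BIC
#'
#' Fits mixtures with `K = 1 .. K_max` components for both the equal- and
#' unequal-variance families and returns the fit maximising
#' `BIC = 2*logL - k_free*log(n)`. Ties are broken toward smaller `K`, then
#' toward the equal-variance family.
#'
#' @inheritParams em_fit
#' @param K_max Largest component count searched. `K` values with fewer than
#'   `2*K` observations are skipped.
#' @return The winning `mixture_fit`, with a `selection` attribute: a data
#'   frame of (`K`, `variance_family`, `logL`, `bic`, `converged`) for every
#'   candidate fitted.
#' @export
select_model <- function(values, K_max = 5L, seed = 1L, n_restarts = 10L,
                         var_floor = 1e-6) {
  if (K_max < 1) stop("K_max must be >= 1")
  n <- length(values)
  candidates <- list()
  rows <- list()
  i <- 0L
  for (family in c("equal", "unequal")) {
    for (K in seq_len(K_max)) {
      if (n < 2 * K) next
      if (K == 1L && family == "unequal") next  # identical to equal at K = 1
      i <- i + 1L
      fit <- em_fit(values, K, variance_family = family,
                    n_restarts = n_restarts, seed = seed + 1000L * K,
                    var_floor = var_floor)
      candidates[[i]] <- fit
      rows[[i]] <- data.frame(
        K = K, variance_family = family, logL = fit$logL, bic = fit$bic,
        converged = fit$converged, stringsAsFactors = FALSE
      )
    }
  }
  selection <- do.call(rbind, rows)
  # maximise BIC; ties -> smaller K, then equal family
  fam_rank <- ifelse(selection$variance_family == "equal", 0L, 1L)
  ord <- order(-selection$bic, selection$K, fam_rank)
  best <- candidates[[ord[1L]]]
  attr(best, "selection") <- selection
  best
}

#' Simulate from a fitted Gaussian mixture
#' @keywords internal
simulate_mixture <- function(fit, n) {
  comp <- sample.int(fit$K, n, replace = TRUE, prob = fit$weights)
  rnorm(n, fit$means[comp], sqrt(fit$variances[comp]))
}

#' Parametric-bootstrap likelihood-ratio test for K vs K + 1 components
#'
#' Tests whether `K_null + 1` mixture components fit the clonal ratio
#' distribution significantly better than `K_null`. The null distribution of
#' `2 * (logL_alt - logL_null)` is irregular for mixtures, so it is evaluated
#' by parametric bootstrap: `B` datasets of the same size are simulated from
#' the fitted `K_null` model, the statistic is recomputed on each, and the
#' p-value is `(1 + #{boot >= observed}) / (B + 1)`.
#'
#' @inheritParams em_fit
#' @param K_null Component count under the null; the alternative is
#'   `K_null + 1`.
#' @param B Bootstrap replications (>= 99; default 1000).
#' @param n_restarts_boot Restarts used when refitting bootstrap replicates
#'   (fewer than for the observed fit, for speed).
#' @param variance_family Variance family used for both fits.
#' @return An `lrt_result`: list with `K_null`, `K_alt`, `lrt_obs`, `B`,
#'   `p_value`, `bootstrap_stats`, `n_failed` (replicates that needed
#'   reseeding).
#' @export
bootstrap_lrt <- function(values, K_null, B = 1000L, seed = 1L,
                          variance_family = "unequal",
                          n_restarts = 10L, n_restarts_boot = 2L,
                          var_floor = 1e-6) {
  if (B < 99) stop("B must be >= 99")
  fit0 <- em_fit(values, K_null, variance_family = variance_family,
                 n_restarts = n_restarts, seed = seed, var_floor = var_floor)
  fit1 <- em_fit(values, K_null + 1L, variance_family = variance_family,
                 n_restarts = n_restarts, seed = seed, var_floor = var_floor)
  lrt_obs <- max(0, 2 * (fit1$logL - fit0$logL))
  n <- length(values)
  set.seed(as.integer(seed) + 7L)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, B)
  stats_b <- numeric(B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      sb <- (boot_seeds[b] + attempt - 1L) %% (.Machine$integer.max - 1L)
      set.seed(sb)
      yb <- simulate_mixture(fit0, n)
      stat <- tryCatch({
        f0 <- em_fit(yb, K_null, variance_family = variance_family,
                     n_restarts = n_restarts_boot, seed = sb,
                     var_floor = var_floor)
        f1 <- em_fit(yb, K_null + 1L, variance_family = variance_family,
                     n_restarts = n_restarts_boot, seed = sb,
                     var_floor = var_floor)
        max(0, 2 * (f1$logL - f0$logL))
      }, error = function(e) NA_real_)
      if (!is.na(stat)) break
      n_failed <- n_failed + 1L
      if (n_failed > 0.1 * B) {
        stop("more than 10% of bootstrap replicates failed to refit")
      }
    }
    stats_b[b] <- stat
  }
  structure(
    list(
      K_null = as.integer(K_null), K_alt = as.integer(K_null + 1L),
      lrt_obs = lrt_obs, B = as.integer(B),
      p_value = (1 + sum(stats_b >= lrt_obs)) / (B + 1),
      bootstrap_stats = stats_b, n_failed = n_failed
    ),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap LRT: K = %d vs %d, LRT = %.3f, B = %d, p = %.4g\n",
    x$K_null, x$K_alt, x$lrt_obs, x$B, x$p_value
  ))
  invisible(x)
}

#' Sequential bootstrap LRT over increasing component counts
#'
#' Tests K vs K + 1 starting at K = 1 and stops at the first non-significant
#' level (p > alpha); all tested levels are reported.
#'
#' @inheritParams bootstrap_lrt
#' @param K_max Largest null component count to test.
#' @param alpha Stopping threshold on the bootstrap p-value.
#' @return Data frame with one row per tested level (`K_null`, `K_alt`,
#'   `lrt_obs`, `p_value`) plus a `K_selected` attribute (last K whose
#'   increment was rejected, plus one; 1 if the first test already fails to
#'   reject).
#' @export
sequential_lrt <- function(values, K_max = 5L, B = 1000L, alpha = 0.05,
                           seed = 1L, ...) {
  rows <- list()
  K_selected <- 1L
  for (K in seq_len(K_max - 1L)) {
    if (length(values) < 2 * (K + 1L)) break
    res <- bootstrap_lrt(values, K, B = B, seed = seed + K, ...)
    rows[[K]] <- data.frame(
      K_null = res$K_null, K_alt = res$K_alt,
      lrt_obs = res$lrt_obs, p_value = res$p_value
    )
    if (res$p_value > alpha) break
    K_selected <- K + 1L
  }
  out <- do.call(rbind, rows)
  attr(out, "K_selected") <- K_selected
  out
}

#' Nonparametric-bootstrap confidence intervals for mixture parameters
#'
#' Resamples the clones with replacement `B` times, refits the mixture at the
#' fixed `K` and variance family of `fit`, matches components across
#' replicates by sorting on the component means, and returns percentile
#' intervals for every weight, mean and variance.
#'
#' @inheritParams em_fit
#' @param fit A converged `mixture_fit` for these values.
#' @param B Bootstrap replications (>= 99; default 1000).
#' @param level Confidence level (default 0.95).
#' @return A `param_ci` object: data frame with columns `parameter`
#'   (`weight`/`mean`/`variance`), `component`, `estimate`, `lower`, `upper`,
#'   plus attributes `B`, `level` and `label_switching` (TRUE when component
#'   means tied in some replicate, in which case the affected intervals are
#'   widened to the union across components).
#' @export
bootstrap_param_ci <- function(values, fit, B = 1000L, level = 0.95,
                               seed = 1L, n_restarts_boot = 2L) {
  if (!inherits(fit, "mixture_fit")) stop("`fit` must be a mixture_fit")
  if (!fit$converged) stop("`fit` must have converged")
  if (B < 99) stop("B must be >= 99")
  n <- length(values)
  K <- fit$K
  set.seed(as.integer(seed))
  boot <- array(NA_real_, c(B, 3L, K),
                dimnames = list(NULL, c("weight", "mean", "variance"), NULL))
  switching <- FALSE
  for (b in seq_len(B)) {
    yb <- values[sample.int(n, n, replace = TRUE)]
    fb <- tryCatch(
      em_fit(yb, K, variance_family = fit$variance_family,
             n_restarts = n_restarts_boot, seed = seed + b,
             var_floor = fit$var_floor),
      error = function(e) NULL
    )
    if (is.null(fb)) next
    if (K > 1L && any(diff(fb$means) < 1e-8)) switching <- TRUE
    boot[b, "weight", ] <- fb$weights
    boot[b, "mean", ] <- fb$means
    boot[b, "variance", ] <- fb$variances
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- list()
  est <- rbind(weight = fit$weights, mean = fit$means, variance = fit$variances)
  for (p in c("weight", "mean", "variance")) {
    for (k in seq_len(K)) {
      q <- quantile(boot[, p, k], probs, na.rm = TRUE, names = FALSE)
      if (switching) {
        # mean ordering ambiguous: widen to the union over components
        q <- c(min(boot[, p, ], na.rm = TRUE), max(boot[, p, ], na.rm = TRUE))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, component = k, estimate = est[p, k],
        lower = q[1L], upper = q[2L], stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "label_switching") <- switching
  class(out) <- c("param_ci", class(out))
  out
}

#' Assign clones to mixture components by posterior responsibility
#'
#' @param fit A converged `mixture_fit`.
#' @param values Numeric vector of clonal ratios.
#' @return List with `labels` (component index per value, argmax posterior),
#'   `posterior` (n x K matrix of responsibilities, rows summing to 1) and
#'   `shares` (fraction of clones assigned to each component, summing to 1).
#' @export
assign_clones <- function(fit, values) {
  if (!fit$converged) stop("`fit` must have converged")
  n <- length(values)
  lp <- vapply(seq_len(fit$K), function(k) {
    log(fit$weights[k]) +
      dnorm(values, fit$means[k], sqrt(fit$variances[k]), log = TRUE)
  }, numeric(n))
  lp <- matrix(lp, nrow = n)
  m <- apply(lp, 1, max)
  post <- exp(lp - (m + log(rowSums(exp(lp - m)))))
  labels <- max.col(post, ties.method = "first")
  shares <- tabulate(labels, fit$K) / n
  list(labels = labels, posterior = post, shares = shares)
}
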