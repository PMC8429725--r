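test_that("K=1 fit equals the closed-form Gaussian MLE", {
  set.seed(5)
  y <- rnorm(200, 0.5, 0.03)
  fit <- em_fit(y, 1)
  expect_equal(fit$means, mean(y), tolerance = 1e-9)
  expect_equal(fit$variances, mean((y - mean(y))^2), tolerance = 1e-9)
  expect_equal(fit$logL, sum(dnorm(y, mean(y), sd = sqrt(mean((y - mean(y))^2)),
                                   log = TRUE)), tolerance = 1e-9)
  # BIC convention: 2*logL - k_free*log(n), k_free = 2 at K = 1
  expect_equal(fit$bic, 2 * fit$logL - 2 * log(200), tolerance = 1e-9)

  # degenerate point mass: mean at the point, variance at the floor
  fit <- em_fit(rep(0.5, 10), 1)
  expect_equal(fit$means, 0.5)
  expect_equal(fit$variances, 1e-6)
  expect_true(is.finite(fit$logL))
})

test_that("free-parameter counts for the two variance families", {
  set.seed(6)
  y <- c(rnorm(40, 0.2, 0.03), rnorm(40, 0.8, 0.03))
  for (K in 1:3) {
    fu <- em_fit(y, K, "unequal", n_restarts = 2)
    fe <- em_fit(y, K, "equal", n_restarts = 2)
    expect_equal(fu$bic, 2 * fu$logL - (3 * K - 1) * log(80))
    expect_equal(fe$bic, 2 * fe$logL - 2 * K * log(80))
    expect_equal(length(unique(fe$variances)), 1L)
  }
})

test_that("EM log-likelihood is monotone non-decreasing on every fit", {
  set.seed(7)
  samples <- list(
    rnorm(60, 0.5, 0.05),
    c(rnorm(30, 0.1, 0.03), rnorm(30, 0.9, 0.03)),
    c(rnorm(20, 0.05, 0.02), rnorm(30, 0.5, 0.06), rnorm(20, 0.95, 0.02)),
    runif(50)
  )
  for (y in samples) {
    for (K in 2:3) {
      for (fam in c("unequal", "equal")) {
        fit <- em_fit(y, K, fam, n_restarts = 3, seed = 42)
        tr <- fit$logL_trace
        expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1e-12)))
      }
    }
  }
})

test_that("compiled EM matches the pure-R reference implementation", {
  set.seed(8)
  y <- c(rnorm(40, 0.2, 0.04), rnorm(40, 0.75, 0.06))
  init <- raexi:::em_init(y, 2, perturb = FALSE)
  ref <- raexi:::em_run(y, 2, init, "unequal", 1000L, 1e-8, 1e-6)
  cpp <- raexi:::.em_run_cpp(y, init$weights, init$means,
                             pmax(init$variances, 1e-6), 0L, 1000L, 1e-8, 1e-6)
  ord <- order(cpp$means)
  expect_equal(ref$logL, cpp$logL, tolerance = 1e-8)
  expect_equal(ref$means, cpp$means[ord], tolerance = 1e-6)
  expect_equal(ref$weights, cpp$weights[ord], tolerance = 1e-6)
})

test_that("K=2 EM log-likelihood beats a dense fixed-sigma grid search", {
  set.seed(9)
  y <- c(rnorm(30, 0.25, 0.05), rnorm(30, 0.75, 0.05))
  fit <- em_fit(y, 2, seed = 1)
  grid_best <- oracle_grid_logL_K2(y, sd_fixed = 0.05)
  expect_gte(fit$logL, grid_best)
})

test_that("em_fit validates its inputs and is seed-deterministic", {
  expect_error(em_fit(rnorm(3), 2), "insufficient data")
  expect_error(em_fit(c(0.1, NA, 0.3, 0.4), 2), "finite")
  set.seed(10)
  y <- c(rnorm(30, 0.2, 0.05), rnorm(30, 0.8, 0.05))
  f1 <- em_fit(y, 2, seed = 99)
  f2 <- em_fit(y, 2, seed = 99)
  expect_identical(f1$logL, f2$logL)
  expect_identical(f1$means, f2$means)
})

test_that("mixture_fit invariants: weights sum to 1, means sorted, floor held", {
  set.seed(12)
  for (rep in 1:10) {
    y <- runif(40 + rep)
    fit <- em_fit(y, sample(2:4, 1), sample(c("equal", "unequal"), 1),
                  n_restarts = 2, seed = rep)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_true(all(diff(fit$means) >= 0))
    expect_true(all(fit$variances >= 1e-6 - 1e-15))
  }
})

test_that("BIC model selection identifies one population for unimodal data", {
  # a narrow single population of 83 clones, biallelic-like
  set.seed(13)
  y <- rnorm(83, 0.5, 0.03)
  fit <- select_model(y, K_max = 5, seed = 1)
  expect_equal(fit$K, 1L)
  sel <- attr(fit, "selection")
  expect_true(all(c("K", "variance_family", "bic") %in% names(sel)))
  expect_equal(max(sel$bic), fit$bic)
})

test_that("constant values select K=1 with the variance floor", {
  fit <- select_model(rep(0.42, 5), K_max = 2, seed = 1)
  expect_equal(fit$K, 1L)
  expect_equal(fit$variances, 1e-6)
})

test_that("three-state fits recover the generating component means", {
  # heteroscedastic three-state mixture; fit at the true K
  recovered <- 0L
  for (s in 1:20) {
    set.seed(s)
    comp <- sample(1:3, 150, TRUE, c(0.25, 0.5, 0.25))
    y <- rnorm(150, c(0.05, 0.5, 0.95)[comp], c(0.03, 0.05, 0.03)[comp])
    fit <- em_fit(y, 3, seed = s)
    if (all(abs(fit$means - c(0.05, 0.5, 0.95)) < 0.03)) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(recovered, 18L)
})

test_that("model selection recovers K for well-separated mixtures", {
  # |mu2 - mu1| = 6 sigma, n = 100, balanced weights
  correct <- 0L
  n_sims <- 50L
  for (s in 1:n_sims) {
    set.seed(s)
    comp <- sample(1:2, 100, TRUE, c(0.5, 0.5))
    y <- rnorm(100, c(0.35, 0.65)[comp], 0.05)
    fit <- select_model(y, K_max = 4, seed = s)
    if (fit$K == 2L) correct <- correct + 1L
  }
  expect_gte(correct / n_sims, 0.9)
})

test_that("bootstrap LRT: clear two-component data gives the minimal p-value", {
  set.seed(14)
  # 10-sigma separation: the observed LRT should exceed every bootstrap stat
  y <- c(rnorm(40, 0.2, 0.02), rnorm(40, 0.8, 0.02))
  res <- bootstrap_lrt(y, 1, B = 99, seed = 2)
  expect_equal(res$p_value, 1 / 100)
  expect_gte(res$lrt_obs, 0)
  expect_equal(res$K_alt, 2L)
})

test_that("bootstrap LRT p-values respect their bounds and default B", {
  expect_error(bootstrap_lrt(rnorm(30), 1, B = 50), "B must be >= 99")
  expect_equal(formals(bootstrap_lrt)$B, 1000L)
  set.seed(15)
  y <- rnorm(60, 0.5, 0.05)
  res <- bootstrap_lrt(y, 1, B = 99, seed = 5)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  expect_length(res$bootstrap_stats, 99L)
})

test_that("sequential LRT stops at the first non-significant increment", {
  set.seed(16)
  y <- c(rnorm(50, 0.15, 0.04), rnorm(50, 0.85, 0.04))
  seq_res <- sequential_lrt(y, K_max = 4, B = 99, seed = 3)
  expect_equal(attr(seq_res, "K_selected"), 2L)
  expect_equal(seq_res$K_null, c(1L, 2L))
  expect_lte(seq_res$p_value[1], 0.05)
  expect_gt(seq_res$p_value[2], 0.05)
})

test_that("bootstrap parameter CIs behave on point masses and cover the mean", {
  y <- rep(0.37, 12)
  fit <- em_fit(y, 1)
  ci <- bootstrap_param_ci(y, fit, B = 99, seed = 1)
  mu_row <- ci[ci$parameter == "mean", ]
  expect_equal(mu_row$lower, 0.37)
  expect_equal(mu_row$upper, 0.37)

  # K=1 Gaussian data: percentile interval covers the truth in most runs
  covered <- 0L
  for (s in 1:30) {
    set.seed(s)
    y <- rnorm(100, 0.5, 0.05)
    fit <- em_fit(y, 1)
    ci <- bootstrap_param_ci(y, fit, B = 199, seed = s)
    mu <- ci[ci$parameter == "mean", ]
    if (mu$lower <= 0.5 && 0.5 <= mu$upper) covered <- covered + 1L
  }
  expect_gte(covered, 26L)  # ~95% nominal, binomial slack at 30 runs
})

test_that("parameter estimates sit inside their own bootstrap intervals", {
  set.seed(17)
  y <- c(rnorm(60, 0.2, 0.04), rnorm(60, 0.8, 0.04))
  fit <- em_fit(y, 2, seed = 1)
  ci <- bootstrap_param_ci(y, fit, B = 199, seed = 2)
  inside <- ci$lower <= ci$estimate & ci$estimate <= ci$upper
  expect_gte(mean(inside), 0.9)
})

test_that("clone assignment by posterior responsibility", {
  set.seed(18)
  y <- rnorm(30, 0.5, 0.05)
  fit <- em_fit(y, 1)
  asg <- assign_clones(fit, y)
  expect_true(all(asg$labels == 1L))
  expect_equal(asg$shares, 1)

  # forced assignment under well-separated components
  fit2 <- em_fit(c(rnorm(30, 0.05, 0.02), rnorm(30, 0.95, 0.02)), 2, seed = 1)
  asg <- assign_clones(fit2, 0.05)
  expect_equal(asg$labels, 1L)
  expect_gt(asg$posterior[1, 1], 0.999)
  expect_equal(rowSums(asg$posterior), 1, tolerance = 1e-9)

  # shares track the generating weights of a 30/70 mixture
  set.seed(19)
  comp <- sample(1:2, 150, TRUE, c(0.3, 0.7))
  y <- rnorm(150, c(0.1, 0.8)[comp], 0.05)
  fit <- em_fit(y, 2, seed = 1)
  asg <- assign_clones(fit, y)
  expect_lt(abs(asg$shares[1] - 0.3), 0.1)
  expect_lt(abs(asg$shares[2] - 0.7), 0.1)
})

test_that("fits agree with mclust as an independent cross-check", {
  skip_if_not_installed("mclust")
  skip_if_not_installed("withr")
  withr::local_package("mclust")
  set.seed(20)
  y <- c(rnorm(60, 0.2, 0.04), rnorm(60, 0.8, 0.06))
  fit <- em_fit(y, 2, "unequal", seed = 1)
  mc <- mclust::Mclust(y, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$logL, mc$loglik, tolerance = 1e-4)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1e-3)
  # same BIC convention (2*logL - k_free*log(n), maximised)
  expect_equal(fit$bic, as.numeric(mc$bic), tolerance = 1e-3)
})
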