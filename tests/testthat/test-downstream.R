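test_that("KS comparison equals the brute-force ECDF maximum gap", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(ks_compare(a, a)$D, 0)
  expect_equal(ks_compare(a, a)$p_value, 1)
  expect_equal(ks_compare(c(0.1, 0.2), c(0.8, 0.9))$D, 1)

  set.seed(50)
  esc <- rnorm(18, 0.5, 0.02)
  comp <- sample(1:3, 150, TRUE, c(0.25, 0.5, 0.25))
  npc <- rnorm(150, c(0.05, 0.5, 0.95)[comp], 0.04)
  res <- ks_compare(esc, npc)
  expect_equal(res$D, oracle_ks_D(esc, npc), tolerance = 1e-12)

  for (i in 1:10) {
    set.seed(i)
    x <- runif(sample(5:40, 1)); y <- runif(sample(5:40, 1))
    expect_equal(ks_compare(x, y)$D, oracle_ks_D(x, y), tolerance = 1e-12)
  }
  expect_error(ks_compare(numeric(0), a), "non-empty")
})

test_that("stability correlation filters low-read genes and needs 3 pairs", {
  pairs <- data.frame(
    clone_id = "XX1", gene_id = sprintf("g%d", 1:5),
    ratio_t1 = c(0.1, 0.3, 0.5, 0.7, 0.9),
    reads_t1 = 100L,
    ratio_t2 = c(0.1, 0.3, 0.5, 0.7, 0.9),
    reads_t2 = c(100L, 100L, 100L, 100L, 19L)
  )
  res <- stability_correlation(pairs)
  expect_equal(res$r, 1)
  expect_equal(res$n_genes, 4L)  # the 19-read gene is dropped

  pairs$ratio_t2 <- 1 - pairs$ratio_t1
  expect_equal(stability_correlation(pairs)$r, -1)

  pairs$reads_t2 <- 19L
  res <- stability_correlation(pairs)
  expect_equal(res$status, "undefined")
  expect_true(is.na(res$r))
})

test_that("expression group split and threshold proposal", {
  expect_equal(split_expression_groups(c(0.2, 0.9), 0.5), c("low", "high"))
  expect_warning(split_expression_groups(c(0.1, 0.2), 0.5), "one expression group")
  # threshold itself counts as high
  expect_equal(suppressWarnings(split_expression_groups(0.5, 0.5)), "high")

  # bimodal lognormal levels: proposed threshold separates the true groups
  set.seed(51)
  truth <- rep(c("low", "high"), c(40, 60))
  levels <- exp(rnorm(100, ifelse(truth == "low", log(0.2), log(1.5)), 0.3))
  thr <- propose_expression_threshold(levels, seed = 1)
  groups <- split_expression_groups(levels, thr)
  expect_gte(mean(groups == truth), 0.95)
})

test_that("dosage t-test matches the pooled-variance oracle", {
  mono <- c(0.9, 1.1, 1.0, 1.2)
  bi <- c(1.9, 2.1, 2.2, 1.8)
  levels <- c(mono, bi)
  cats <- c(rep("monoallelic_cast", 4), rep("biallelic", 4))
  res <- dosage_ttest(levels, cats)
  oracle <- oracle_pooled_t(mono, bi)
  expect_equal(res$t, oracle$t, tolerance = 1e-9)
  expect_equal(res$df, 6)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-9)

  # equal means give t = 0, p = 1
  res <- dosage_ttest(c(1, 2, 1, 2), c("monoallelic_129", "monoallelic_129",
                                       "biallelic", "biallelic"))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  # biased clones are excluded from the comparison
  res <- dosage_ttest(c(mono, bi, 5, 5),
                      c(cats, "biased_cast", "biased_129"))
  expect_equal(res$n_monoallelic + res$n_biallelic, 8)
  expect_error(dosage_ttest(c(1, 2), c("monoallelic_129", "biallelic")),
               ">= 2")
})

test_that("monoallelic clones carry half the mRNA in the per-allele model", {
  sim <- simulate_dosage_clones(30, 30, seed = 7)
  cats <- as.character(classify_ratio(sim$ratio))
  res <- dosage_ttest(sim$level, cats)
  expect_gt(res$ratio_of_means, 0.45)
  expect_lt(res$ratio_of_means, 0.55)
  expect_lt(res$p_value, 0.01)
})

test_that("dosage halving estimator tightens as clone numbers grow", {
  ratios <- vapply(c(50, 400), function(n) {
    sim <- simulate_dosage_clones(n, n, seed = 11)
    res <- dosage_ttest(sim$level, as.character(classify_ratio(sim$ratio)))
    res$ratio_of_means
  }, numeric(1))
  expect_lt(abs(ratios[2] - 0.5), abs(ratios[1] - 0.5) + 0.02)
  expect_lt(abs(ratios[2] - 0.5), 0.03)
})

test_that("protein-mRNA regression reuses the OLS contract", {
  rna <- seq(0.2, 2, length.out = 11)
  res <- protein_rna_regression(0.8 * rna, rna)
  expect_equal(res$slope, 0.8, tolerance = 1e-9)
  expect_equal(res$r_squared, 1)
  expect_equal(res$df2, 9L)  # 11 clones -> F(1, 9)

  set.seed(52)
  protein <- 0.8 * rna + rnorm(11, 0, 0.1)
  res <- protein_rna_regression(protein, rna)
  oracle <- oracle_ols(rna, protein)
  expect_equal(res$f_stat, oracle$f_stat, tolerance = 1e-9)
})

test_that("screen hit rule: above mean + 3 SD in both clones, ND never hits", {
  silent <- c(cl31 = "ref", cl84 = "cast")
  ctrl <- expand.grid(compound_id = sprintf("control_%02d", 1:11),
                      clone_id = names(silent), stringsAsFactors = FALSE)
  ctrl$is_control <- TRUE
  # silent fraction 0.02 in every control well, except spread for SD
  sfrac <- rep(c(0.01, 0.02, 0.03), length.out = 22)
  ctrl$ratio <- ifelse(ctrl$clone_id == "cl84", sfrac, 1 - sfrac)

  cmpd <- data.frame(
    compound_id = c("hit", "hit", "one_sided", "one_sided", "nd"),
    clone_id = c("cl31", "cl84", "cl31", "cl84", "cl31"),
    is_control = FALSE,
    ratio = c(1 - 0.30, 0.30,   # strong shift in both clones
              1 - 0.30, 0.02,   # shift in clone 31 only
              1 - 0.30)         # measured in one clone only
  )
  res <- call_screen_hits(rbind(ctrl, cmpd), silent)
  expect_equal(res$hits, "hit")
  expect_false("one_sided" %in% res$hits)
  expect_true("nd" %in% res$nd)
  # threshold is the control mean + 3 * sample SD of the silent fraction
  thr <- res$thresholds[res$thresholds$clone_id == "cl31", ]
  expect_equal(thr$threshold, mean(sfrac[1:11]) + 3 * sd(sfrac[1:11]),
               tolerance = 1e-12)

  # a compound sitting exactly at the control mean is never a hit
  at_mean <- data.frame(
    compound_id = "null", clone_id = names(silent), is_control = FALSE,
    ratio = c(1 - mean(sfrac[1:11]), mean(sfrac[12:22]))
  )
  res <- call_screen_hits(rbind(ctrl, at_mean), silent)
  expect_length(res$hits, 0)
})

test_that("simulated screens call every strong hit and control false calls", {
  # 10-sigma effects are always called
  for (s in 1:20) {
    sim <- simulate_screen_plate(50, 5, control_sd = 0.01, hit_effect = 0.1,
                                 seed = s)
    res <- call_screen_hits(sim$plate, sim$silent_allele)
    expect_setequal(res$hits, sim$truth$compound_id[sim$truth$is_hit])
  }
  # zero noise: exactly the true hits
  sim <- simulate_screen_plate(30, 4, control_sd = 1e-9, hit_effect = 0.05,
                               seed = 1)
  res <- call_screen_hits(sim$plate, sim$silent_allele)
  expect_setequal(res$hits, sim$truth$compound_id[sim$truth$is_hit])
})

test_that("4PL dose-response recovers exact and noisy parameters", {
  doses <- rep(c(0.01, 0.1, 0.3, 1, 3, 10, 30), each = 3)
  y_exact <- 0 + (1 - 0) / (1 + 10^(1 * (log10(1) - log10(doses))))
  fit <- fit_dose_response(doses, y_exact, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_lte(fit$bottom, fit$top)

  # noisy replicates: EC50 within +/- 10% across seeds
  ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    y <- y_exact + rnorm(length(doses), 0, 0.02)
    fit <- fit_dose_response(doses, y, seed = s)
    if (fit$converged && abs(fit$ec50 - 1) < 0.1) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("zero-dose wells anchor the bottom asymptote", {
  doses <- rep(c(0, 0.1, 1, 10, 100), each = 3)
  true_bottom <- 0.05
  y <- true_bottom + (0.9 - true_bottom) /
    (1 + 10^(1.2 * (log10(2) - log10(pmax(doses, 1e-3)))))
  y[doses == 0] <- true_bottom
  fit <- fit_dose_response(doses, y, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$bottom, true_bottom, tolerance = 0.01)
  expect_equal(fit$ec50, 2, tolerance = 0.2)
})
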