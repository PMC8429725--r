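#' Two-sample Kolmogorov-Smirnov comparison of allelic-ratio distributions
#'
#' Used to compare the cumulative distributions of allelic expression ratios
#' between cell types (e.g. ESC clones vs NPC clones).
#'
#' @param sample_a,sample_b Non-empty numeric vectors of ratios.
#' @return List with `D` (maximum ECDF gap) and `p_value` (asymptotic).
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("samples must be non-empty")
  res <- suppressWarnings(ks.test(sample_a, sample_b))
  list(D = unname(res$statistic), p_value = res$p.value)
}

#' Per-clone stability of allelic ratios between two timepoints
#'
#' For each clone, computes the Pearson correlation of per-gene allelic ratios
#' between two states (e.g. NPC clone vs its differentiated astrocytes) over
#' the genes whose read counts pass the filter at both timepoints. High r
#' means the clone's allelic choices are mitotically stable.
#'
#' @param pairs Data frame with columns `clone_id`, `gene_id`, `ratio_t1`,
#'   `reads_t1`, `ratio_t2`, `reads_t2`.
#' @param min_reads Minimum allele-specific reads at each timepoint
#'   (default 20).
#' @return Data frame with one row per clone: `clone_id`, `r` (`NA` with
#'   status `"undefined"` when fewer than 3 genes remain), `n_genes`,
#'   `status`.
#' @export
stability_correlation <- function(pairs, min_reads = 20L) {
  clones <- unique(pairs$clone_id)
  keep <- pairs$reads_t1 >= min_reads & pairs$reads_t2 >= min_reads &
    is.finite(pairs$ratio_t1) & is.finite(pairs$ratio_t2)
  pairs <- pairs[keep, , drop = FALSE]
  out <- lapply(clones, function(cl) {
    sub <- pairs[pairs$clone_id == cl, , drop = FALSE]
    if (nrow(sub) < 3) {
      data.frame(clone_id = cl, r = NA_real_, n_genes = nrow(sub),
                 status = "undefined", stringsAsFactors = FALSE)
    } else {
      data.frame(clone_id = cl, r = cor(sub$ratio_t1, sub$ratio_t2),
                 n_genes = nrow(sub), status = "ok", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Split clones into high- and low-expression groups
#'
#' @param levels Numeric vector of relative expression levels (normalised to
#'   housekeeping genes).
#' @param threshold Level at or above which a clone is "high". The threshold
#'   is a required analysis choice; [propose_expression_threshold()] can
#'   suggest one from the bimodality of log-levels.
#' @return Character vector of `"high"` / `"low"` labels. Warns when one group
#'   is empty (the dosage comparison is then undefined).
#' @export
split_expression_groups <- function(levels, threshold) {
  groups <- ifelse(levels >= threshold, "high", "low")
  if (length(unique(groups)) < 2) {
    warning("all clones fall in one expression group; dosage test undefined")
  }
  groups
}

#' Propose a high/low expression threshold from a 2-component mixture
#'
#' Fits a two-component Gaussian mixture to log-transformed expression levels
#' and returns the point between the two component means where the weighted
#' densities cross (the antimode), back-transformed to the level scale.
#'
#' @param levels Positive expression levels.
#' @param seed Seed for the mixture fit restarts.
#' @return Proposed threshold on the level scale.
#' @export
propose_expression_threshold <- function(levels, seed = 1L) {
  if (any(levels <= 0)) stop("expression levels must be positive")
  x <- log(levels)
  fit <- em_fit(x, K = 2, seed = seed)
  grid <- seq(fit$means[1], fit$means[2], length.out = 2001)
  d1 <- fit$weights[1] * dnorm(grid, fit$means[1], sqrt(fit$variances[1]))
  d2 <- fit$weights[2] * dnorm(grid, fit$means[2], sqrt(fit$variances[2]))
  exp(grid[which.min(abs(d1 - d2))])
}

#' Dosage comparison: expression in monoallelic vs biallelic clones
#'
#' Among high-expression clones, compares mean expression levels between
#' monoallelic clones (either direction) and biallelic clones with a
#' two-tailed unpaired Student t-test (equal variances, df = n1 + n2 - 2).
#' Biased clones are excluded. If one functional allele produces half the
#' mRNA of two, the mono/biallelic mean ratio is ~0.5.
#'
#' @param levels Numeric expression levels of the (high-expression) clones.
#' @param categories Allelic category per clone, as returned by
#'   [classify_ratio()].
#' @return List with `t`, `df`, `p_value`, `mean_monoallelic`,
#'   `mean_biallelic`, `ratio_of_means` (mono/biallelic), `n_monoallelic`,
#'   `n_biallelic`.
#' @export
dosage_ttest <- function(levels, categories) {
  categories <- as.character(categories)
  mono <- levels[categories %in% c("monoallelic_129", "monoallelic_cast")]
  bi <- levels[categories == "biallelic"]
  if (length(mono) < 2 || length(bi) < 2) {
    stop("need >= 2 monoallelic and >= 2 biallelic clones")
  }
  res <- t.test(mono, bi, var.equal = TRUE)
  list(
    t = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value,
    mean_monoallelic = mean(mono), mean_biallelic = mean(bi),
    ratio_of_means = mean(mono) / mean(bi),
    n_monoallelic = length(mono), n_biallelic = length(bi)
  )
}

#' Linear regression of protein level on mRNA abundance
#'
#' Tests whether allelic dosage effects propagate to the protein level:
#' ordinary least squares of normalised protein level on relative mRNA
#' abundance across clones, with the overall F test on (1, n - 2) df.
#'
#' @param protein,rna Paired numeric vectors per clone (n >= 3).
#' @return Same one-row data frame as [regress_peak()].
#' @export
protein_rna_regression <- function(protein, rna) {
  regress_peak(rna, protein)
}

#' Call epidrug screen hits from post-treatment allelic ratios
#'
#' Two clones silencing opposite alleles are treated with each compound; the
#' readout is the allelic expression ratio after treatment. Per clone, the
#' compound's measurement is re-expressed as the fraction of expression from
#' that clone's *silent* allele, and compared with the clone's own control
#' wells: a compound is a hit iff its silent-allele fraction exceeds
#' `control mean + n_sigma * control SD` (sample SD, n-1) in BOTH clones.
#' Compounds missing a measurement in either clone are marked `ND` and are
#' never hits.
#'
#' @param plate Data frame with columns `compound_id`, `clone_id`, `ratio`
#'   (Cast fraction in \[0,1\]) and logical `is_control`.
#' @param silent_allele Named character vector mapping each clone id to
#'   `"cast"` or `"ref"` (which allele that clone silences).
#' @param n_sigma Threshold multiplier (default 3).
#' @return A `screen_hits` list: `per_clone` (data frame compound x clone with
#'   `silent_fraction`, `effect` = silent fraction minus control mean,
#'   `above_threshold`), `thresholds` (per-clone control mean, SD, threshold),
#'   `hits` (compound ids above threshold in both clones), `nd` (compound ids
#'   with missing data).
#' @export
call_screen_hits <- function(plate, silent_allele, n_sigma = 3) {
  clones <- names(silent_allele)
  if (length(clones) < 2) stop("need at least two clones")
  if (!all(silent_allele %in% c("cast", "ref"))) {
    stop("silent_allele values must be 'cast' or 'ref'")
  }
  silent_frac <- function(ratio, clone) {
    if (silent_allele[[clone]] == "cast") ratio else 1 - ratio
  }
  thresholds <- lapply(clones, function(cl) {
    ctrl <- plate[plate$is_control & plate$clone_id == cl, , drop = FALSE]
    if (nrow(ctrl) < 2) stop("need >= 2 control wells per clone: ", cl)
    s <- silent_frac(ctrl$ratio, cl)
    data.frame(clone_id = cl, control_mean = mean(s), control_sd = sd(s),
               threshold = mean(s) + n_sigma * sd(s),
               n_controls = nrow(ctrl), stringsAsFactors = FALSE)
  })
  thresholds <- do.call(rbind, thresholds)
  compounds <- unique(plate$compound_id[!plate$is_control])
  per_clone <- list()
  for (cl in clones) {
    thr <- thresholds[thresholds$clone_id == cl, ]
    sub <- plate[!plate$is_control & plate$clone_id == cl, , drop = FALSE]
    s <- silent_frac(sub$ratio, cl)
    per_clone[[cl]] <- data.frame(
      compound_id = sub$compound_id, clone_id = cl,
      silent_fraction = s, effect = s - thr$control_mean,
      above_threshold = s > thr$threshold, stringsAsFactors = FALSE
    )
  }
  per_clone <- do.call(rbind, per_clone)
  measured <- table(per_clone$compound_id)
  nd <- union(
    compounds[!(compounds %in% names(measured))],
    names(measured)[measured < length(clones)]
  )
  complete <- setdiff(compounds, nd)
  hits <- vapply(complete, function(cid) {
    all(per_clone$above_threshold[per_clone$compound_id == cid])
  }, logical(1))
  structure(
    list(
      per_clone = per_clone, thresholds = thresholds,
      hits = complete[hits], nd = nd, n_sigma = n_sigma
    ),
    class = "screen_hits"
  )
}

#' @export
print.screen_hits <- function(x, ...) {
  cat(sprintf(
    "Screen: %d hits (> mean + %g SD in both clones), %d compounds ND\n",
    length(x$hits), x$n_sigma, length(x$nd)
  ))
  if (length(x$hits)) cat("hits:", paste(x$hits, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on log10(dose):
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(ec50) - log10(dose))))`.
#' Zero doses (vehicle wells) are placed at a configurable floor so they
#' anchor the bottom asymptote. Fitting uses Levenberg-Marquardt
#' (`minpack.lm::nlsLM`) from a grid of starting values plus seeded jitter to
#' avoid local minima; the lowest-SSE convergent fit is returned.
#'
#' @param doses Dose per well (uM); zero allowed.
#' @param responses Response per well (allelic ratio or ratio shift).
#' @param seed Seed for the jittered multistart.
#' @param zero_dose_floor_decades Decades below the lowest nonzero dose at
#'   which zero doses are placed (default 2).
#' @return A `dose_response` object: list with `bottom`, `top`, `ec50` (uM),
#'   `hill`, `sse`, `converged`, `n`. `bottom <= top` after orientation
#'   normalisation (a falling curve is expressed with negative `hill`).
#'   `converged = FALSE` with `NA` parameters when no start converges.
#' @export
fit_dose_response <- function(doses, responses, seed = 1L,
                              zero_dose_floor_decades = 2) {
  if (length(doses) != length(responses)) stop("doses and responses paired")
  if (length(unique(doses)) < 4) stop("need >= 4 dose levels")
  nonzero <- doses[doses > 0]
  floor_dose <- min(nonzero) / 10^zero_dose_floor_decades
  x <- log10(pmax(doses, floor_dose))
  y <- responses
  fourpl <- function(x, bottom, top, logec50, hill) {
    bottom + (top - bottom) / (1 + 10^(hill * (logec50 - x)))
  }
  set.seed(as.integer(seed))
  starts <- expand.grid(
    logec50 = quantile(unique(x), c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(0.5, 1, 2, -1)
  )
  starts <- rbind(
    starts,
    data.frame(logec50 = runif(6, min(x), max(x)),
               hill = runif(6, -3, 3))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fourpl(x, bottom, top, logec50, hill),
        start = list(bottom = min(y), top = max(y),
                     logec50 = starts$logec50[i], hill = starts$hill[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(coef = coef(fit), sse = sse)
    }
  }
  if (is.null(best)) {
    return(structure(
      list(bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
           hill = NA_real_, sse = NA_real_, converged = FALSE,
           n = length(doses)),
      class = "dose_response"
    ))
  }
  cf <- best$coef
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  hill <- unname(cf["hill"])
  if (bottom > top) {
    # re-express with swapped asymptotes: identical curve, negative hill
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  structure(
    list(
      bottom = bottom, top = top, ec50 = 10^unname(cf["logec50"]),
      hill = hill, sse = best$sse, converged = TRUE, n = length(doses)
    ),
    class = "dose_response"
  )
}

#' @export
print.dose_response <- function(x, ...) {
  if (!x$converged) {
    cat("4PL dose-response: no convergent fit\n")
  } else {
    cat(sprintf(
      "4PL dose-response: EC50 = %.3g uM, hill = %.2f, range [%.3g, %.3g], SSE = %.3g\n",
      x$ec50, x$hill, x$bottom, x$top, x$sse
    ))
  }
  invisible(x)
}
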