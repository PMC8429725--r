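#' Construct a nascent RNA-FISH cell tally
#'
#' @param n0,n1,n2 Counts of cells showing 0, 1 or 2 nascent transcription
#'   signals (pinpoints). A cell has two alleles, so `n_tot = n1 + 2*n2`
#'   pinpoints over `N_cells = n0 + n1 + n2` cells.
#' @param region_id,animal_id Identifiers for the tissue region (e.g. CA1) and
#'   the animal (optional).
#' @return A `fish_counts` data frame row with derived `N_cells` and `n_tot`.
#' @export
fish_counts <- function(n0, n1, n2, region_id = "region", animal_id = NA) {
  if (any(c(n0, n1, n2) < 0)) stop("cell counts must be non-negative")
  out <- data.frame(
    region_id = region_id, animal_id = animal_id,
    n0 = as.integer(n0), n1 = as.integer(n1), n2 = as.integer(n2),
    stringsAsFactors = FALSE
  )
  out$N_cells <- out$n0 + out$n1 + out$n2
  out$n_tot <- out$n1 + 2L * out$n2
  if (any(out$N_cells < 1)) stop("N_cells must be >= 1")
  class(out) <- c("fish_counts", class(out))
  out
}

#' Estimate the per-allele detection probability from a FISH tally
#'
#' For a biallelic gene with identical, unsynchronised alleles the probability
#' of detecting an active allele's nascent RNA is estimated as
#' `P_detect = n_tot / (2 * N_cells)`: total pinpoints over total alleles.
#' `P_detect` folds together the probability of being in the ON phase of
#' transcription and the detection sensitivity of the FISH assay; the two are
#' not separately identifiable from these data.
#'
#' @param counts A `fish_counts` row (or any list with `n0`, `n1`, `n2`).
#' @return Estimated detection probability in \[0,1\].
#' @export
estimate_p_detect <- function(counts) {
  N <- counts$n0 + counts$n1 + counts$n2
  if (any(N < 1)) stop("N_cells must be >= 1")
  (counts$n1 + 2 * counts$n2) / (2 * N)
}

#' Expected cells with 0/1/2 detected alleles under independent detection
#'
#' If monoallelic-looking cells arise only from transcriptional bursting or
#' missed detection, each of a cell's two alleles is detected independently
#' with probability `p` and the number of detected alleles is Binomial(2, p):
#' `e0 = N(1-p)^2`, `e1 = 2Np(1-p)`, `e2 = Np^2`.
#'
#' @param p Detection probability in \[0,1\].
#' @param N Number of cells (>= 1).
#' @return Numeric vector `c(e0, e1, e2)` summing to `N`.
#' @export
expected_allele_counts <- function(p, N) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (N < 1) stop("N must be >= 1")
  c(e0 = N * (1 - p)^2, e1 = 2 * N * p * (1 - p), e2 = N * p^2)
}

#' Goodness-of-fit test for stable monoallelic expression in FISH tallies
#'
#' Tests whether the observed cells with 0/1/2 nascent signals are compatible
#' with purely bursty biallelic expression. Under the null, detected-allele
#' counts follow Binomial(2, P_detect) with P_detect estimated from the tally;
#' an excess of single-signal cells indicates a population with one stably
#' silent allele. The chi-squared statistic is compared to a chi-squared
#' distribution with one degree of freedom (three classes, minus one, minus
#' one estimated parameter).
#'
#' @param counts A `fish_counts` row (or list with `n0`, `n1`, `n2`).
#' @return A `burst_test` object: list with `p_detect`, `expected` (e0, e1,
#'   e2), `chi2`, `df = 1`, `p_value`, `low_expected_warning` (TRUE when any
#'   expected class < 5).
#' @examples
#' burst_gof_test(fish_counts(10, 30, 60))  # chi2 = 4, p ~ 0.0455
#' @export
burst_gof_test <- function(counts) {
  obs <- c(counts$n0, counts$n1, counts$n2)
  N <- sum(obs)
  if (N < 1) stop("N_cells must be >= 1")
  p <- estimate_p_detect(counts)
  e <- expected_allele_counts(p, N)
  keep <- !(e == 0 & obs == 0)
  if (any(e == 0 & obs > 0)) {
    chi2 <- Inf
    p_value <- 0
    warning("observed cells in a class with zero expected count")
  } else {
    chi2 <- sum((obs[keep] - e[keep])^2 / e[keep])
    p_value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(
      p_detect = p, expected = e, chi2 = chi2, df = 1L, p_value = p_value,
      N_cells = N, low_expected_warning = any(e < 5)
    ),
    class = "burst_test"
  )
}

#' @export
print.burst_test <- function(x, ...) {
  cat(sprintf(
    "Burst GOF test: P_detect = %.3f, chi2 = %.3f (df = 1), p = %.4g%s\n",
    x$p_detect, x$chi2, x$p_value,
    if (x$low_expected_warning) " [expected class < 5]" else ""
  ))
  invisible(x)
}

#' Pool FISH tallies across animals or regions
#'
#' Sums the 0/1/2-signal cell counts over rows sharing the pooling key. The
#' binomial model assumes the pooled cells are homogeneous (same cell type,
#' genetically identical alleles), so pooling across different regions is an
#' error unless `allow_mixed = TRUE`.
#'
#' @param counts A `fish_counts` data frame (several rows).
#' @param by `"region"` (pool animals within a region, the default) or
#'   `"animal"`.
#' @param allow_mixed Permit pooling rows from different regions.
#' @return A `fish_counts` data frame with one row per pooling key.
#' @export
pool_regions <- function(counts, by = c("region", "animal"),
                         allow_mixed = FALSE) {
  by <- match.arg(by)
  key <- if (by == "region") counts$region_id else counts$animal_id
  if (by == "animal" && length(unique(counts$region_id)) > 1 && !allow_mixed) {
    stop("refusing to pool cells across different regions; ",
         "set allow_mixed = TRUE to override")
  }
  agg <- aggregate(counts[c("n0", "n1", "n2")], by = list(key = key), sum)
  fish_counts(
    n0 = agg$n0, n1 = agg$n1, n2 = agg$n2,
    region_id = if (by == "region") agg$key else
      paste(unique(counts$region_id), collapse = "+"),
    animal_id = if (by == "animal") agg$key else NA
  )
}
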