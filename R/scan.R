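#' Select accessible-chromatin peaks within a window around a gene's TSS
#'
#' Keeps the peaks whose midpoint falls within `tss +/- window_bp` and that
#' contain at least one strain-discriminating SNP (without a SNP the peak has
#' no allele-specific reads and cannot be analysed). Coordinates are 0-based
#' half-open (BED convention); window membership is decided on the midpoint so
#' peaks straddling the edge are handled deterministically.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end`, `peak_id` and
#'   logical `has_snp`.
#' @param tss TSS coordinate (bp) of the gene of interest.
#' @param window_bp Half-width of the scan window; default 3 Mb.
#' @return The retained rows of `peaks`, with an attribute
#'   `n_dropped_no_snp` counting in-window peaks discarded for lacking a SNP.
#' @export
select_window_peaks <- function(peaks, tss, window_bp = 3e6) {
  if (is.null(tss) || is.na(tss)) stop("missing TSS coordinate")
  if (window_bp <= 0) stop("window_bp must be positive")
  mid <- (peaks$start + peaks$end) / 2
  in_window <- mid >= tss - window_bp & mid <= tss + window_bp
  kept <- peaks[in_window & peaks$has_snp, , drop = FALSE]
  attr(kept, "n_dropped_no_snp") <- sum(in_window & !peaks$has_snp)
  kept
}

#' Filter a peak's per-clone allelic series before regression
#'
#' A peak enters the accessibility-expression regression only if, after
#' dropping clones with fewer than `min_reads` allele-specific ATAC reads, it
#' retains at least `min_values` clones and at least `min_biased_clones` of
#' them show an allelic expression bias for the target gene (RNA ratio below
#' `bias_lo` or above `bias_hi`). Without biased clones there is no allelic
#' signal to explain and the regression is uninformative.
#'
#' @param series Data frame with columns `clone_id`, `atac_ratio`,
#'   `atac_reads`, `rna_ratio` (the target gene's RNA allelic ratio in the
#'   same clone).
#' @param min_reads Minimum allele-specific ATAC reads per clone (default 10).
#' @param min_values Minimum clones retained (default 4, i.e. "more than
#'   three values").
#' @param bias_lo,bias_hi Expression-bias bounds (defaults 1/3 and 2/3).
#' @param min_biased_clones Minimum biased clones (default 2).
#' @return List with `series` (the retained rows) and `status`: `"tested"`,
#'   `"excluded_few_values"` or `"excluded_no_bias"`.
#' @export
apply_scan_filters <- function(series, min_reads = 10L, min_values = 4L,
                               bias_lo = 1 / 3, bias_hi = 2 / 3,
                               min_biased_clones = 2L) {
  keep <- series$atac_reads >= min_reads &
    is.finite(series$atac_ratio) & is.finite(series$rna_ratio)
  series <- series[keep, , drop = FALSE]
  if (nrow(series) < min_values) {
    return(list(series = series, status = "excluded_few_values"))
  }
  biased <- series$rna_ratio < bias_lo | series$rna_ratio > bias_hi
  if (sum(biased) < min_biased_clones) {
    return(list(series = series, status = "excluded_no_bias"))
  }
  list(series = series, status = "tested")
}

#' Regress allelic expression on allelic accessibility for one peak
#'
#' Ordinary least squares of the gene's RNA allelic ratio on the peak's ATAC
#' allelic ratio across clones, with the overall F test
#' `F = (n - 2) * R^2 / (1 - R^2)` on (1, n - 2) degrees of freedom. F, R^2
#' and the p-value are symmetric in the two variables; only the slope depends
#' on the regression direction.
#'
#' @param atac,rna Paired numeric vectors of per-clone ratios (n >= 3).
#' @return A one-row data frame: `n_clones_used`, `slope`, `intercept`,
#'   `r_squared`, `f_stat`, `df1`, `df2`, `p_raw`, `status` (`"tested"` or
#'   `"degenerate_predictor"` when the ATAC ratios are constant).
#' @export
regress_peak <- function(atac, rna) {
  if (length(atac) != length(rna)) stop("atac and rna must be paired")
  n <- length(atac)
  if (n < 3) stop("need at least 3 paired clones")
  sxx <- sum((atac - mean(atac))^2)
  if (sxx == 0) {
    return(data.frame(
      n_clones_used = n, slope = NA_real_, intercept = NA_real_,
      r_squared = NA_real_, f_stat = NA_real_, df1 = 1L, df2 = n - 2L,
      p_raw = NA_real_, status = "degenerate_predictor",
      stringsAsFactors = FALSE
    ))
  }
  fit <- lm(rna ~ atac)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  syy <- sum((rna - mean(rna))^2)
  rss <- sum(residuals(fit)^2)
  r2 <- if (syy == 0) 0 else 1 - rss / syy
  r2 <- min(max(r2, 0), 1)
  f_stat <- if (r2 >= 1) Inf else (n - 2) * r2 / (1 - r2)
  p_raw <- pf(f_stat, 1, n - 2, lower.tail = FALSE)
  data.frame(
    n_clones_used = n, slope = slope, intercept = intercept,
    r_squared = r2, f_stat = f_stat, df1 = 1L, df2 = n - 2L,
    p_raw = p_raw, status = "tested", stringsAsFactors = FALSE
  )
}

#' Scan the peaks around a gene's TSS for accessibility coupled to expression
#'
#' Full per-gene scan: select in-window SNP-containing peaks, build each
#' peak's per-clone allelic series, apply the read/value/bias filters, regress
#' RNA allelic ratio on ATAC allelic ratio per peak, Bonferroni-adjust the
#' p-values over the peaks actually tested for this gene, and report the peak
#' with the smallest adjusted p (ties broken toward the peak nearest the TSS).
#'
#' @param gene_id Gene identifier (used to label the result).
#' @param tss TSS coordinate (bp).
#' @param peaks Peak table (see [select_window_peaks()]).
#' @param atac_counts Long data frame `peak_id`, `clone_id`, `cast_count`,
#'   `ref_count` of allele-specific ATAC reads.
#' @param rna_ratios Named numeric vector: the gene's RNA allelic ratio per
#'   clone (names are clone ids); clones with `NA` are ignored.
#' @param window_bp,min_reads,min_values,bias_lo,bias_hi,min_biased_clones
#'   Filter settings, see [select_window_peaks()] and [apply_scan_filters()].
#' @return A `scan_result`: list with `gene_id`, `tss`, `window_bp`,
#'   `m_tested`, `regressions` (one row per in-window peak with status and,
#'   for tested peaks, statistics and Bonferroni-adjusted `p_adjusted` =
#'   `min(1, m_tested * p_raw)`), `best_peak` (`NA` when nothing was tested),
#'   and exclusion counts.
#' @export
scan_gene <- function(gene_id, tss, peaks, atac_counts, rna_ratios,
                      window_bp = 3e6, min_reads = 10L, min_values = 4L,
                      bias_lo = 1 / 3, bias_hi = 2 / 3,
                      min_biased_clones = 2L) {
  windowed <- select_window_peaks(peaks, tss, window_bp)
  if (!nrow(windowed)) stop("no peaks in the scan window")
  rna_ratios <- rna_ratios[!is.na(rna_ratios)]
  rows <- vector("list", nrow(windowed))
  for (i in seq_len(nrow(windowed))) {
    pid <- windowed$peak_id[i]
    pc <- atac_counts[atac_counts$peak_id == pid, , drop = FALSE]
    pc <- pc[as.character(pc$clone_id) %in% names(rna_ratios), , drop = FALSE]
    total <- pc$cast_count + pc$ref_count
    series <- data.frame(
      clone_id = as.character(pc$clone_id),
      atac_ratio = ifelse(total > 0, pc$cast_count / total, NA_real_),
      atac_reads = total,
      rna_ratio = rna_ratios[as.character(pc$clone_id)],
      stringsAsFactors = FALSE
    )
    filt <- apply_scan_filters(series, min_reads, min_values,
                               bias_lo, bias_hi, min_biased_clones)
    if (filt$status != "tested") {
      rows[[i]] <- data.frame(
        peak_id = pid, n_clones_used = nrow(filt$series),
        slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
        f_stat = NA_real_, df1 = 1L, df2 = NA_integer_, p_raw = NA_real_,
        status = filt$status, stringsAsFactors = FALSE
      )
    } else {
      reg <- regress_peak(filt$series$atac_ratio, filt$series$rna_ratio)
      rows[[i]] <- cbind(data.frame(peak_id = pid), reg)
    }
  }
  regressions <- do.call(rbind, rows)
  regressions$midpoint <- (windowed$start + windowed$end) / 2
  tested <- regressions$status == "tested"
  m <- sum(tested)
  regressions$p_adjusted <- NA_real_
  regressions$p_adjusted[tested] <- pmin(1, m * regressions$p_raw[tested])
  best_peak <- NA_character_
  if (m >= 1) {
    cand <- regressions[tested, , drop = FALSE]
    ord <- order(cand$p_adjusted, abs(cand$midpoint - tss))
    best_peak <- cand$peak_id[ord[1L]]
  } else {
    warning("no peak passed the scan filters; nothing tested")
  }
  structure(
    list(
      gene_id = gene_id, tss = tss, window_bp = window_bp,
      m_tested = m, regressions = regressions, best_peak = best_peak,
      n_dropped_no_snp = attr(windowed, "n_dropped_no_snp"),
      n_excluded_few_values = sum(regressions$status == "excluded_few_values"),
      n_excluded_no_bias = sum(regressions$status == "excluded_no_bias")
    ),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "Regulatory scan for %s: %d peaks in +/-%g Mb window, %d tested\n",
    x$gene_id, nrow(x$regressions), x$window_bp / 1e6, x$m_tested
  ))
  if (!is.na(x$best_peak)) {
    best <- x$regressions[x$regressions$peak_id == x$best_peak, ]
    cat(sprintf(
      "best peak: %s  F(1,%d) = %.2f, p_adj = %.3g\n",
      x$best_peak, best$df2, best$f_stat, best$p_adjusted
    ))
  }
  invisible(x)
}
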