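#' Allelic category levels, in genomic order from 129-monoallelic to
#' Cast-monoallelic.
#' @keywords internal
ALLELIC_CATEGORIES <- c(
  "monoallelic_129", "biased_129", "biallelic", "biased_cast", "monoallelic_cast"
)

#' Compute an allelic expression/accessibility ratio from allele-specific counts
#'
#' The allelic ratio is the fraction of allele-specific signal assigned to the
#' Castaneus (Cast) allele over the total (Cast + 129/Sv). Entries whose total
#' allele-specific read count falls below `min_reads` are flagged
#' `excluded_low_reads` and carry an `NA` ratio: low-coverage ratios are too
#' noisy to interpret and are removed before any downstream modelling.
#'
#' @param cast Non-negative integer vector: reads (or pyrosequencing signal
#'   units) assigned to the Cast allele.
#' @param ref Non-negative integer vector: reads assigned to the 129/Sv allele.
#' @param min_reads Minimum informative (Cast + 129) reads for a usable ratio.
#'   Default 20, the RNA-seq gene-level filter; use 10 for ATAC peaks.
#' @return A data frame with columns `value` (fraction in \[0,1\], `NA` when
#'   excluded), `n_informative` (total allele-specific reads) and `status`
#'   (`"ok"` or `"excluded_low_reads"`).
#' @examples
#' compute_allelic_ratio(80, 20)           # 0.80, ok
#' compute_allelic_ratio(10, 5)            # excluded: only 15 informative reads
#' @export
compute_allelic_ratio <- function(cast, ref, min_reads = 20L) {
  if (length(cast) != length(ref)) {
    stop("`cast` and `ref` must have equal length")
  }
  if (any(!is.finite(cast)) || any(!is.finite(ref))) {
    stop("counts must be finite")
  }
  if (any(cast < 0) || any(ref < 0)) {
    stop("counts must be non-negative")
  }
  total <- cast + ref
  if (min_reads < 1 && any(total == 0)) {
    stop("allelic ratio undefined: zero informative reads with min_reads = 0")
  }
  ok <- total >= min_reads
  value <- ifelse(ok, cast / total, NA_real_)
  data.frame(
    value = value,
    n_informative = as.integer(total),
    status = ifelse(ok, "ok", "excluded_low_reads"),
    stringsAsFactors = FALSE
  )
}

#' Build a gene-by-clone allelic ratio matrix from a long count table
#'
#' @param counts Data frame with columns `gene_id`, `clone_id`, `cast_count`,
#'   `ref_count` — one row per gene x clone. Duplicate (gene, clone) pairs are
#'   an error.
#' @param min_reads Read filter passed to [compute_allelic_ratio()].
#' @param provenance Label recording where the ratios come from
#'   (`"RNA-seq"`, `"pyrosequencing"` or `"ATAC-seq"`).
#' @return A `ratio_matrix` object: list with `ratios` (genes x clones numeric
#'   matrix, `NA` for excluded or absent entries), `n_informative` (same shape),
#'   `n_excluded_low_reads`, and `provenance`.
#' @export
build_ratio_matrix <- function(counts, min_reads = 20L, provenance = "RNA-seq") {
  required <- c("gene_id", "clone_id", "cast_count", "ref_count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    stop("missing column ", paste(missing_cols, collapse = ", "))
  }
  genes <- unique(as.character(counts$gene_id))
  clones <- unique(as.character(counts$clone_id))
  key <- paste(counts$gene_id, counts$clone_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1L]
    stop(sprintf(
      "duplicate (gene, clone) pair: (%s, %s)",
      counts$gene_id[first], counts$clone_id[first]
    ))
  }
  ratios <- matrix(NA_real_, length(genes), length(clones),
                   dimnames = list(genes, clones))
  n_inf <- matrix(NA_integer_, length(genes), length(clones),
                  dimnames = list(genes, clones))
  if (nrow(counts)) {
    r <- compute_allelic_ratio(counts$cast_count, counts$ref_count, min_reads)
    idx <- cbind(
      match(as.character(counts$gene_id), genes),
      match(as.character(counts$clone_id), clones)
    )
    ratios[idx] <- r$value
    n_inf[idx] <- r$n_informative
    n_excl <- sum(r$status == "excluded_low_reads")
  } else {
    n_excl <- 0L
  }
  structure(
    list(
      ratios = ratios, n_informative = n_inf,
      n_excluded_low_reads = n_excl, provenance = provenance,
      min_reads = min_reads
    ),
    class = "ratio_matrix"
  )
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf(
    "ratio_matrix: %d genes x %d clones (%s), %d entries excluded (< %d reads)\n",
    nrow(x$ratios), ncol(x$ratios), x$provenance,
    x$n_excluded_low_reads, x$min_reads
  ))
  invisible(x)
}

#' Classify an allelic ratio into the five allelic categories
#'
#' Categories follow the standard cut-offs: monoallelic when the ratio is below
#' 15% or above 85%, biased in 15–35% or 65–85%, biallelic in between. At the
#' printed interval ends the biased bins are closed (0.15, 0.35, 0.65 and 0.85
#' are all "biased") and the monoallelic/biallelic bins open, so the five bins
#' partition \[0,1\].
#'
#' @param r Numeric vector of ratios in \[0,1\].
#' @return Factor with levels `monoallelic_129 < biased_129 < biallelic <
#'   biased_cast < monoallelic_cast`.
#' @export
classify_ratio <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
    stop("ratios must lie in [0, 1]")
  }
  out <- character(length(r))
  out[r < 0.15] <- "monoallelic_129"
  out[r >= 0.15 & r <= 0.35] <- "biased_129"
  out[r > 0.35 & r < 0.65] <- "biallelic"
  out[r >= 0.65 & r <= 0.85] <- "biased_cast"
  out[r > 0.85] <- "monoallelic_cast"
  factor(out, levels = ALLELIC_CATEGORIES, ordered = TRUE)
}

#' Proportion of clones falling in each allelic category
#'
#' @param ratios Non-empty numeric vector of allelic ratios (`NA`s dropped).
#' @return Named list: `proportions` (length-5 named vector summing to 1),
#'   `monoallelic` (combined 129 + Cast monoallelic proportion), `n`.
#' @export
category_proportions <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) {
    stop("cannot compute category proportions of an empty ratio collection")
  }
  categories <- classify_ratio(ratios)
  counts <- table(categories)
  props <- as.numeric(counts) / length(ratios)
  names(props) <- names(counts)
  list(
    proportions = props,
    monoallelic = unname(props["monoallelic_129"] + props["monoallelic_cast"]),
    n = length(ratios)
  )
}
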