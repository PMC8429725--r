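#' Read a long allele-specific count table
#'
#' Expects a tab-delimited file with a header row and columns `gene_id`,
#' `clone_id`, `cast_count`, `ref_count`. Counts must be non-negative
#' integers; violations are reported with their row number.
#'
#' @param path Path to the file.
#' @return Data frame of typed records.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "clone_id", "cast_count", "ref_count")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("missing column ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("cast_count", "ref_count")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric %s at row %d", col, bad))
    }
    if (any(v != floor(v), na.rm = TRUE)) {
      bad <- which(v != floor(v))[1L]
      stop(sprintf("non-integer %s at row %d", col, bad))
    }
    if (any(v < 0, na.rm = TRUE)) {
      bad <- which(v < 0)[1L]
      stop(sprintf("negative %s at row %d", col, bad))
    }
    tab[[col]] <- as.integer(v)
  }
  tab
}

#' Read a wide pyrosequencing percentage matrix
#'
#' Pyrosequencing reports allelic ratios as percentages without read counts,
#' so no read filter can be applied and informative-read counts are absent.
#' Expects a tab-delimited table with a `gene_id` column followed by one
#' column per clone holding Cast percentages in \[0,100\] (`NA` allowed).
#'
#' @param path Path to the file.
#' @return A `ratio_matrix` (provenance `"pyrosequencing"`) with ratios on
#'   the fraction scale and `n_informative` all `NA`.
#' @export
read_pyro_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) stop("missing column gene_id")
  genes <- as.character(tab$gene_id)
  m <- as.matrix(tab[setdiff(names(tab), "gene_id")])
  if (!is.numeric(m)) stop("clone columns must be numeric percentages")
  if (any(m < 0 | m > 100, na.rm = TRUE)) {
    stop("percentages must lie in [0, 100]")
  }
  ratios <- m / 100
  rownames(ratios) <- genes
  n_inf <- matrix(NA_integer_, nrow(ratios), ncol(ratios),
                  dimnames = dimnames(ratios))
  structure(
    list(ratios = ratios, n_informative = n_inf,
         n_excluded_low_reads = 0L, provenance = "pyrosequencing",
         min_reads = NA_integer_),
    class = "ratio_matrix"
  )
}

#' Read a FISH cell-tally table
#'
#' Tab-delimited with header `region_id`, `animal_id`, `n0`, `n1`, `n2`.
#'
#' @param path Path to the file.
#' @return A `fish_counts` data frame.
#' @export
read_fish_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("region_id", "animal_id", "n0", "n1", "n2")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("missing column ", paste(missing_cols, collapse = ", "))
  }
  fish_counts(tab$n0, tab$n1, tab$n2, tab$region_id, tab$animal_id)
}

#' Read a peak table in BED-like format
#'
#' Tab-delimited with header `chrom`, `start`, `end`, `peak_id` and an
#' optional logical `has_snp` column (assumed TRUE when absent). Coordinates
#' are 0-based half-open.
#'
#' @param path Path to the file.
#' @return Peak data frame for [select_window_peaks()].
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "peak_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("missing column ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$has_snp)) tab$has_snp <- TRUE
  tab$has_snp <- as.logical(tab$has_snp)
  if (any(tab$start >= tab$end)) stop("peak with start >= end")
  tab
}

#' Write a tab-delimited report table
#'
#' All reports are UTF-8 tab-delimited with a header row; ratios are written
#' with full precision so a write/read round trip is lossless to 1e-12.
#'
#' @param x Data frame.
#' @param path Output path (directories created as needed).
#' @return `path`, invisibly.
#' @export
write_report_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mixture-model report
#'
#' @param fit A `mixture_fit` (optionally carrying a `selection` attribute
#'   from [select_model()]).
#' @param ci Optional `param_ci` from [bootstrap_param_ci()]; its bounds are
#'   merged into the component table.
#' @param dir Output directory.
#' @return Paths of the files written (component report and, when available,
#'   the model-selection table).
#' @export
write_mixture_report <- function(fit, dir, ci = NULL) {
  comp <- data.frame(
    component = seq_len(fit$K), weight = fit$weights,
    mean = fit$means, variance = fit$variances
  )
  if (!is.null(ci)) {
    for (p in c("weight", "mean", "variance")) {
      sub <- ci[ci$parameter == p, ]
      comp[[paste0(p, "_lower")]] <- sub$lower[match(comp$component, sub$component)]
      comp[[paste0(p, "_upper")]] <- sub$upper[match(comp$component, sub$component)]
    }
  }
  paths <- write_report_table(comp, file.path(dir, "model_report.tsv"))
  sel <- attr(fit, "selection")
  if (!is.null(sel)) {
    paths <- c(paths, write_report_table(sel, file.path(dir, "model_selection.tsv")))
  }
  invisible(paths)
}

#' Write a regulatory-scan report sorted by adjusted p-value
#'
#' @param scan A `scan_result`.
#' @param dir Output directory.
#' @return Path of `scan_report.tsv`, invisibly.
#' @export
write_scan_report <- function(scan, dir) {
  reg <- scan$regressions
  reg <- reg[order(reg$p_adjusted, method = "radix", na.last = TRUE), ]
  write_report_table(reg, file.path(dir, "scan_report.tsv"))
}

#' Write a run manifest
#'
#' Records the configuration, seed and per-stage record/exclusion counts that
#' make a run reproducible: re-running with the manifest's config and seed
#' regenerates identical tables.
#'
#' @param config Named list of settings (thresholds, seed, inputs); nested
#'   lists are flattened with dotted names.
#' @param counts Named list/vector of record and exclusion counts.
#' @param dir Output directory.
#' @return Path of `manifest.tsv`, invisibly.
#' @export
write_manifest <- function(config, counts, dir) {
  flat <- unlist(config)
  man <- data.frame(
    key = c("r_version", names(flat), names(unlist(counts))),
    value = c(as.character(getRversion()), as.character(flat),
              as.character(unlist(counts))),
    stringsAsFactors = FALSE
  )
  write_report_table(man, file.path(dir, "manifest.tsv"))
}

#' Read a run manifest back as a named list
#'
#' Inverse of [write_manifest()]: keys become names, values stay character
#' (the caller coerces types as needed).
#'
#' @param path Path to a `manifest.tsv`.
#' @return Named character vector of settings and counts.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  man <- utils::read.delim(path, colClasses = "character")
  setNames(man$value, man$key)
}
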