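#' Specify a gene's ground-truth allelic modality structure
#'
#' @param weights,means,sds Parallel numeric vectors describing the mixture of
#'   allelic states: clone-population weights (summing to 1), state means on
#'   the ratio scale \[0,1\] and state SDs.
#' @param read_depth Mean total allele-specific reads per clone (Poisson).
#' @param measurement_sd Additional technical noise added to each clone's
#'   true ratio.
#' @param experiment_weight_concentration Dirichlet concentration controlling
#'   how much the state weights vary between independent differentiation
#'   experiments (`Inf` = identical weights in every experiment; smaller =
#'   more variable allelic choice outcomes per experiment).
#' @return A `gene_modality_spec` list.
#' @export
gene_modality_spec <- function(weights, means, sds, read_depth = 1000,
                               measurement_sd = 0,
                               experiment_weight_concentration = Inf) {
  if (length(weights) != length(means) || length(means) != length(sds)) {
    stop("weights, means and sds must have equal length")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (any(means < 0 | means > 1)) stop("means must lie in [0, 1]")
  if (any(sds <= 0)) stop("sds must be positive")
  structure(
    list(weights = weights, means = means, sds = sds,
         read_depth = read_depth, measurement_sd = measurement_sd,
         experiment_weight_concentration = experiment_weight_concentration),
    class = "gene_modality_spec"
  )
}

#' Preset modality specs mirroring the qualitative regimes seen across genes
#'
#' Three regimes: a single biallelic population (narrow, mean near 0.5), a
#' two-state biased gene (reciprocally biased subpopulations, no full
#' monoallelism), and a three-state RME gene with monoallelic populations in
#' both directions plus a biallelic population.
#'
#' @return Named list of `gene_modality_spec`s: `unimodal_biallelic`,
#'   `bimodal_biased`, `trimodal_rme`.
#' @export
rme_presets <- function() {
  list(
    unimodal_biallelic = gene_modality_spec(1, 0.5, 0.03),
    bimodal_biased = gene_modality_spec(
      c(0.5, 0.5), c(0.25, 0.75), c(0.06, 0.06)
    ),
    trimodal_rme = gene_modality_spec(
      c(0.25, 0.5, 0.25), c(0.05, 0.5, 0.95), c(0.03, 0.03, 0.03)
    )
  )
}

# Dirichlet draw via independent gammas; concentration Inf returns base weights
rdirichlet1 <- function(base_weights, concentration) {
  if (!is.finite(concentration)) return(base_weights)
  g <- rgamma(length(base_weights), shape = concentration * base_weights)
  if (sum(g) == 0) return(base_weights)
  g / sum(g)
}

# Truncated-normal draw on [0,1] by inverse-CDF
rtruncnorm01 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Simulate allele-specific counts for clones of one gene
#'
#' Each clone is assigned to a differentiation experiment; the experiment's
#' state weights are a Dirichlet perturbation of the spec weights (allelic
#' choice outcomes vary between experiments); the clone's allelic state is
#' drawn from those weights; its true ratio is a truncated Gaussian around the
#' state mean plus optional technical noise; sequencing is emulated as
#' `depth ~ Poisson(read_depth)` total allele-specific reads with
#' `cast ~ Binomial(depth, ratio)`.
#'
#' @param spec A [gene_modality_spec()].
#' @param n_clones Number of clones.
#' @param n_experiments Number of independent differentiation experiments the
#'   clones are spread over (round-robin).
#' @param seed Integer seed; identical spec + seed give identical output.
#' @param gene_id Label used in the count table.
#' @return List with `counts` (data frame `gene_id`, `clone_id`,
#'   `cast_count`, `ref_count`) and `truth` (data frame `clone_id`,
#'   `experiment`, `component`, `true_ratio`).
#' @export
simulate_gene_clones <- function(spec, n_clones, n_experiments = 1L, seed = 1L,
                                 gene_id = "gene") {
  if (n_clones < 1) stop("n_clones must be >= 1")
  set.seed(as.integer(seed))
  K <- length(spec$weights)
  exp_weights <- lapply(seq_len(n_experiments), function(e) {
    rdirichlet1(spec$weights, spec$experiment_weight_concentration)
  })
  experiment <- rep_len(seq_len(n_experiments), n_clones)
  component <- integer(n_clones)
  true_ratio <- numeric(n_clones)
  for (i in seq_len(n_clones)) {
    w <- exp_weights[[experiment[i]]]
    component[i] <- sample.int(K, 1, prob = w)
    true_ratio[i] <- rtruncnorm01(1, spec$means[component[i]],
                                  spec$sds[component[i]])
  }
  if (spec$measurement_sd > 0) {
    true_ratio <- true_ratio + rnorm(n_clones, 0, spec$measurement_sd)
  }
  true_ratio <- pmin(pmax(true_ratio, 0), 1)
  depth <- rpois(n_clones, spec$read_depth)
  cast <- rbinom(n_clones, depth, true_ratio)
  clone_id <- sprintf("clone_%03d", seq_len(n_clones))
  list(
    counts = data.frame(
      gene_id = gene_id, clone_id = clone_id,
      cast_count = cast, ref_count = depth - cast,
      stringsAsFactors = FALSE
    ),
    truth = data.frame(
      clone_id = clone_id, experiment = experiment,
      component = component, true_ratio = true_ratio,
      stringsAsFactors = FALSE
    )
  )
}

#' Specify a simulated RNA-FISH cell population
#'
#' @param N_cells Number of cells.
#' @param stable_fraction Fraction of cells with one permanently silent allele
#'   (stable monoallelic expression); the rest are bursty biallelic.
#' @param P_ON Probability an active allele is in the ON transcription phase.
#' @param P_sense FISH detection sensitivity. The per-allele detection
#'   probability is `P_detect = P_ON * P_sense`.
#' @param allele_bias Probability that a stable cell's silent allele is the
#'   reference allele (detection is allele-blind, so this only labels truth).
#' @return A `fish_sim_spec` list.
#' @export
fish_sim_spec <- function(N_cells, stable_fraction = 0, P_ON = 1,
                          P_sense = 1, allele_bias = 0.5) {
  stopifnot(N_cells >= 1)
  fr <- c(stable_fraction, P_ON, P_sense, allele_bias)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  structure(
    list(N_cells = as.integer(N_cells), stable_fraction = stable_fraction,
         P_ON = P_ON, P_sense = P_sense, allele_bias = allele_bias),
    class = "fish_sim_spec"
  )
}

#' Simulate an RNA-FISH cell population and tally detected alleles
#'
#' Stable monoallelic cells have one active allele, detected with probability
#' `P_detect = P_ON * P_sense` (so they show 0 or 1 signal); bursty biallelic
#' cells have two independently detected alleles (0, 1 or 2 signals,
#' Binomial(2, P_detect)). Expected fractions: `E[n2]/N = (1-f) p^2`,
#' `E[n1]/N = f p + (1-f) 2p(1-p)` with `f` the stable fraction.
#'
#' @param spec A [fish_sim_spec()].
#' @param seed Integer seed.
#' @param region_id,animal_id Labels for the resulting tally.
#' @return List with `counts` (a [fish_counts()] row) and `truth` (data frame
#'   per cell: `stable`, `n_detected`).
#' @export
simulate_fish_population <- function(spec, seed = 1L, region_id = "region",
                                     animal_id = NA) {
  set.seed(as.integer(seed))
  N <- spec$N_cells
  p <- spec$P_ON * spec$P_sense
  stable <- runif(N) < spec$stable_fraction
  n_detected <- integer(N)
  n_detected[stable] <- rbinom(sum(stable), 1, p)
  n_detected[!stable] <- rbinom(sum(!stable), 2, p)
  silent_is_ref <- rep(NA, N)
  silent_is_ref[stable] <- runif(sum(stable)) < spec$allele_bias
  tab <- tabulate(n_detected + 1L, 3L)
  list(
    counts = fish_counts(tab[1], tab[2], tab[3], region_id, animal_id),
    truth = data.frame(stable = stable, n_detected = n_detected,
                       silent_is_ref = silent_is_ref)
  )
}

#' Specify a synthetic peak landscape around a TSS
#'
#' @param n_peaks Number of accessible-chromatin peaks in the window.
#' @param tss TSS coordinate (bp).
#' @param window_bp Half-width of the landscape (default 3 Mb).
#' @param coupled_peak_index 1-based index of the peak whose allelic
#'   accessibility tracks allelic expression (the causal regulatory element),
#'   or `NA` for a null landscape in which no peak is coupled.
#' @param coupling_noise_sd SD of the noise between the coupled peak's ATAC
#'   ratio and the clone's RNA ratio.
#' @param baseline_ratio_sd SD of uncoupled peaks' ATAC ratios around 0.5.
#' @param peak_read_depth Mean allele-specific reads per peak per clone
#'   (Poisson).
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(n_peaks, tss = 5e6, window_bp = 3e6,
                           coupled_peak_index = 1L, coupling_noise_sd = 0.05,
                           baseline_ratio_sd = 0.05, peak_read_depth = 100) {
  if (!is.na(coupled_peak_index) &&
      (coupled_peak_index < 1 || coupled_peak_index > n_peaks)) {
    stop("coupled_peak_index out of range")
  }
  structure(
    list(n_peaks = as.integer(n_peaks), tss = tss, window_bp = window_bp,
         coupled_peak_index = as.integer(coupled_peak_index),
         coupling_noise_sd = coupling_noise_sd,
         baseline_ratio_sd = baseline_ratio_sd,
         peak_read_depth = peak_read_depth),
    class = "landscape_spec"
  )
}

#' Simulate a peak landscape with one expression-coupled peak
#'
#' Peaks are placed uniformly in the window around the TSS. The coupled peak's
#' per-clone ATAC allelic ratio equals the clone's RNA allelic ratio plus
#' Gaussian noise (clipped to \[0,1\]); every other peak's ratio is Gaussian
#' around 0.5. Allele-specific reads are Binomial draws at Poisson depth.
#'
#' @param spec A [landscape_spec()].
#' @param clone_rna_ratios Named numeric vector: RNA allelic ratio per clone.
#' @param seed Integer seed.
#' @return List with `peaks` (data frame `chrom`, `start`, `end`, `peak_id`,
#'   `has_snp`), `atac_counts` (long data frame `peak_id`, `clone_id`,
#'   `cast_count`, `ref_count`) and `truth` (list with `coupled_peak_id`,
#'   `atac_ratio` matrix peaks x clones).
#' @export
simulate_peak_landscape <- function(spec, clone_rna_ratios, seed = 1L) {
  set.seed(as.integer(seed))
  n_clones <- length(clone_rna_ratios)
  clone_ids <- names(clone_rna_ratios)
  if (is.null(clone_ids)) {
    clone_ids <- sprintf("clone_%03d", seq_len(n_clones))
    names(clone_rna_ratios) <- clone_ids
  }
  mid <- runif(spec$n_peaks, spec$tss - spec$window_bp,
               spec$tss + spec$window_bp)
  width <- round(runif(spec$n_peaks, 200, 1000))
  start <- pmax(0, round(mid - width / 2))
  peak_id <- sprintf("peak_%04d", seq_len(spec$n_peaks))
  peaks <- data.frame(
    chrom = "chrSim", start = start, end = start + width,
    peak_id = peak_id, has_snp = TRUE, stringsAsFactors = FALSE
  )
  ratio <- matrix(
    pmin(pmax(rnorm(spec$n_peaks * n_clones, 0.5, spec$baseline_ratio_sd),
              0), 1),
    spec$n_peaks, n_clones, dimnames = list(peak_id, clone_ids)
  )
  ci <- spec$coupled_peak_index
  if (!is.na(ci)) {
    ratio[ci, ] <- pmin(pmax(
      clone_rna_ratios + rnorm(n_clones, 0, spec$coupling_noise_sd), 0), 1)
  }
  depth <- matrix(rpois(spec$n_peaks * n_clones, spec$peak_read_depth),
                  spec$n_peaks, n_clones)
  cast <- matrix(rbinom(spec$n_peaks * n_clones, depth, ratio),
                 spec$n_peaks, n_clones)
  atac_counts <- data.frame(
    peak_id = rep(peak_id, n_clones),
    clone_id = rep(clone_ids, each = spec$n_peaks),
    cast_count = as.vector(cast),
    ref_count = as.vector(depth - cast),
    stringsAsFactors = FALSE
  )
  list(
    peaks = peaks, atac_counts = atac_counts,
    truth = list(
      coupled_peak_id = if (is.na(ci)) NA_character_ else peak_id[ci],
      atac_ratio = ratio
    )
  )
}

#' Simulate an epidrug screen plate with known hits
#'
#' Generates 11 control wells per clone plus `n_compounds` compound wells
#' per clone, all on the silent-allele-fraction scale: null compounds are
#' drawn from the clone's control distribution, true hits are shifted by
#' `hit_effect` in BOTH clones. Ratios are then expressed on the Cast scale
#' according to each clone's silent allele.
#'
#' @param n_compounds Total compounds.
#' @param n_hits Number of true hits (first `n_hits` compounds).
#' @param control_mean_per_clone Named numeric vector (length 2): baseline
#'   silent-allele fraction per clone.
#' @param control_sd Well-to-well SD.
#' @param hit_effect Shift added to true hits' silent-allele fraction.
#' @param silent_allele Named character vector (`"cast"`/`"ref"`) per clone.
#' @param seed Integer seed.
#' @param n_controls Control wells per clone (default 11).
#' @return List with `plate` (data frame `compound_id`, `clone_id`, `ratio`,
#'   `is_control`, ready for [call_screen_hits()]), `silent_allele`, and
#'   `truth` (data frame `compound_id`, `is_hit`).
#' @export
simulate_screen_plate <- function(n_compounds, n_hits,
                                  control_mean_per_clone =
                                    c(clone_31 = 0.03, clone_84 = 0.03),
                                  control_sd = 0.01, hit_effect = 0.2,
                                  silent_allele =
                                    c(clone_31 = "ref", clone_84 = "cast"),
                                  seed = 1L, n_controls = 11L) {
  if (n_hits > n_compounds) stop("n_hits must be <= n_compounds")
  set.seed(as.integer(seed))
  clones <- names(control_mean_per_clone)
  compound_id <- sprintf("cmpd_%04d", seq_len(n_compounds))
  is_hit <- seq_len(n_compounds) <= n_hits
  rows <- list()
  for (cl in clones) {
    mu <- control_mean_per_clone[[cl]]
    ctrl_s <- rnorm(n_controls, mu, control_sd)
    cmpd_s <- rnorm(n_compounds, mu, control_sd) + ifelse(is_hit, hit_effect, 0)
    s <- c(ctrl_s, cmpd_s)
    s <- pmin(pmax(s, 0), 1)
    ratio <- if (silent_allele[[cl]] == "cast") s else 1 - s
    rows[[cl]] <- data.frame(
      compound_id = c(sprintf("control_%02d", seq_len(n_controls)), compound_id),
      clone_id = cl, ratio = ratio,
      is_control = c(rep(TRUE, n_controls), rep(FALSE, n_compounds)),
      stringsAsFactors = FALSE
    )
  }
  list(
    plate = do.call(rbind, rows),
    silent_allele = silent_allele,
    truth = data.frame(compound_id = compound_id, is_hit = is_hit,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate per-allele expression levels for dosage analysis
#'
#' Each allele, when active, contributes an expression level around
#' `per_allele_mean`; biallelic clones express both alleles, monoallelic
#' clones one, so monoallelic clones carry ~half the mRNA.
#'
#' @param n_mono,n_bi Clones per group.
#' @param per_allele_mean,per_allele_sd Per-allele expression contribution.
#' @param seed Integer seed.
#' @return Data frame `clone_id`, `level`, `ratio` (allelic ratio: ~0 or ~1
#'   for monoallelic clones, ~0.5 for biallelic), `true_group`.
#' @export
simulate_dosage_clones <- function(n_mono, n_bi, per_allele_mean = 1,
                                   per_allele_sd = 0.1, seed = 1L) {
  set.seed(as.integer(seed))
  allele_levels <- function(n) {
    matrix(rnorm(2 * n, per_allele_mean, per_allele_sd), n, 2)
  }
  mono_alleles <- allele_levels(n_mono)
  mono_side <- sample(c(1L, 2L), n_mono, replace = TRUE)
  mono_level <- mono_alleles[cbind(seq_len(n_mono), mono_side)]
  mono_ratio <- ifelse(mono_side == 1L, 0.98, 0.02) +
    rnorm(n_mono, 0, 0.01)
  bi <- allele_levels(n_bi)
  bi_level <- rowSums(bi)
  bi_ratio <- bi[, 1] / bi_level
  data.frame(
    clone_id = sprintf("clone_%03d", seq_len(n_mono + n_bi)),
    level = c(mono_level, bi_level),
    ratio = pmin(pmax(c(mono_ratio, bi_ratio), 0), 1),
    true_group = rep(c("monoallelic", "biallelic"), c(n_mono, n_bi)),
    stringsAsFactors = FALSE
  )
}
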