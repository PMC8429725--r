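#!/usr/bin/env Rscript
# Generate the synthetic study: allele-specific clone counts for three genes
# with different allelic modality structure, RNA-FISH cell tallies for two
# brain-region-like populations, an ATAC peak landscape with one
# expression-coupled TSS peak, an epidrug screen plate, and a dose-response
# series. Everything downstream (02-05) consumes these tables.

library(raexi)

seed <- 20260919L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Clonal allelic ratios: one gene per modality regime, 150 clones from six
## differentiation experiments, with experiment-to-experiment variability in
## the allelic-state weights.
presets <- rme_presets()
counts <- list(); truths <- list()
for (g in names(presets)) {
  spec <- presets[[g]]
  spec$experiment_weight_concentration <- 30
  sim <- simulate_gene_clones(spec, n_clones = 150, n_experiments = 6,
                              seed = seed + which(names(presets) == g),
                              gene_id = g)
  counts[[g]] <- sim$counts
  sim$truth$gene_id <- g
  truths[[g]] <- sim$truth
}
write_report_table(do.call(rbind, counts), file.path(out, "clone_counts.tsv"))
write_report_table(do.call(rbind, truths), file.path(out, "clone_truth.tsv"))

## FISH: a CA1-like region with a stable monoallelic population in three
## animals, and a CA3-like fully bursty-biallelic region.
fish <- list()
for (a in 1:3) {
  fish[[length(fish) + 1]] <- simulate_fish_population(
    fish_sim_spec(300, stable_fraction = 0.33, P_ON = 0.85, P_sense = 0.95),
    seed = seed + 10 + a, region_id = "CA1_like", animal_id = paste0("m", a)
  )$counts
  fish[[length(fish) + 1]] <- simulate_fish_population(
    fish_sim_spec(300, stable_fraction = 0, P_ON = 0.85, P_sense = 0.95),
    seed = seed + 20 + a, region_id = "CA3_like", animal_id = paste0("m", a)
  )$counts
}
write_report_table(do.call(rbind, fish), file.path(out, "fish_cells.tsv"))

## Peak landscape: 150 SNP-containing peaks in +/-3 Mb of a TSS at 5 Mb,
## the 75th coupled to expression; 13 clones spanning the ratio range.
rna <- seq(0.05, 0.95, length.out = 13)
names(rna) <- sprintf("clone_%02d", 1:13)
land <- simulate_peak_landscape(
  landscape_spec(150, tss = 5e6, coupled_peak_index = 75,
                 coupling_noise_sd = 0.05),
  rna, seed = seed + 30)
write_report_table(land$peaks, file.path(out, "peaks.tsv"))
write_report_table(land$atac_counts, file.path(out, "atac_counts.tsv"))
write_report_table(
  data.frame(clone_id = names(rna), rna_ratio = rna),
  file.path(out, "rna_ratios.tsv"))
write_report_table(
  data.frame(key = "coupled_peak_id", value = land$truth$coupled_peak_id),
  file.path(out, "landscape_truth.tsv"))

## Dosage: per-allele expression for 30 monoallelic and 30 biallelic clones.
dos <- simulate_dosage_clones(30, 30, seed = seed + 40)
write_report_table(dos, file.path(out, "dosage_clones.tsv"))

## Screen: 181 compounds, 6 true hits, two clones silencing opposite alleles.
scr <- simulate_screen_plate(181, 6, control_sd = 0.01, hit_effect = 0.12,
                             seed = seed + 50)
write_report_table(scr$plate, file.path(out, "screen_plate.tsv"))
write_report_table(scr$truth, file.path(out, "screen_truth.tsv"))

## Dose-response: 4PL with EC50 1.6 uM, triplicate wells over 7 doses.
doses <- rep(c(0, 0.1, 0.3, 1, 3, 10, 30), each = 3)
set.seed(seed + 60)
resp <- 0.02 + (0.45 - 0.02) /
  (1 + 10^(log10(1.6) - log10(pmax(doses, 1e-3)))) +
  rnorm(length(doses), 0, 0.015)
write_report_table(data.frame(dose_uM = doses, ratio = resp),
                   file.path(out, "dose_response.tsv"))

cat("synthetic study written to", out, "\n")
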