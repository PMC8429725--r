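#!/usr/bin/env Rscript
# Downstream statistics: gene-dosage comparison between monoallelic and
# biallelic clones, epidrug-screen hit calling against the mean + 3 SD rule
# in both clones, and the 4PL dose-response fit for a confirmed hit.

library(raexi)

out <- "results/downstream"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Dosage: monoallelic vs biallelic expression among the simulated clones
dos <- utils::read.delim("results/data/dosage_clones.tsv")
cats <- as.character(classify_ratio(dos$ratio))
dt <- dosage_ttest(dos$level, cats)
cat(sprintf(
  "dosage: mono/biallelic mean ratio = %.3f (t = %.2f, df = %d, p = %.3g)\n",
  dt$ratio_of_means, dt$t, dt$df, dt$p_value))
write_report_table(as.data.frame(dt), file.path(out, "dosage_ttest.tsv"))

## Screen: hits shifting the ratio toward the silent allele in both clones
plate <- utils::read.delim("results/data/screen_plate.tsv")
silent <- c(clone_31 = "ref", clone_84 = "cast")
hits <- call_screen_hits(plate, silent)
print(hits)
truth <- utils::read.delim("results/data/screen_truth.tsv")
true_hits <- truth$compound_id[truth$is_hit]
cat(sprintf("true hits recovered: %d/%d, false hits: %d\n",
            length(intersect(hits$hits, true_hits)), length(true_hits),
            length(setdiff(hits$hits, true_hits))))
write_report_table(hits$per_clone, file.path(out, "screen_effects.tsv"))
write_report_table(hits$thresholds, file.path(out, "screen_thresholds.tsv"))
write_report_table(data.frame(compound_id = hits$hits),
                   file.path(out, "screen_hits.tsv"))

## Dose-response of a hit compound
dr <- utils::read.delim("results/data/dose_response.tsv")
fit <- fit_dose_response(dr$dose_uM, dr$ratio, seed = 20260919L)
print(fit)
write_report_table(
  data.frame(bottom = fit$bottom, top = fit$top, ec50_uM = fit$ec50,
             hill = fit$hill, sse = fit$sse),
  file.path(out, "dose_response_fit.tsv"))
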