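# raexi

Analysis of **random allelic expression imbalance (RAExI)** in clonal cell
populations from an F1 hybrid cross (Mus musculus castaneus × 129/Sv).

Some autosomal genes are expressed from their two alleles in proportions
that differ between clonal cell lines but are stably inherited within each
clone — from balanced biallelic expression, through reproducible biases, to
strict random monoallelic expression (RME). `raexi` is for researchers who
have allele-resolved count tables (RNA-seq, ATAC-seq, pyrosequencing) from
such clones, RNA-FISH cell tallies from tissue, or allelic screen readouts,
and want the statistical machinery of a RAExI study:

- **Allelic ratios**: `r = Cast / (Cast + 129)` per gene × clone, with read
  filters and the five-category classification
  (monoallelic `r < 0.15` or `> 0.85`; biased `0.15–0.35` / `0.65–0.85`;
  biallelic `0.35–0.65`).
- **Modality decomposition**: each gene's clonal ratio distribution is
  fitted as a univariate Gaussian mixture
  `p(r) = Σ π_k N(r; μ_k, σ_k²)` by EM (compiled inner loop); the number of
  allelic states maximises `BIC = 2·logL − k·log n` over both equal- and
  unequal-variance families, confirmed by parametric-bootstrap likelihood
  ratio tests (K vs K+1) with bootstrap confidence intervals for all
  parameters.
- **FISH burst test**: under bursting/imperfect detection alone, detected
  alleles per cell are `Binomial(2, P_detect)` with
  `P_detect = n_tot / (2·N_cells)`; a χ² goodness-of-fit test with 1 df
  detects an excess of stably monoallelic cells.
- **Regulatory scan**: within ±3 Mb of a gene's TSS, OLS of RNA allelic
  ratio on each SNP-containing ATAC peak's allelic ratio across clones
  (`F = (n−2)R²/(1−R²)`), Bonferroni-corrected over peaks tested.
- **Downstream statistics**: KS comparisons between cell types, per-clone
  stability correlations, the mono-vs-biallelic dosage t-test, protein~mRNA
  regression, the epidrug screen hit rule (`> control mean + 3·SD` toward
  the silent allele in *both* clones), and 4PL dose–response (EC50) fits.
- **Synthetic data**: seed-deterministic generators with ground-truth labels
  for every stage (modality mixtures with per-experiment weight
  variability and binomial read sampling; stable/bursty FISH populations;
  peak landscapes with one expression-coupled peak; screen plates with
  planted hits).

## Worked example

The FISH burst test on a tally of 100 cells — 10 with no nascent signal, 30
with one, 60 with two:

```r
library(raexi)
burst_gof_test(fish_counts(10, 30, 60))
#> Burst GOF test: P_detect = 0.750, chi2 = 4.000 (df = 1), p = 0.0455
```

`P_detect = (30 + 2·60) / 200 = 0.75`; the binomial expectations are
(6.25, 37.5, 56.25) cells, giving χ² = 2.25 + 1.5 + 0.25 = 4.0 on 1 df:
the 30% single-signal cells are a borderline-significant excess over what
bursting alone would produce.

The full synthetic study is the `analysis/` workflow
(`Rscript analysis/01_simulate.R` … `05_dosage_screen.R`, writing under
`results/`). Its drivers print, for example:

```
trimodal_rme: BIC selects K = 3 (equal), sequential LRT K = 3
CA1_like pooled: 48% single-signal cells, P_detect = 0.67, chi2(1) = 7.7, p = 0.00558
best peak peak_0075; generator's coupled peak peak_0075; recovered
dosage: mono/biallelic mean ratio = 0.496 (t = -31.38, df = 58, p = 4.37e-38)
true hits recovered: 6/6, false hits: 0
4PL dose-response: EC50 = 1.34 uM, hill = 1.07, range [0.0151, 0.424], SSE = 0.00362
```

i.e. the pipeline recovers the generator's three allelic states, flags the
stable monoallelic cell population (and not the purely bursty control
region), pinpoints the one TSS peak whose allelic accessibility drives
allelic expression among 150 candidates, measures the two-fold dosage
difference of monoallelic clones, and calls exactly the planted screen hits.

See `vignettes/raexi-methods.Rmd` for the models, their assumptions, the
tunable thresholds and the known limitations.

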