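---
title: "Models and methods for random allelic expression imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for random allelic expression imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raexi)
```

## The problem

In an F1 hybrid (Mus musculus castaneus x 129/Sv), strain SNPs make the two
parental alleles of every autosomal gene distinguishable in sequencing reads.
Clonal cell lines — for example neural progenitor cell (NPC) clones, each
expanded from a single cell — then reveal *random allelic expression
imbalance* (RAExI): for some genes, different clones stably express the two
alleles in different, clonally heritable proportions, ranging from balanced
biallelic expression through reproducible biases to strict random monoallelic
expression (RME). `raexi` implements the quantitative stages of a RAExI
study: ratio computation and classification, mixture-based modality
decomposition, an in-vivo RNA-FISH test for stable monoallelism, a
chromatin-accessibility scan for the regulatory element coupled to the
allelic choice, and the downstream dosage, stability, screen and
dose-response statistics. A synthetic-data module generates
ground-truth-labelled inputs with the statistical structure each stage
assumes, so the whole pipeline is testable without any external data.

## Allelic ratios and categories

The allelic ratio of a gene in a clone is
$r = \mathrm{Cast}/(\mathrm{Cast} + 129)$, the fraction of allele-specific
signal from the Castaneus allele. Ratios are stored as fractions in $[0,1]$
and rendered as percentages only in reports. Entries with fewer than
`min_reads` informative reads are excluded rather than computed: the default
is 20 reads for RNA-seq gene ratios and 10 for ATAC peaks, both configurable.

Clones are classified into five categories: monoallelic ($r < 0.15$ or
$r > 0.85$), biased ($0.15 \le r \le 0.35$ or $0.65 \le r \le 0.85$) and
biallelic ($0.35 < r < 0.65$). The interval notation leaves the boundary
points ambiguous; we declare the biased bins closed at their printed ends and
the monoallelic/biallelic bins open, which makes the five bins a partition of
$[0,1]$. Nothing downstream is sensitive to this convention — it only decides
the bin of ratios landing exactly on a boundary.

## Mixture decomposition of clonal ratio distributions

A gene's allelic modality structure is modelled as a univariate Gaussian
mixture over clones:
$$ p(r) = \sum_{k=1}^{K} \pi_k \, \mathcal{N}(r;\, \mu_k, \sigma_k^2), $$
where each component is one allelic state. Two variance families are
searched: component-specific variances ("unequal", $3K-1$ free parameters)
and a shared variance ("equal", $2K$), since real genes show states of
visibly different spread. Plain Gaussians are fitted to the bounded data;
densities are deliberately not renormalised to $[0,1]$, matching standard
practice for these distributions.

Fitting is by EM, in a compiled inner loop with log-space responsibilities.
For $K=1$ the MLE is closed form and EM is skipped. Initialisation cuts the
sorted sample into $K$ quantile blocks; `n_restarts = 10` randomly perturbed
restarts guard against local maxima, under a fixed seed so every fit is
reproducible. Convergence is declared when the relative log-likelihood change
falls below $10^{-8}$ (at most 1000 iterations); the full log-likelihood
trace is retained and checked for monotonicity in the test suite. A variance
floor of $10^{-6}$ (ratio$^2$ units) prevents singular components when
values are exactly replicated.

The number of allelic states is selected by maximising
$\mathrm{BIC} = 2\log L - k_{\mathrm{free}}\log n$ over $K = 1..K_{\max}$
(default 5) and both families, with ties broken toward smaller $K$ and then
the equal family. Two uncertainty layers complement the BIC choice:

* a **parametric-bootstrap likelihood-ratio test** of $K$ vs $K+1$ (the LRT
  null distribution is irregular for mixtures): $B$ datasets (default 1000)
  are simulated from the fitted $K$-component model, the statistic
  $2(\log L_{K+1} - \log L_K)$ is recomputed on each, and
  $p = (1 + \#\{T_b \ge T_{\mathrm{obs}}\})/(B+1)$. Testing is sequential
  from $K=1$, stopping at the first $p > 0.05$. Bootstrap refits use 2
  restarts rather than 10 — the refit starts from a dataset drawn from the
  null fit, where the quantile initialisation is already close;
* **nonparametric-bootstrap percentile intervals** for every weight, mean and
  variance (resample clones, refit at fixed $K$, match components by sorted
  means). If component means tie in a replicate, label switching cannot be
  resolved and the affected intervals are widened to the union across
  components and flagged.

### What model selection can and cannot do here

With well-separated homoscedastic states (the three-state RME preset:
weights 0.25/0.5/0.25, means 0.05/0.5/0.95, sd 0.03, 150 clones), BIC
recovers $K=3$ in about 98% of simulations and the component means within
$\pm 0.03$. Two effects degrade this in less ideal settings, and both are
properties of BIC over this model family rather than of the implementation
(mclust reproduces them on identical data):

* **heteroscedastic truth**: an equal-variance $(K+1)$-model and an
  unequal-variance $K$-model can have the *same* number of free parameters
  (e.g. 8 for equal-$K{=}4$ vs unequal-$K{=}3$), so BIC decides on
  log-likelihood alone, and splitting one wide state in the equal family
  wins a substantial fraction of the time;
* **read-level noise**: binomial sampling at finite depth adds variance
  $r(1-r)/\mathrm{depth}$, largest at $r = 0.5$, and truncation skews
  boundary states, so the fitted Gaussian family is mildly misspecified.
  Through the full read-sampling generator the $K=3$ recovery rate drops to
  roughly 80%.

The package reports both the clean-mixture and the end-to-end recovery rates
in its acceptance outputs, and the selection table (every $K$, family, BIC)
is always attached to the winning fit so a borderline choice is visible.

## The RNA-FISH burst test

Nascent-RNA FISH counts, per cell, how many alleles show an active
transcription focus (0, 1 or 2). Single-signal cells are ambiguous: they can
reflect stable monoallelic expression, or merely transcriptional bursting
and imperfect detection. Under the bursting-only null, each of a cell's two
alleles is detected independently with probability
$P_{\mathrm{detect}} = P_{\mathrm{ON}} \times P_{\mathrm{sense}}$, so
detected-allele counts are $\mathrm{Binomial}(2, P_{\mathrm{detect}})$.
$P_{\mathrm{detect}}$ is estimated from the same tally as
$n_{\mathrm{tot}}/(2N_{\mathrm{cells}})$ (total pinpoints over total
alleles); $P_{\mathrm{ON}}$ and $P_{\mathrm{sense}}$ are not separately
identifiable and are only distinguished in the simulator. The observed
$(n_0, n_1, n_2)$ are compared to the binomial expectations by a
$\chi^2$ goodness-of-fit test with one degree of freedom (three classes,
minus one, minus one estimated parameter). A warning (not a failure) is
raised when an expected class falls below 5; no continuity correction is
applied. The test assumes the pooled cells are homogeneous — same cell
type, genetically identical alleles — so pooling across regions requires an
explicit override; the default analysis pools animals within a region and
also reports per-animal results.

**Power.** The mixture of stable-monoallelic and bursty cells re-estimates
$P_{\mathrm{detect}}$ downward, and the resulting binomial is often nearly
indistinguishable from the mixture: the only detectable signature is the
single-signal fraction exceeding the binomial ceiling of $1/2$. At
$P_{\mathrm{detect}} = 0.6$ with a 33% stable fraction and 300 cells the
noncentrality is only $\approx 0.46$ and power $\approx 0.10$; power
reaches 90% only as detection approaches completeness (the test suite
checks Monte-Carlo power against this noncentral-$\chi^2$ analysis in both
regimes). High detection efficiency — strong probes, highly expressed
genes — is therefore a prerequisite for this design, which is why the
synthetic in-vivo study uses $P_{\mathrm{ON}} = 0.85$,
$P_{\mathrm{sense}} = 0.95$.

## The regulatory-region scan

For a gene of interest, every accessible-chromatin peak containing at least
one strain-discriminating SNP and whose midpoint lies within $\pm 3$ Mb of
the TSS is tested: ordinary least squares of the gene's RNA allelic ratio on
the peak's ATAC allelic ratio across clones, with
$F = (n-2)R^2/(1-R^2)$ on $(1, n-2)$ df. Per-clone peak values with fewer
than 10 allele-specific reads are dropped; a peak is tested only if at least
4 values remain and at least 2 of those clones show an expression bias
(RNA ratio $< 1/3$ or $> 2/3$) — without biased clones there is no allelic
signal to explain. P-values are Bonferroni-adjusted over the peaks actually
tested for that gene ($p_{\mathrm{adj}} = \min(1, m\,p)$), and the best peak
is the minimal adjusted p, ties broken toward the peak nearest the TSS.
Coordinates are 0-based half-open (BED); window membership by midpoint makes
edge-straddling peaks deterministic. The regression direction (RNA on ATAC)
only affects the reported slope — $F$, $R^2$ and $p$ are symmetric.
Whether "values" are counted before or after the bias criterion is not
canonical; here the read filter runs first, then the value count, then the
bias count among the clones entering the regression, all configurable.

## Downstream statistics

* **Distribution comparisons** between cell types use the two-sample
  Kolmogorov–Smirnov test; **stability** between timepoints is the per-clone
  Pearson correlation of gene ratios passing the 20-read filter at both
  timepoints (undefined below 3 shared genes).
* **Dosage**: among high-expression clones (threshold a required analysis
  input, with an optional 2-component log-level mixture to propose one),
  monoallelic vs biallelic expression levels are compared by a two-tailed
  unpaired Student t-test with pooled variance ($df = n_1+n_2-2$), biased
  clones excluded. Under a per-allele expression model the mono/biallelic
  mean ratio estimator is consistent for 0.5. Protein-level effects use OLS
  of normalised protein on relative mRNA.
* **Screen hits**: each compound's post-treatment ratio is re-expressed as
  the fraction from the clone's *silent* allele (the two screened clones
  silence opposite alleles), and a hit must exceed the clone's own control
  mean $+ 3\times$ sample SD in *both* clones; compounds missing a
  measurement are ND, never hits. With the threshold estimated from 11
  control wells, a null compound's per-clone exceedance probability is
  $P(t_{10} > 3/\sqrt{1+1/11}) \approx 0.008$, not the $0.00135$ normal
  tail — but a *called* hit requires both clones, which keeps the null hit
  rate around $10^{-4}$.
* **Dose–response**: a four-parameter logistic on $\log_{10}$ dose,
  $y = b + (t-b)/(1+10^{h(\log_{10}\mathrm{EC50} - x)})$, fitted by
  Levenberg–Marquardt least squares from a grid of starts plus seeded
  jitter; zero doses anchor the bottom asymptote at a floor two decades
  below the smallest nonzero dose. After fitting, orientation is normalised
  so bottom $\le$ top (a falling curve keeps a negative Hill slope).

## The synthetic study

`rme_presets()` provides three modality regimes mirroring what RAExI genes
show in practice: a single narrow biallelic state; two reciprocally biased
states with no full monoallelism; and three states with monoallelic
populations in both directions. `simulate_gene_clones()` layers the
processes real count tables contain: Dirichlet-perturbed state weights per
differentiation experiment (the allelic choice outcome varies between
experiments), truncated-Gaussian true ratios, optional technical noise, and
binomial allele-specific reads at Poisson depth (default mean 1000,
a typical allele-specific coverage for a well-expressed gene). True ratios
are truncated to $[0,1]$ even though the fitter uses plain Gaussians — the
same mild misspecification real ratios impose — and recovery expectations
account for it (see above). The FISH, landscape and screen generators
implement exactly the null and alternative structures their tests assume,
and all generators are seed-deterministic (identical spec + seed gives
identical output).

What the generators do *not* emulate: mapping bias and reference bias in
allele assignment, overdispersion beyond binomial (e.g. extraction
batches), linked peaks in the landscape (uncoupled peaks are independent),
and plate-position effects in the screen. Passing tests therefore
demonstrate correctness of the statistics under their stated models, not
robustness to these artefacts.

## Problem sizes and numerical choices

The packaged analyses and tests use: 150 clones per simulated gene, 200
simulations for selection-rate and LRT-calibration studies (B = 199 within
each LRT), 100 landscapes of 150 peaks x 13 clones for the scan, 1000
populations for the FISH type-I study, and 10,000 null compounds for the
screen false-positive study — sizes at which the Monte-Carlo error of each
estimated rate is small relative to the property being checked while the
full suite stays fast. Production-scale defaults (B = 1000) remain the
function defaults. Ties in `max.col` assignment are broken toward the first
component; bootstrap p-values are never 0 by construction
($p \ge 1/(B+1)$); degenerate inputs (constant values, zero-variance
predictors, empty filters) return explicit statuses rather than errors
wherever the quantity is undefined rather than erroneous.
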