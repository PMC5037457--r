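---
title: "Joint label-free abundance and dynamic SILAC turnover analysis"
author: "dynaSILAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint label-free abundance and dynamic SILAC turnover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaSILAC)
options(dynaSILAC.quiet = TRUE)
```

## The measurement model

A forward dynamic SILAC experiment switches cultured cells to media with
heavy-isotope lysine and arginine at `t = 0`. Every tryptic peptide then
exists in a light form (synthesized before the switch) and a heavy form
(after), and a single LC-MS run yields both of the quantities this package
works with:

* **Total peptide intensity** `I_total = I_L + I_H` — a label-free abundance
  measure, summed over the channels that were actually observed. A missing
  channel is skipped; a missing value is never treated as zero, because a
  peptide that was not detected carries no evidence of absence at this
  abundance scale.
* **Relative isotope abundance** `RIA = I_H / (I_L + I_H)` — the fraction of
  the peptide pool synthesized since the switch, a turnover readout that is
  independent of total abundance. An unchanged protein with half its
  molecules replaced has `RIA = 0.5`; a protein at half abundance with
  `I_L = 0.1, I_H = 0.4` has `RIA = 0.8`.

The asymptote of RIA over time is not 1 but the **precursor-pool RIA** `r`:
the heavy fraction of the free intracellular amino-acid pool. It is estimated
from a peptide carrying two labelable lysines. Molecules synthesized after
the switch draw each lysine independently, so the doubly-heavy and mixed
forms occur as `r^2 : 2r(1-r)` and

$$\hat r = \frac{2\,I_{HH}}{2\,I_{HH} + I_{HL}},$$

independent of how much protein has turned over. With first-order turnover at
rate `k` (per hour) and an instantaneous pool switch, the expected trajectory
is

$$\mathrm{RIA}(t) = r\,(1 - e^{-kt}).$$

The package assumes a single well-mixed precursor pool with no equilibration
delay and no isotope recycling beyond the single parameter `r`. Rate
constants are fitted only as a validation aid (`fitTurnoverRate()`); the
analysis proper compares RIA distributions, which requires no kinetic
assumption beyond monotone incorporation.

## Peptide curation

Turnover statistics use only peptides that satisfy three criteria, applied
globally (a peptide is in or out for all samples — per-sample curation would
let a peptide drift in and out of the tested population and unbalance the
group comparison):

1. the heavy and the light form were each identified by MS/MS at least once
   (`not_dual_identified`);
2. light and heavy retention times agree within `rt_tolerance_min`
   (default 0.5 min) in every co-observation (`rt_mismatch`);
3. the heavy-channel noise is below 1/10 of the light peak at `t = 0`,
   implemented as light(T=0) / noise_heavy ≥ `snr_min` (default 10); a
   peptide with no `t = 0` observation cannot be evaluated and is rejected
   under the same flag (`snr_low`).

Tightening any threshold can only shrink the retained set, a property the
test suite checks directly.

## Abundance arm

Peptide totals are scaled per sample to the **robust median**: each sample is
multiplied by (reference median / sample median), with the reference taken as
the median of the per-sample medians. Median-of-medians is used because it is
insensitive to the missingness pattern and to a minority of truly changing
peptides; a second normalization pass is a no-op. Scaled totals are summed to
protein level (sum over non-missing peptides; missing when nothing was
quantified), log2-transformed, and z-scored per protein for PCA. Technical
precision is summarized per protein as the CV of the linear-scale intensity
across QC-pool injections; it is undefined (and fails the filter explicitly)
when fewer than two pools quantified the protein.

Differential expression between gravity conditions at a time point uses an
equal-variance Student's t-test on log2 values, a signed linear fold change
(ratio when up, negative reciprocal when down, so |FC| ≥ 1), and the
four-criterion filter: p < 0.05, |FC| > 1.5, ≥ 2 matched peptides, QC CV
< 20%. All four thresholds live in `pipelineConfig()`.

Temporal-trend classification runs two Bonferroni-corrected ANOVA families
per protein — time within each condition (2 tests; the shared 0 h baseline
enters both series) and condition at each time point (as many tests as time
points) — and assigns exactly one of `no_change`, `similar_change`
(time significant, conditions never differ) or `dissimilar_change` (any
per-time condition test significant). The family definitions follow the two
sentences that name them; other groupings are defensible, which is why both
supporting p-value families are returned alongside the class. The
"error-weighted" ANOVA of the original processing software is proprietary;
`weightedAnova()` therefore exposes an inverse-variance-weighted WLS F-test
with an ordinary ANOVA fallback when no variance estimates exist, and the
two are interchangeable by argument.

## Enrichment arm

Protein scores (signed log2 fold change for abundance; difference in mean
curated RIA, microgravity minus normal, for turnover) are mapped to gene
symbols through a user-supplied table, collapsing colliding accessions to the
most extreme score. `gsea()` implements the weighted running-sum enrichment
score with a **gene-label permutation** null: with 3–4 samples per group a
phenotype permutation has too few distinct relabelings to estimate tail
probabilities, so set labels are permuted instead (one shared relabeling per
permutation across all sets, so the pooled FDR reference is coherent). NES
divides ES by the mean magnitude of same-sign null ES; the FDR q is the
classic ratio-of-tails estimator on the pooled normalized null, with the
q-value running-minimum applied from the least extreme NES toward the most
extreme within each sign. Defaults: 1000 permutations, set sizes 5–500,
weight exponent 1.

## What the simulator emulates — and what it does not

`simulateExperiment()` generates the full study design: 3 baseline (0 h)
samples, two conditions × {12, 48, 120} h × 3 replicates, 4 QC-pool
injections (per-peptide mean of all biological samples plus ~5% technical
noise), and one doubly-lysine reporter peptide per sample whose isotopologues
are multinomial draws at the configured pool RIA (default 0.95 — labeling
deliberately incomplete). Protein half-lives are log-normal (median 60 h,
log-SD 0.75, spanning roughly a day to a couple of weeks — a realistic
spread for cultured cardiomyocytes); under microgravity every rate is
multiplied by `rateMultiplier` (default 0.4, a marked slowing). Abundance
trends default to the 44/25/31% no-change / similar / dissimilar split with
2-fold shared and 3-fold condition-specific changes, log-linear in time.
Channel intensities carry independent mean-1 log-normal noise (CV 20%);
missingness and MS/MS identification are logistic in log-intensity so
low-abundance peptides drop out first; retention times jitter with SD
0.05 min, with 3% of peptides deliberately misaligned by 0.6–3 min and a
log-normal S/N distribution (median 50) so that every curation criterion has
real victims.

The simulator does **not** model chromatographic peak shapes, isotopologue
envelopes, shared (razor) peptides, pool-equilibration delays, or
non-first-order turnover. Passing tests therefore demonstrate that the
pipeline recovers truth under its own noise model at realistic magnitudes —
not that real LC-MS data satisfy that model.

## Calibration choices

Null calibration of the peptide-level RIA t-test is run under a
homogeneous-turnover configuration (`halfLifeLogSD = 0`). The reason is
structural, not cosmetic: peptide RIA observations cluster by protein through
the shared rate constant, and in a balanced design those protein effects
cancel from the group-mean difference while still inflating the pooled
variance estimate, making the test conservative. Calibration under the
test's own independence assumptions answers "is the statistic implemented
correctly"; the conservatism under realistic rate heterogeneity is a known
property of pooling clustered observations and is documented here as a
limitation of the peptide-level test (a protein-level rollup, available in
`fitTurnoverRates()` aggregation, sidesteps it at the cost of power).

Other numeric choices: turnover fits run `nls` (port algorithm, k bounded in
[1e-8, 10] per hour) with a log-grid + golden-section fallback, flagging
fits at the bound; PCA uses complete-case proteins only (no imputation
anywhere in the package); confidence ellipses use the chi-square(2) quantile
at 99.999% to mirror the original QC display; GSEA ties are broken by gene
name so results are reproducible across platforms.

Problem sizes in the test suite (300 proteins for trend recovery over 10
seeds, 200 seeds for t-test calibration, 500 random sets at 200 permutations
for FDR calibration, ~200 curated peptides for effect detection over 20
seeds) were chosen as the smallest designs at which the binomial/KS
tolerances of the respective checks are meaningful.

## A worked run

```{r example, eval = FALSE}
sim <- simulateExperiment(simulationConfig(nProteins = 100), seed = 1)
quant <- quantifyAbundance(sim$peptides, sim$design)
cur <- curatePeptides(sim$peptides, sim$design)
ria <- riaTable(sim$peptides, cur$audit)
estimatePoolRIA(sim$peptides, sim$design)
compareRIAGroups(ria, sim$design)$tests
classifyTrends(quant$proteinMatrix)$fractions
```

The same chain, with enrichment and TSV/JSON outputs, is available as
`runAll(outDir, seed)` and through the `inst/scripts/silac-pipeline.R`
command-line wrapper (`simulate`, `quantify`, `turnover`, `differential`,
`enrich`, `run-all`). Identical seeds give byte-identical output trees.

## Known limitations

* Statistics at peptide level treat observations as independent; see the
  calibration note above.
* The pool-RIA t-test compares per-sample ratio estimates whose variance
  depends on incorporation (slower turnover means fewer post-switch
  molecules); with 3 replicates per cell the equal-variance test is only
  approximately calibrated, though empirically within Monte-Carlo tolerance.
* Razor-peptide assignment is delegated to the upstream producer: each input
  row must carry exactly one accession.
* No imputation and no moderated-variance (empirical Bayes) testing are
  provided; proteins with insufficient replication are flagged, not rescued.
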