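# dynaSILAC

Joint label-free abundance and protein-turnover analysis for forward
dynamic SILAC proteomics experiments.

## The problem

In a forward dynamic SILAC design, cultured cells are switched at `t = 0` to
media containing heavy-isotope lysine and arginine. From then on every
tryptic peptide exists as a light form (protein made before the switch) and a
heavy form (made after), separable by mass in the same LC-MS runs. A single
experiment therefore reports two orthogonal things about every protein:

* **abundance** — the total peptide intensity,
  `I_total = I_L + I_H`, treated as an ordinary label-free quantification
  signal (robust-median scaling, peptide→protein summation, log2);
* **turnover** — the relative isotope abundance,
  `RIA = I_H / (I_L + I_H)`, which climbs from 0 toward the precursor-pool
  limit `r` as protein is replaced. Under one-pool first-order kinetics,
  `RIA(t) = r (1 − e^{−kt})`.

The pool limit `r` itself is estimated from a doubly lysine-labeled peptide:
post-switch molecules carry heavy/heavy vs heavy/light lysines in ratio
`r² : 2r(1−r)`, so `r̂ = 2 I_HH / (2 I_HH + I_HL)` independent of turnover.

The package is aimed at time-course designs comparing two conditions (here
labeled `normal_g` and `micro_g`, after the rotating-wall-vessel simulated
microgravity experiments that motivate it) with QC-pool injections, and
covers the full downstream path: peptide curation for turnover analysis
(dual MS/MS identification, retention-time agreement ≤ 0.5 min, heavy-noise
S/N ≥ 10 at `t = 0`), per-time Student's t-tests on RIA, error/inverse-
variance-weighted ANOVA, Bonferroni and Benjamini–Hochberg correction, a
four-criterion differential-expression filter (p < 0.05, |FC| > 1.5,
≥ 2 peptides, QC CV < 20%), three-way temporal-trend classification, PCA QC
with confidence ellipses, and permutation gene-set enrichment (GSEA with
gene-label permutation and ratio-of-tails FDR) on both the abundance and the
turnover rankings.

Because raw data of this kind are rarely redistributable, the package ships
a first-class simulator (`simulateExperiment()`) that generates the whole
design — baseline, two conditions × {12, 48, 120} h × 3 replicates, QC
pools, a double-lysine pool reporter — with known ground truth (rates, fold
changes, trend classes, pool RIA), so every stage is testable end to end.

## Worked example

```r
library(dynaSILAC)
sim   <- simulateExperiment(simulationConfig(nProteins = 100), seed = 1)
quant <- quantifyAbundance(sim$peptides, sim$design)
cur   <- curatePeptides(sim$peptides, sim$design)
ria   <- riaTable(sim$peptides, cur$audit)

estimatePoolRIA(sim$peptides, sim$design)
#> Precursor-pool RIA: r_hat = 0.9486 (n = 12 samples)
#>   micro_g   0.9496
#>   normal_g  0.9476
#>   between-condition t-test p = 0.139

compareRIAGroups(ria, sim$design)$tests
#>   time_h n_normal_g n_micro_g       p_value
#> 1     12       1473      1467  7.825293e-32
#> 2     48       1476      1475  4.111909e-99
#> 3    120       1467      1477 2.088772e-123

classifyTrends(quant$proteinMatrix)$fractions
#>         no_change    similar_change dissimilar_change
#>             0.446             0.238             0.317
```

Reading the output: the pool reporter recovers the simulated precursor RIA
(true value 0.95) with **no** condition difference — the label supply is the
same in both arms — while the peptide-level RIA tests show massively slowed
turnover under `micro_g` (the simulation multiplies every rate constant by
0.4). Abundance trends classify close to the generating 44/25/31%
no-change/similar/dissimilar split. The curation step retained 497 of 559
peptides (the rest fail the MS/MS, retention-time or S/N criteria by
construction), and the 120 h differential filter called 27 of 101 proteins
(15 up, 12 down).

The same chain with all TSV outputs and a JSON run manifest:

```r
runAll("out/", seed = 1)
```

or from a shell via the thin wrapper
`inst/scripts/silac-pipeline.R` (`simulate`, `quantify`, `turnover`,
`differential`, `enrich`, `run-all`). Fixed seeds give byte-identical
output trees.

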