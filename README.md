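# ncvbench

Benchmarking framework for noncoding-variant pathogenicity scores.

Computational impact scores for noncoding SNVs (ncSNVs) are routinely
validated as classifiers of disease-associated variants (DAVs) versus
common population polymorphisms (CPPs) on balanced test sets, where they
report excellent AUROC. That setting hides the three properties that
matter when the scores are actually used: whether a score can tell *which
allele* at a position is harmful, whether it can separate a causal variant
from its physical/LD *neighbours*, and whether it survives the heavy
*class imbalance* of real candidate lists. `ncvbench` builds one test set
per question and the statistics to grade any per-(chrom, pos, alt) score
table on them, plus the evolutionary machinery the tasks rest on — all
runnable on synthetic data with no external download.

## What it computes

* **Task 1 — allelic contrast.** Position-matched pairs of a common
  (non-pathogenic) allele and an *evolutionarily forbidden* allele — a
  base never observed at that position across a deep species panel
  (~2.9 × 10⁹ years of summed branch length), hence under persistent
  purifying selection. Metrics: matched-pair success rate with tie credit
  ½, Mann–Whitney AUROC, DeLong variance/z-test, exact Wilcoxon
  signed-rank.
* **Task 2 — fine mapping.** Evidence-filtered DAVs paired with every
  nearby CPP (MAF > 5%, within 1 kb, or sharing an LD block). Metrics:
  success rates stratified by conservation class (ultra/well/least:
  per-site Fitch-parsimony rate = 0, < 2, ≥ 2 substitutions/site/Gy),
  genomic context and distance bin; paired one-sided t; score-correlation
  decay with distance.
* **Task 3 — prioritisation under imbalance.** Mixtures of CPP : DAV at
  ratios 1:1 … 100:1 with > 1 kb pairwise separation. Metrics:
  top-10-percentile precision, average-precision AUPRC per ratio, and the
  maximum ratio at which AUPRC stays above 0.8.
* **Neutral conservation calibration.** An HKY85 simulator with exact
  closed-form transition matrices P(t) on a dated Yule phylogeny shows
  how rarely complete cross-species conservation arises neutrally
  (≈ 0.2% of sites under the default 58-taxon / 2.9 Gy / 2.2 × 10⁻⁹
  subs·base⁻¹·yr⁻¹ / κ = 3.6 conditions — at most 0.6%).
* **Synthetic score model.** Scores decompose as
  `s = δ·truth + A_allele + P_position + R_region + ε` with
  `R` an exponential-kernel Gaussian process over genomic coordinate
  (correlation `exp(-d/L)`), reproducing the distance-decaying inter-site
  correlation of published predictors and making the three tasks
  dissociate by construction.

## Worked example

Four simulated tools of designed strengths, run through all three tasks:

```r
library(ncvbench)
run_benchmark_demo(seed = 3)
#>            tool task1_success task1_auroc task2_success task3_max_ratio
#> 1 allele_strong      0.921875   0.9181059          1.00        13.93493
#> 2   allele_weak      0.640625   0.6365613          0.48         0.00000
#> 3 position_only      0.500000   0.5000000          0.84         1.16869
#> 4   region_only      0.500000   0.5000000          0.52         0.00000
```

Reading the table: the strong allele-specific tool (pathogenicity shift
δ = 2 against allelic noise σ = 1) discriminates alleles at the same
position — its success rate 0.922 matches the closed form Φ(δ/(σ√2)) =
0.921 — and tolerates ~14:1 imbalance before AUPRC drops below 0.8. The
position-level tool scores *exactly* 0.5 on task 1 (it gives all
alternates one score; ties earn half credit) yet clearly beats chance on
the region-matched task (0.84). The region-level tool, whose scores are
only a smooth function of genomic position, is near chance everywhere.
This is the dissociation the benchmark is designed to expose: good
regional discrimination says nothing about allelic or positional
resolution.

The neutral-conservation calibration:

```r
cfg <- sim_config(n_taxa = 58, total_length_years = 2.9e9, rate = 2.2e-9,
                  kappa = 3.6, gc = 0.5, n_sites = 100000, seed = 1)
neutral_conserved_fraction(cfg)$fraction
#> [1] 0.00216
```

i.e. only ~0.2% of neutrally evolving sites *look* completely conserved
across the 58-leaf panel, so complete conservation is a strong
non-neutrality signal.

## Package layout

* `R/io.R` — VCF/TSV variant catalogs, score tables with a coordinate
  pragma, Newick/FASTA, metadata-headed TSVs.
* `R/synthetic.R` — Yule trees, HKY alignment simulation, variant-catalog
  and score-table generators.
* `R/conservation.R` — Fitch parsimony, absolute rates and classes,
  neutral conserved-fraction experiments.
* `R/testsets.R` — the three test-set builders and their filters.
* `R/evalstats.R` — AUROC/DeLong, AUPRC, success rates, correlation-
  by-distance, balanced-accuracy cutoffs, exact tests.
* `R/pipeline.R` — seeded simulate → build → evaluate orchestration and
  the demo benchmark.

See `vignettes/benchmarking-noncoding-scores.Rmd` for the models,
parameter choices and limitations.
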