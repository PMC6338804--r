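---
title: "Benchmarking noncoding variant pathogenicity scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking noncoding variant pathogenicity scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncvbench)
```

## The problem

Impact scores for noncoding single-nucleotide variants (ncSNVs) are usually
validated as binary classifiers on balanced sets of disease-associated
variants (DAVs) against common population polymorphisms (CPPs). High AUROC
in that setting does not imply the scores answer the questions they are
used for in practice:

1. **Allelic resolution.** At a segregating position, which of the three
   alternates is the harmful one? A tool that emits one score per position
   cannot answer this at all.
2. **Positional resolution.** Within a fine-mapping credible interval, can
   the causal variant be separated from its physical or LD neighbours?
   Scores that are smooth along the genome cannot.
3. **Imbalance robustness.** In a realistic candidate list, non-pathogenic
   variants outnumber pathogenic ones many-fold, and AUROC is blind to
   that prevalence.

`ncvbench` builds one test set per question and the statistics to grade an
arbitrary score table on each, with every input replaceable by a synthetic
counterpart so the whole pipeline runs with no external download.

## Evolutionary machinery

### Per-site rates by parsimony

`fitch_min_substitutions()` computes, for one alignment column on a binary
rooted tree, the minimum number of substitutions consistent with the leaf
bases (Fitch's dynamic program, leaves encoded as state bitmasks). Gaps and
ambiguous bases carry the full state set `{A,C,G,T}`: they are missing
data, not a fifth state, because a fifth state would count indels as
substitutions. The count divided by the total tree length in billions of
years is an absolute rate in substitutions/site/Gy
(`evolutionary_rate()`), classed as *ultra* (rate 0), *well* (0 < rate <
2) or *least* conserved (rate >= 2, boundary closed on the right). The
denominator is the full tree length, including branches leading to gap
leaves — there is no per-column renormalisation; pass `total_length_years`
explicitly to use a reduced species panel's length instead.

### Neutral sequence evolution

`simulate_alignment()` evolves i.i.d. sites under HKY85 down a dated tree.
The stationary distribution is parameterised by G+C content,
`pi = ((1-gc)/2, gc/2, gc/2, (1-gc)/2)` on (A, C, G, T), with
transition/transversion *instantaneous-rate* ratio `kappa`; whether a
quoted ts/tv of 3.6 means the rate ratio or the realised count ratio is a
genuine ambiguity, and we adopt the rate-ratio reading because that is the
conventional meaning of the HKY kappa parameter in simulation software; it
is exposed as a parameter either way. The rate matrix is normalised so
that the expected substitution rate at stationarity equals `rate`
(substitutions per base per year), which is what makes a statement like
"2.2e-9 per base per year" well defined. Branch transition matrices are
computed in closed form from the spectral decomposition of the
pi-symmetrised rate matrix (exact for any reversible chain), not by
discretised simulation; the test suite cross-checks them against an
independent series matrix exponential and an exact uniformisation
(jump-chain) simulator.

`gen_tree()` draws a pure-birth (Yule) topology and rescales all branches
by one factor so the total branch length is hit exactly (default 2.9
billion years over 58 taxa). Only the total evolutionary time materially
drives the neutral conservation result, which is why the topology is left
random while the time budget is pinned.

`neutral_conserved_fraction()` ties these together: under the default
mammalian-like conditions (58 taxa, 2.9 Gy, rate 2.2e-9/base/year, kappa
3.6, GC 0.5, 100,000 sites) the fraction of columns with an identical base
across all leaves is a fraction of a percent — the quantitative licence
for treating completely conserved positions as non-neutral, and the
quantity `scripts/acceptance.R` recomputes.

## The synthetic data model

### Variant catalogs

`simulate_catalog()` emulates the *shape* of curated variant collections:
DAVs cluster in the 1 kb region upstream of gene TSSs with configurable
per-gene counts (real collections have genes carrying more than 40 DAVs in
that window), while CPPs fall as a homogeneous Poisson process along the
chromosome. CPP minor-allele frequencies default to Uniform(0.05, 0.5) —
common by construction, matching the MAF > 5% definition of a CPP — and
DAV frequencies to Beta(1, 200) (rare, mean 0.5%). Evidence flags
(`dm_certain`, `functional_evidence`, `in_regulatory_element`) are
independent Bernoulli draws with defaults 0.8/0.7/0.8, chosen so that
roughly half of raw DAVs survive the three evidence filters, similar to
the attrition seen when clinical-guideline-style filters are applied to
curated databases. Context labels follow position relative to the nearest
gene; LD blocks are a fixed 20 kb tiling — labels are *assigned*, not
emerged from a coalescent, so LD-matched analyses exercise bookkeeping,
not population genetics.

### Tool scores

`simulate_scores()` writes the score of alternate `a` at position `p` as

    s(p, a) = delta * truth(p, a) + A(p, a) + P(p) + R(x_p) + eps

with `A ~ N(0, sigma_allelic^2)` per allele, `P ~ N(0,
sigma_positional^2)` per position, `R` a zero-mean Gaussian process over
genomic coordinate with covariance `sigma_regional^2 * exp(-d /
corr_length_bp)`, and white noise `eps`. The exponential kernel is Markov,
so the process is drawn exactly in O(n) by sequential nearest-neighbour
conditioning (an AR(1) on irregularly spaced points) — no covariance
matrix is ever formed. When `allele_specific = FALSE` the allelic term is
dropped and all alternates at a position share one score; the
pathogenicity shift then applies at position level (a position counts as
pathogenic when any of its alternates is), since a position-level tool
cannot express within-position contrasts.

This decomposition is what makes the three tasks dissociate *by
construction*: a tool with only positional/regional variance is exactly at
chance (50%, given half-credit ties) on the allelic task however large its
variance components; regional correlation with e-folding length
`corr_length_bp` reproduces the distance-decaying inter-site score
correlation of published predictors and is what degrades matched-pair
separation at short range.

What the generator does **not** emulate: real LD structure, selection,
rate heterogeneity, indels, non-stationary base composition, ascertainment
bias in variant databases, or the feature sets of real tools. Green tests
therefore demonstrate the pipeline's statistical machinery is correct and
well calibrated on data with the assumed variance structure — not that any
real predictor behaves this way.

## Test-set construction

* **Task 1** (`build_position_matched()`): candidate CPP positions are
  filtered to the 5–15% frequency window (applied to the derived-allele
  frequency when known, else MAF — the two readings coexist in practice,
  and `freq_mode` switches them), dropped if blacklisted for known
  associations, the highest-MAF alternate designated non-pathogenic,
  positions dropped when a remaining allele segregates in great apes, and
  a forbidden allele (never observed across the species panel) chosen
  uniformly at random when several qualify. Every random choice is driven
  by the builder seed.
* **Task 2** (`filter_davs()` + `build_region_matched()` /
  `build_ld_matched()`): three evidence filters, then pairing of each
  anchor DAV with every qualifying CPP (MAF > 5%, no known association)
  within 1 kb inclusive — "within" is read inclusively throughout — or
  sharing its LD-block label. Distance bins default to upper edges 10, 50,
  100, 200, 500, 1000 bp; bins are disjoint intervals by default with a
  cumulative (nested-threshold) option, since figure-style captions of the
  form "distance < 10 bp" admit both readings.
  `gene_balanced_subsample()` keeps one random DAV per gene within 10 kb
  to counteract per-gene clustering.
* **Task 3** (`build_mixtures()`): members pairwise separated by more than
  1 kb (greedy in position order for DAVs; CPP candidates greedily
  accepted in seeded random order), then per ratio rho all eligible DAVs
  plus `round(rho * n_dav)` sampled CPPs. Unsatisfiable ratios are skipped
  with a warning rather than silently shrunk.

## Evaluation statistics

* `auroc()` is the Mann–Whitney estimator with midrank ties;
  `delong_auc_test()` estimates its variance from the structural
  components (fast midrank formulation) and tests against 0.5 by default —
  the one-sample form, because per-tool significance against chance is the
  primary use; a paired two-tool mode (component covariances) is provided
  for head-to-head comparisons.
* `success_rate()` half-credits ties. This is load-bearing: it makes the
  random expectation exactly 50% and gives allele-invariant tools exactly
  0.5 on task 1 rather than an artefactual 0 or 1.
* `auprc()` uses the average-precision step convention, never trapezoidal
  interpolation (which overstates PR area); ties are processed as blocks.
  `top_percentile_precision()` cuts at the (100-p)th percentile of the
  mixed score distribution, includes boundary ties, and divides by the
  realised list size.
* `max_ratio_at_target()` interpolates linearly between the last tested
  ratio above the AUPRC target and the first below; a tool below target
  already at the smallest tested ratio reports 0, i.e. "unusable at any
  tested imbalance".
* `balanced_accuracy_cutoff()` maximises TPR + TNR (equivalently
  Youden-optimal; the maximiser is the same whether the sum or the mean is
  used) over observed-score thresholds under the rule "score >= cutoff is
  positive", returning the midpoint of the optimal threshold interval.
* `wilcoxon_signed_rank()` is exact for n <= 25 including under ties
  (dynamic programming over doubled midranks); `paired_t_one_sided()`,
  `fisher_exact_or()` (sample odds ratio ad/bc with the exact p) and
  `one_way_anova()` wrap the standard tests.
* `predictor_distance_correlation()` pools (anchor, neighbour) value pairs
  over all anchors within each nested distance class and reports one
  Pearson r per predictor per class. A per-anchor correlation against a
  scalar anchor value would be undefined, so pooling is the coherent
  reading of "average correlation within a flanking distance".

## Numerical and degenerate-input choices

* Transition matrices are clamped at zero and row-renormalised after the
  spectral reconstruction to absorb round-off.
* DeLong with zero variance (perfect separation) warns and reports p = 0;
  a zero-variance *difference* of identical score sets reports p = 1.
* Wilcoxon with all-zero differences, AUROC/AUPRC with an empty class,
  ANOVA with one group, and rate computation on a zero-length tree are
  errors, not silent NAs.
* Correlation bins with fewer than 3 pairs, or with constant scores,
  report NA; empty success-rate strata are omitted with a warning.
* Builders are deterministic under their seed and invariant to input row
  order (inputs are canonically sorted before any seeded draw).
* All positions are 1-based inclusive internally; 0-based score files are
  declared by a `#coords=0` pragma and shifted on read. All alleles are on
  the + strand; no strand flipping is attempted.

## Problem sizes

The package's own checks run at deliberate desk scale: 100,000 sites for
the 58-taxon neutral conservation experiment (Monte-Carlo SE about
0.015% at the observed fraction), 100,000 sites per parameter set for the
simulator cross-validation, 10,000 pairs for the closed-form success-rate
recovery (3 binomial SEs ~ 1.3%), 10,000 replicate pairs for the
Gaussian-process correlation recovery, 200 random instances per exhaustive
oracle comparison, and a 10,000-replicate bootstrap for the DeLong
variance. These sizes put the Monte-Carlo error well inside every
tolerance asserted.

## Limitations

The LD machinery labels blocks rather than modelling linkage; the context
assignment is a caricature of genome annotation; simulated scores are
Gaussian, while real tools are bounded and often heavily tied; and no
multiple-testing correction is applied across tools or strata — raw
p-values are reported by design. The benchmark measures whether a score
*table* supports the three inferences; it neither reimplements nor
audits any published predictor.
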