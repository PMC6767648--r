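---
title: "Gene functional-deficit scoring and exome-based disease prediction with avadx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene functional-deficit scoring and exome-based disease prediction with avadx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avadx)
```

## The problem and the model

Genome-wide association studies find common disease-associated loci, but for
complex diseases like Crohn's disease (CD) the individual loci carry small
odds ratios and are diagnostically weak. avadx takes the complementary,
function-first view: disease-causing variation should be *functionally
detrimental* to the genes it hits, and an individual's disease risk should be
readable from how functionally damaged their genes are — including damage
from rare or private variants that association studies cannot see.

The pipeline turns a multi-sample exome VCF into a per-individual,
per-gene **functional-deficit score** and learns a case/control decision
boundary over those scores:

1. **Variant scoring.** Each exonic variant gets a `v_score` in [0, 1] from
   its consequence class and, for nonsynonymous variants, an external
   functional-effect prediction `s` in [-100, 100]:
   - nonsynonymous, `s >= 0` (effect): `v = 0.06 + 0.94 * s / 100`
   - nonsynonymous, `s < 0` (neutral): `v = 0.055`
   - synonymous: `v = 0.05`; unscorable: `v = 0.055`
   - indel: `v = 1` (a heuristic proxy for loss of function)
2. **Gene scoring.** For gene *g* in one individual,
   `gene_score(g) = sum_i het_i * v_i` over the variants the individual
   carries in *g*, with `het = 0.25` for heterozygous and `het = 1` for
   homozygous-alternate calls. A gene untouched by variants scores 0.
3. **Feature selection, inside every cross-validation fold**: case-exclusive
   patterns (`select_dis`), exact Kolmogorov-Smirnov and Welch t-test screens
   at p < 0.05 without multiplicity correction (`screen_by_test`), and a
   cost-sensitive DKM merit ranking (`dkm_rank`).
4. **Learning.** A support vector machine (e1071) on numeric targets +100
   (CD) / -100 (HC), trained on bootstrap-balanced classes, evaluated by
   family-aware leave-one-out cross-validation and permutation nulls.
5. **Prediction of one new exome**: restrict to training loci, score genes,
   remove the batch effect between the training panel and this single
   individual (mean-only ComBat), resample the training panel to 500 per
   class, train a fresh model, score the individual, and call CD at the
   loose/default/strict cutoffs (0 / 14.3 / 45 on the reference panels).

## Filtering assumptions

Training panels keep only autosomal `FILTER == PASS` variants with a
confident genotype in *every* panel individual; a single missing call
removes the locus. This makes gene-score zeros interpretable ("no scored
variant here") rather than ambiguous ("possibly uncalled"). Test exomes are
reduced to exactly the training loci, matched as exact
`(chrom, pos, ref, alt)` tuples — no left-normalization is attempted, since
matching is only ever done between identically processed panels; indel
representation differences across callers are therefore out of scope.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `het_weight` | 0.25 | heterozygous contribution relative to homozygous |
| `alpha` | 0.05 | per-gene screen threshold (uncorrected, by design) |
| `top_k` | 125 | DKM-ranked genes per model |
| `balance` | match-major | minor-class bootstrap in CV folds |
| `resample_target` | 500 | per-class bootstrap for prediction models |
| `cutoffs` | 0 / 14.3 / 45 | loose / default / strict CD call thresholds |
| `n_perm` | 1000 | label permutations for the AUC null |
| `cutoff_rounds` | 1000 | calibration rounds for the default cutoff |

The screens are deliberately uncorrected: they are feature *selection*, not
inference, and the in-fold discipline (selection never sees the held-out
individuals) is what protects against overfitting. The `DISO` overfit
check — case-exclusive selection on the *full* panel — is available only
behind an explicit `overfit_check` flag precisely because it demonstrates
what leakage does (it reaches perfect cross-validated AUC trivially).

## The DKM criterion

The cited cost-sensitive feature-selection implementation is not
re-used here; the criterion is authored from its definition. For a gene
with scores `x` and a candidate threshold `t`, with impurity
`f(p) = 2 * sqrt(p (1 - p))` on the cost-weighted case probability `p`,
the merit is the largest `f(p_root) - sum_parts (n_part/n) f(p_part)` over
all thresholds midway between consecutive distinct values of `x`. Uniform
costs (the default) reduce it to the plain DKM criterion. Ties in merit
break lexicographically by gene ID so rankings are reproducible. Exact
parity with the external implementation is not claimed; the package's
tests instead verify the criterion against an independent brute-force
split enumeration.

## Batch adjustment

Gene-score profiles of separately sequenced panels separate by batch before
they separate by phenotype (visible as the first principal component).
Adjustment uses the parametric empirical-Bayes (ComBat) machinery from
\pkg{sva}, the standard implementation of this method. Two modes matter:

- **Per test individual (the prediction path):** the unknown batch contains
  one exome, so only means can be adjusted (`mean_only`), class labels are
  never consulted, and the EB posterior — which in this implementation
  deliberately ignores batch sizes — shrinks the singleton's per-gene
  deviations toward the training panel by a factor `t2 / (t2 + 1)`, where
  `t2` is the across-gene moment estimate of the location-prior variance.
  In simulation this moves a training-distributed test vector by a bounded,
  proportional amount (about 60% of its deviation from the training mean).
- **Two large batches:** the full location+scale adjustment applies; the
  mean-only mode is *not* recommended there, because its singleton-calibrated
  shrinkage removes only part of a strong location shift.

One honest limitation, inherited from the EB machinery and from sparse
burden scores: a gene whose scores are uniform inside a multi-sample batch
(typically all zero) is passed through unadjusted, and mean adjustment
cannot reconcile distribution *shapes* (zero-inflation differs between a
batch with and without calls at a locus). Adjusted scores may be negative;
they are deliberately not clamped, since clamping would reintroduce
batch-correlated distortion into the features.

## The synthetic cohort generator

Restricted-access cohorts cannot ship with a package, so every pipeline
stage is exercised on synthetic data (`generate_cohort`). The generator
emulates the statistical structure the method assumes, at desk scale:

- diploid genotypes in Hardy-Weinberg equilibrium at per-variant allele
  frequencies drawn from 0.005–0.15 — a rare-variant-dominated spectrum,
  because the method's premise is that rare and private functional variants
  carry the signal; a common-variant-heavy spectrum would let high-`v_score`
  homozygotes dominate gene scores with noise no real exome panel shows;
- 60 cases / 60 controls and 2000 genes by default, 10 of them causal: each
  causal gene carries one high-effect variant (effect score 40–100) whose
  carrier probability is raised by `case_enrichment` (default 0.5) in cases;
- background nonsynonymous effect scores from a normal centred at -20
  (sd 30, clamped) — mostly neutral, occasionally damaging; 30% synonymous
  and 3% indels;
- two related same-status pairs sharing half their genotypes, exercising the
  family-aware fold plan;
- optional planted batch shifts (`plant_batch_shift`) implemented as extra
  alternate alleles at *existing* loci (probability 0.8 per shifted
  individual per touched variant), so the artifact survives restriction to
  training loci exactly as a real calling-pipeline difference would. A
  gene's displacement is capped by its own variant content.

The generator does **not** model linkage disequilibrium, population
structure, or sequencing error, and its per-gene signal is cleaner than
real CD genetics (one planted variant per causal gene, no locus
heterogeneity). Passing tests therefore demonstrate that the machinery
recovers the structure it assumes — not that real cohorts carry that
structure.

## Numerical and design choices

- **Learner.** Epsilon support-vector regression (RBF kernel,
  library-default hyperparameters) on targets +/-100: continuous cutoffs at
  0/14.3/45 imply regression-style scores, and no hyperparameter tuning is
  performed on principle. A C-classification mode (decision values scaled
  to the same +/-100 convention) is available behind `model_config(mode=)`.
- **Effect score 0** counts as an effect (`v = 0.06`): the operational
  scoring table governs over the narrative neutral/effect split.
- **Ties at a cutoff** are called CD (`score >= cutoff`).
- **ROC/PR AUC** are trapezoidal over achieved threshold points; ROC AUC
  then equals the tie-aware normalized Mann-Whitney statistic (verified
  against that oracle), and the PR curve is anchored at recall 0 with the
  first achieved precision. Nonlinear PR interpolation would differ by a
  small amount on short score vectors.
- **MCC** is 0 whenever a denominator factor is 0; other 0/0 metrics are
  reported as `NA`, never silently as 0. Balanced precision is
  `TPR / (TPR + FPR)`, i.e., precision standardized to equal class sizes.
- **Default cutoff** is the mode (over calibration rounds, rounded to one
  decimal, ties toward the smaller value) of the midpoint between the mean
  held-out CD score and the mean held-out HC score.
- **Determinism.** Every stochastic stage fans a master seed out into
  per-fold / per-repeat / per-permutation streams; the full pipeline is
  bit-reproducible under a fixed seed.
- **Problem sizes in the shipped checks.** The package's statistical checks
  run at deliberately reduced scale, chosen as the smallest sizes at which
  the properties are stable: calibration uses 100-replicate screens at 30
  individuals per class (the exact KS null is markedly conservative at very
  small n), 15-20 observed permutation replicates with 20-permutation
  nulls, and 20 null cohorts of 30/30 individuals x 300 genes; recovery
  checks use the full 60/60 x 2000-gene generator defaults; batch-robust
  prediction checks average the signed AUC difference over two cohorts of
  50 held-out exomes each, with per-class resampling scaled to 300; cutoff
  calibration and its narrative metrics run at 100 per class on the same
  fixed-gene protocol, so cutoff and scores share one scale.
  Reference-protocol sizes (100 repeats, 1000 permutations, 1000
  calibration rounds, 500/500 resampling) remain the package defaults for
  real analyses.

## Known limitations

- In-fold feature selection dilutes cross-validated performance: with 125
  features of which ~10 are truly informative, the default-hyperparameter
  SVM pays a measurable AUC cost for the noise features, and features
  selected *because* they looked informative in-fold cost more than random
  ones. Under the generator's default strong-signal conditions the in-fold
  DKM-125 CV ROC AUC averages ~0.85 (seed-to-seed 0.76–0.93) against a
  causal-burden ceiling of ~0.95; smaller gene counts score higher here,
  but 125 is kept as the default configuration rather than tuned per
  cohort.
- Scores order individuals by CD-likeness but are not calibrated disease
  probabilities, and must not be read as disease severity.
- Recognizing healthy individuals is intrinsically weaker than recognizing
  cases: the model learns patterns common to cases, not the unbounded
  variety of health.
- The mean-only per-individual adjustment does not guarantee that several
  *test* panels become mutually indistinguishable; it only aligns each test
  exome with the training panel.
- The singleton-batch EB shrinkage compresses an adjusted test exome's
  per-gene deviations toward the training mean, so per-individual
  prediction scores sit closer to zero than cross-validation scores do.
  Rankings (AUCs) are unaffected, but a cutoff calibrated on
  cross-validation scores does not transfer reliably to adjusted
  per-individual scores on small synthetic panels; the shipped
  reproduction script therefore reports cutoff-narrative metrics on the
  score population the cutoff was calibrated for.
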