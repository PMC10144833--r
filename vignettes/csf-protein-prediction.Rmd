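---
title: "Positive-unlabeled prediction of CSF proteins: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive-unlabeled prediction of CSF proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter and their
defaults, what the synthetic generators do and do not emulate, the
numerical choices, and the places where the design was genuinely open.

## The problem and the model

Whether a protein can be secreted into cerebrospinal fluid (CSF) is a
binary property we can only partially observe: proteomics catalogues
list proteins *detected* in CSF, but an undetected protein may simply be
below current instrument sensitivity — long, heavy proteins are
systematically harder for mass spectrometry. Training a conventional
classifier with "not yet detected" as the negative class would bake that
detection bias into the labels. The package therefore treats the task as
**positive-unlabeled (PU) learning**: a positive set `P` of verified CSF
proteins and an unlabeled pool `U` that mixes hidden positives with true
negatives.

The classifier is a **bagging ensemble over a disjoint partition of
`U`**. The pool is shuffled and cut into `T` equal subsets `U1 ... UT`
(remainder dropped); each `Ut` is paired with an equal-size random
sample from `P`, so every member trains on an exactly class-balanced
set in which unlabeled examples carry label 0. Each member is a small
feed-forward network: ReLU hidden layers

$$h_i^{l+1} = \max(0,\; w_i^{l+1} \cdot h^l + b_i^{l+1}),$$

a two-unit linear output $o_i = h \cdot \alpha_i + \beta_i$, and a
positive-class probability $p = e^{o_2} / (e^{o_1} + e^{o_2})$, trained
by minimizing mean binary cross-entropy with Adam. Because any single
member sees only a slice of `U`, its label noise (hidden positives
marked 0) differs from its siblings'; the ensemble prediction averages
only the members whose training data *exclude* the query protein
(out-of-bag averaging), so a training protein is never scored by a model
that memorized its possibly-wrong label. A protein is called CSF when
the averaged probability strictly exceeds 0.5.

Assumptions worth stating: hidden positives are assumed to be a minority
of `U` (the balanced per-member training still pushes them toward the
positive side of the decision boundary only if the signal from true
negatives dominates); sequences are assumed to be informative about
secretion through composition-derived descriptors; and the feature
blocks that require external predictors (signal peptides, transmembrane
helices, disorder, secondary structure) are treated as optional inputs,
not recomputed — absent, they are imputed at the training median and
carry no information.

## Feature construction

`build_feature_matrix()` produces 52 named blocks totalling 1610
dimensions. The computed blocks and their tunables:

| block | dims | parameters (default) |
|---|---|---|
| sequence length, mass, isoelectric point | 1+1+1 | average residue masses + one water; pI by bisection on the Henderson–Hasselbalch net charge with a standard pKa set |
| amino-acid / dipeptide composition | 20 + 400 | — |
| Moreau–Broto / Moran / Geary autocorrelation | 3 × 90 | 3 scales (hydrophobicity, polarity, polarizability) × maxlag 30 |
| quasi-sequence-order | 160 | two distance matrices × (20 + maxlag 60), coupling weight 0.1 |
| pseudo-amino-acid composition | 150 | λ = 130, weight 0.05, hydrophobicity/hydrophilicity/side-chain-mass scales |
| amphiphilic pseudo-AAC | 80 | λ = 30, weight 0.05 |
| total amino-acid property | 3 | sequence sums of hydrophobicity, charge, polarity |
| physicochemical profiles | 23 × 21 | property-weighted composition (20) + sequence mean (1) per scale |

The remaining 17 blocks (domain/motif, 15 dims; structural, 26 dims)
enter only through `ingest_external_features()`.

Open choices resolved here, and why:

- **Autocorrelation scale trio and lag count** (3 × 30 = 90 per kind)
  use the classic hydrophobicity/polarity/polarizability scales — the
  conventional triple for these descriptors.
- **Quasi-sequence-order** uses maxlag 60 over two matrices to give the
  160-dimension block. The first matrix is the Grantham distance,
  computed in code from its published formula
  (ρ√(1.833 Δc² + 0.1018 Δp² + 0.000399 Δv²), ρ = 50.723) and
  spot-checked against published values (Leu–Ile ≈ 5, Arg–Lys ≈ 26).
  The second is a **package-constructed physicochemical distance**
  (Euclidean over z-scored hydrophobicity, hydrophilicity and
  side-chain mass, rescaled to [0, 1]): the classical second matrix for
  this descriptor is not redistributable here, so a synthetic stand-in
  with the same structural role is shipped and documented as such.
- **λ = 130 / λ = 30** for the pseudo-composition blocks reproduce the
  150- and 80-dimension layouts; sequences shorter than a block's λ or
  maxlag get that block flagged missing (`NA`) rather than erroring —
  short real proteins exist, and the imputation step handles them.
- **21-dimension profiles** are defined as the composition weighted by
  the per-residue scale value plus the sequence mean of the scale.
  Scales with no redistributable literature table (surface tension,
  solubility, CLogP, and the ten interface / ligand-binding propensity
  scales) are shipped as fixed linear mixtures of the documented scales
  and flagged as synthetic in `aa_scales()`. This is benign by
  construction: after standardization a profile column is proportional
  to a composition column, so selection and classification see the same
  information regardless of the stand-in values; users with the original
  tables can supply them via the external-ingestion path.
- **Non-standard residues** (B, J, O, U, X, Z) are stripped with a
  warning by default (`policy = "strip"`), keeping real FASTA usable;
  `policy = "reject"` is available for strict pipelines.

## Preprocessing

`fit_scaler()` learns per-column medians (over observed values), then
means and standard deviations (population convention, divide-by-n) over
the imputed training matrix; `scaler_transform()` applies them to any
matrix. Statistics are learned from training data only — the
fit/transform split is the package's answer to a question the
methodology leaves open, and the defensible one: validation and test
rows can be perturbed freely without changing the transform.
Zero-variance columns map to 0 rather than NaN so downstream selection
stays well defined.

## Two-stage feature selection

Stage one tests each dimension with a two-sided Wilcoxon rank-sum test
(normal approximation with tie and continuity correction) and keeps
dimensions with Benjamini–Hochberg q ≤ α (default 0.05). Two wordings of
the screen circulate — "p more than q" versus a fixed q ≤ 0.05 cutoff —
and the package implements the explicit cutoff, with α exposed.

Stage two is recursive feature elimination on the *fixed* q-value
ranking: each iteration drops the `step = 20` largest-q surviving
dimensions (ties broken by column order, so the elimination order is
fully deterministic), retrains the surrogate model, and records
validation F1 and AUC; the final partial iteration drops down to a floor
of one column. Since BH adjustment preserves the p-value ordering,
ranking by q or by p gives identical eliminations. The surrogate is a
single network with the ensemble architecture rather than the full
`T`-member ensemble — a 16-fold cheaper stand-in whose relative scores
track the ensemble's — and its seed is reused at every iteration so the
curve is reproducible. `select_optimal()` picks the smallest feature
count scoring within `epsilon = 0.005` of the curve maximum (criterion
AUC by default): a plateau rule formalizing "performance became stable".
RFE retrains on training data only and scores on the validation split.

## Ensemble defaults

`pu_config()` defaults — `T = 16`, hidden `c(128, 128, 128)`, dropout
0.1, batch size 32, Adam at 0.001 for exactly 20 epochs, threshold 0.5 —
are the reference hyperparameters of the method. There is no early
stopping, schedule or weight decay. Per-member seeds derive
deterministically from the master seed; initialization is uniform in
±1/√fan_in. The softmax subtracts the row maximum before
exponentiating, and the loss clips probabilities at 1e-7. Partition
remainders are dropped (and recorded: 11954 ids over 16 subsets gives
747 each with 2 dropped) but still receive out-of-bag predictions as
unseen ids. Positive sampling is without replacement within a subset and
independent across subsets, so a positive can appear in several members;
one sampled into *all* members falls back to the all-member average with
a warning. Retraining on the whole dataset before prospective prediction
is done by simply calling `pu_fit()` on the merged pools.

## Differential expression and biomarkers

`de_analysis()` log2(x+1)-transforms, normalizes, tests each gene with
the same rank-sum/BH machinery (on the transformed scale — rank-sum
p-values are invariant under the monotone transform, which the suite
verifies), and computes fold change on the *raw* scale as the ratio of
case to control sums. The normalization method behind "normalize the
expression data" is not pinned by the methodology; quantile
normalization (each sample's sorted values replaced by cross-sample
means of sorted values, ties averaged) is the default, with
`method = "none"` available. Calls: up ⇔ q ≤ 0.05 and FC > 2, down ⇔
q ≤ 0.05 and FC < 0.5. Degenerate fold changes (control sum zero) are
flagged: Inf when the case sum is positive, 1 when both are zero.

`map_genes_to_proteins()` propagates calls through a many-to-many
gene→protein table; a protein inheriting both up and down is ambiguous
and excluded (with a warning) rather than arbitrated, and each protein
keeps the FC/q of its most significant gene. `intersect_biomarkers()`
partitions differentially expressed proteins into verified CSF
(verification overrides prediction), predicted candidates
(probability > 0.5, unverified — the biomarker nominations), and
not-CSF.

## Synthetic data: what it emulates, what it does not

The generators make every stage testable offline:

- `gen_pu_sequences()` — class-dependent residue composition (uniform
  base tilted by `exp(±shift)` over a fixed alternating pattern,
  per-sequence Dirichlet jitter, uniform lengths 50–300) with a
  configurable fraction (default 0.2) of hidden positives inside the
  unlabeled pool, latent truth recorded. Defaults: 300 positives, 600
  unlabeled, shift 0.5 — strongly separable by design, so that ensemble
  quality is attributable to the machinery, not to luck; shift 0 is the
  null generator. Lengths below λ = 130 occur by construction,
  exercising the missing-block path.
- `gen_feature_table()` — Gaussian features, 50 informative columns
  mean-shifted by 1.0 against 450 noise columns at 500 samples per
  class: the regime in which the stage-one screen should retain ≥95% of
  informative and ~5% of null columns.
- `gen_expression()` — per-gene log-normal baseline, 50 up-genes ×4 and
  50 down-genes ×0.25 planted among 900 nulls, 40 case / 40 control,
  log-scale noise sd 0.5.

What passing tests on these fixtures shows: the pipeline's statistics,
contracts and learning machinery behave correctly when their modelling
assumptions hold. What it does not show: performance on real proteomes,
where class signal is far weaker and structured (homology, domain
architecture, signal peptides), sequence composition is not Dirichlet,
expression is not log-normal with independent genes, and the
hidden-positive fraction is unknown. The generators contain no sequence
order structure at all beyond composition, so the autocorrelation / QSO
/ pseudo-composition blocks carry only incidental signal there.

## Numerical choices and degenerate inputs

- Property scales are z-normalized with the population (divide-by-20)
  convention; normalization is idempotent.
- Moran and Geary autocorrelation of a constant-property sequence
  (zero variance) return 0, not NaN.
- Rank-sum on a constant column returns p = 1; zero-denominator
  classification scores return 0 with a warning; AUC uses midranks.
- Infeasible descriptor blocks are `NA` (never silently zero) until
  median imputation.
- The Adam update, dropout masks and shuffling are all driven by seeds
  derived from the user-supplied seed; two identical calls produce
  bit-identical models.

## Problem sizes used in the shipped analyses

The test suite runs the generators at the defaults above (reduced sizes
for the purely structural checks, where the contract being tested does
not depend on scale). `scripts/acceptance.R` runs the full pipeline at
the generator defaults — 900 training sequences featurized to 1610
dimensions, stage-one screening, ~40 RFE iterations with the full
surrogate architecture, a 16-member ensemble, and a 1000-gene expression
stage — sizes chosen to exercise every code path at realistic
dimensionality while completing in minutes on one CPU.

## Known limitations

- The domain/motif and structural blocks are inert unless the user
  supplies predictor outputs; results on sequence-only input rest
  entirely on the computed blocks.
- The propensity-scale stand-ins make those profile columns
  composition-proportional; with real tables supplied they would carry
  distinct weightings.
- The RFE surrogate is a single network; the selected subset is not
  guaranteed optimal for the full ensemble.
- PU bagging calibrates probabilities only loosely; the 0.5 threshold
  is a convention, not an estimated operating point.
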