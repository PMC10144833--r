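# csfpred

Predicting which human proteins are secreted into cerebrospinal fluid
(CSF), and screening them against differentially expressed genes to
nominate fluid biomarker candidates.

CSF bathes the brain and spinal cord, so proteins secreted into it are
prime biomarker material for central-nervous-system disease — but
experimentally cataloguing the CSF proteome is slow and expensive, and
the absence of a protein from today's catalogues is not evidence that it
cannot reach CSF. That makes the computational problem
*positive-unlabeled* (PU): we have a set of verified CSF proteins `P`
and a large pool `U` of proteins that are unlabeled, not negative.
`csfpred` is for computational proteomics researchers who want a
transparent, fully scripted implementation of this prediction pipeline,
runnable end to end on synthetic data without any external databases.

## The method

**Features.** Each protein sequence is expanded into a 1610-dimension
vector over 52 named blocks: amino-acid and dipeptide composition,
normalized Moreau–Broto / Moran / Geary autocorrelation (3 property
scales × 30 lags each), quasi-sequence-order descriptors over two
residue-distance matrices (maxlag 60), type-1 pseudo-amino-acid
composition (λ = 130) and its amphiphilic variant (λ = 30), 21-dimension
physicochemical profiles, and simple scalars (length, mass, isoelectric
point). Predictor-derived blocks (signal peptide, transmembrane,
glycosylation, disorder, secondary structure) are ingested from external
tables rather than recomputed. Missing entries are median-imputed and
all columns standardized with training-set statistics only.

**Two-stage feature selection.** Stage one computes a two-sided Wilcoxon
rank-sum p-value per dimension against the CSF label and removes
dimensions with Benjamini–Hochberg q-value above 0.05. Stage two runs
recursive feature elimination on the fixed q-value ranking: the 20 least
important surviving dimensions are dropped per iteration, a surrogate
network is retrained, and validation F1/AUC are recorded; the final
subset is the smallest one whose validation score is within a small
tolerance of the best.

**PU bagging ensemble.** The unlabeled pool is shuffled and cut into
`T = 16` disjoint subsets; each is paired with an equal-size random
sample of positives, giving `T` exactly class-balanced training sets.
One feed-forward network (three ReLU hidden layers of 128 units,
dropout 0.1, softmax over two output units) is trained per subset with
Adam (learning rate 0.001, batch size 32, 20 epochs, cross-entropy
loss). A protein's score is the *out-of-bag* average

> p(x) = mean over { members t : x not in training set of t } of p_t(x)

and a protein is called CSF when p > 0.5 (strict).

**Biomarker stage.** Expression matrices are log2(x+1)-transformed and
quantile-normalized; per-gene rank-sum q-values and the fold change
FC_i = Σc_ij / Σn_ij (case sums over control sums) call genes up
(q ≤ 0.05, FC > 2) or down (q ≤ 0.05, FC < 0.5). Gene calls are mapped
to proteins and intersected with the predictions: differentially
expressed proteins that are predicted CSF but not experimentally
verified are the biomarker candidates.

## Worked example

```r
library(csfpred)

# small PU dataset: 60 labeled CSF proteins, 120 unlabeled (20% hidden positives)
sim <- gen_pu_sequences(n_pos = 60, n_unlabeled = 120, seed = 1)
features <- build_feature_matrix(
  sim$records, feature_config(c("aac", "dpc", "sequence_length", "mass")))
scaler <- fit_scaler(features)
std <- scaler_transform(features, scaler)
ens <- pu_fit(std, sim$positive_ids, sim$unlabeled_ids,
              pu_config(T = 4, hidden = c(32, 32), epochs = 10, seed = 1))
ens
#> <pu_ensemble> T=4, 422 features, hidden [32, 32]

pred <- predict(ens, std)
pred
#> # A tibble: 180 × 4
#>   protein_id probability label n_models
#>   <chr>            <dbl> <lgl>    <dbl>
#> 1 POS0001          0.830 TRUE         1
#> 2 POS0002          0.876 TRUE         3
#> 3 POS0003          0.687 TRUE         1
#> # i 177 more rows

truth <- c(rep(TRUE, 60), sim$truth$latent_positive)
evaluate_predictions(truth, pred$probability)
#> # A tibble: 1 × 6
#>     acc    pr    re    f1   mcc   auc
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0.994 0.988     1 0.994 0.989     1
```

`probability` is the out-of-bag ensemble score (here against the
generator's hidden truth: ACC 0.994, AUC 1 — the synthetic classes are
deliberately well separated); `n_models` is how many ensemble members
were averaged — unlabeled training proteins get exactly `T − 1`, ids
never seen in training get all `T`. Labeled positives sampled into every
member's training set fall back to the all-member average with a
warning, which the run above shows for 4 of the 60 positives (small `T`
makes this common; at `T = 16` it is rare).

Feature selection and the differential-expression stage chain the same
way: `run_feature_selection()` returns an object with `tidy()`,
`glance()` and `autoplot()` methods, `de_analysis()` /
`map_genes_to_proteins()` / `intersect_biomarkers()` produce the
biomarker candidate table. A thin command-line wrapper
(`inst/exec/csfpred`, subcommands `featurize`, `select`, `train`,
`predict`, `evaluate`, `de`, `biomarkers`, `simulate`) drives the same
functions from a shell.

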