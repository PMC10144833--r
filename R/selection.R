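# Two-stage feature selection: rank-sum + BH-FDR screen for irrelevant
# dimensions, then q-value-ranked recursive feature elimination with
# validation scoring for redundant ones.

#' Per-column rank-sum p-values
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test of each feature column
#' against a binary grouping (normal approximation with tie and
#' continuity correction).  Columns that are constant across both groups
#' get p = 1.
#'
#' @param data Tibble of numeric feature columns (a `protein_id` column,
#'   if present, is ignored); no missing values.
#' @param labels Binary vector, one per row.
#' @return Named vector of p-values in \[0, 1\].
#' @export
ranksum_pvalues <- function(data, labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be binary with no missing values")
  if (!any(labels) || all(labels)) stop("both label groups must be non-empty")
  cols <- setdiff(names(data), "protein_id")
  vapply(cols, function(cl) {
    x <- data[[cl]]
    if (anyNA(x)) stop("missing values in column ", cl, "; impute first")
    if (length(unique(x)) == 1L) return(1)
    suppressWarnings(
      stats::wilcox.test(x[labels], x[!labels], exact = FALSE,
                         correct = TRUE)$p.value)
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values with monotonicity enforcement;
#' `q >= p` elementwise.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values, names preserved.
#' @export
bh_qvalues <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Stage-one irrelevance filter
#'
#' @param q Vector of q-values.
#' @param alpha FDR cutoff (default 0.05).
#' @return Logical keep-mask: `TRUE` iff `q <= alpha`.
#' @export
stage1_filter <- function(q, alpha = 0.05) {
  q <= alpha
}

# evaluate one candidate column set: train the surrogate model, score on
# the validation split
.rfe_eval <- function(cols, train, labels, valid, valid_labels, train_fun,
                      seed) {
  model <- train_fun(as.matrix(train[, cols, drop = FALSE]),
                     as.numeric(labels), seed)
  prob <- mlp_forward(model, as.matrix(valid[, cols, drop = FALSE]))
  sc <- classification_scores(confusion_counts(valid_labels, prob > 0.5))
  tibble::tibble(n_features = length(cols), f1 = sc$f1,
                 auc = auc_score(valid_labels, prob))
}

default_rfe_model <- function(hidden = c(128, 128, 128), dropout = 0.1,
                              epochs = 20, batch_size = 32,
                              learning_rate = 0.001) {
  function(X, y, seed) {
    mlp_train(X, y, hidden = hidden, dropout = dropout,
              batch_size = batch_size, learning_rate = learning_rate,
              epochs = epochs, seed = seed)
  }
}

#' Recursive feature elimination on a fixed importance ranking
#'
#' Starting from all columns, repeatedly drops the `step` columns with the
#' largest q-value (least important; ties broken by column order), retrains
#' the surrogate classifier on the survivors and records validation F1 and
#' AUC.  Because the ranking is fixed, the elimination order is fully
#' determined before the first iteration.  The final iteration drops the
#' remainder down to a floor of one column.
#'
#' @param train,valid Feature tibbles (training / validation split).
#' @param labels,valid_labels Binary labels per row.
#' @param importance Named q-values covering every feature column (larger
#'   means less important).
#' @param step Columns removed per iteration (default 20).
#' @param train_fun Surrogate model factory `function(X, y, seed)`
#'   returning a `csf_mlp`; defaults to a single network with the ensemble
#'   architecture.
#' @param seed Seed for the surrogate model, reused at each iteration so
#'   the curve is reproducible.
#' @return List with `curve` (tibble `n_features`, `f1`, `auc`; first row
#'   is the full set) and `ranking` (columns ordered most- to
#'   least-important).
#' @export
rfe <- function(train, labels, valid, valid_labels, importance, step = 20,
                train_fun = default_rfe_model(), seed = 1) {
  cols <- setdiff(names(train), "protein_id")
  stopifnot(all(cols %in% names(importance)))
  imp <- importance[cols]
  ranking <- cols[order(imp, seq_along(imp))]  # stable: ties by column order
  surviving <- ranking
  curve <- .rfe_eval(surviving, train, labels, valid, valid_labels,
                     train_fun, seed)
  while (length(surviving) > 1L) {
    drop_n <- min(step, length(surviving) - 1L)
    surviving <- surviving[seq_len(length(surviving) - drop_n)]
    curve <- dplyr::bind_rows(
      curve, .rfe_eval(surviving, train, labels, valid, valid_labels,
                       train_fun, seed))
  }
  list(curve = curve, ranking = ranking)
}

#' Pick the optimal feature count from an RFE curve
#'
#' Smallest feature count whose criterion score is within `epsilon` of the
#' best score on the curve.
#'
#' @param curve Tibble with `n_features` and the criterion column.
#' @param epsilon Plateau tolerance (default 0.005).
#' @param criterion `"auc"` (default) or `"f1"`.
#' @return The selected `n_features`.
#' @export
select_optimal <- function(curve, epsilon = 0.005,
                           criterion = c("auc", "f1")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(curve) > 0)
  score <- curve[[criterion]]
  ok <- score >= max(score) - epsilon
  min(curve$n_features[ok])
}

#' Two-stage feature selection
#'
#' Runs the rank-sum/FDR screen on the training split, then recursive
#' feature elimination over the surviving columns with validation
#' scoring, and returns the selected column set.
#'
#' @inheritParams rfe
#' @param alpha Stage-one FDR cutoff (default 0.05).
#' @param epsilon,criterion Plateau rule, see [select_optimal()].
#' @return A `csf_selection` object: `p_values`, `q_values`,
#'   `stage1_mask`, `curve`, `ranking`, `selected_columns`.
#' @export
run_feature_selection <- function(train, labels, valid, valid_labels,
                                  alpha = 0.05, step = 20,
                                  epsilon = 0.005, criterion = "auc",
                                  train_fun = default_rfe_model(),
                                  seed = 1) {
  p <- ranksum_pvalues(train, labels)
  q <- bh_qvalues(p)
  keep <- stage1_filter(q, alpha)
  if (!any(keep)) stop("stage one removed every feature; nothing to select")
  surv <- names(q)[keep]
  id_cols <- intersect("protein_id", names(train))
  r <- rfe(train[, c(id_cols, surv)], labels,
           valid[, c(id_cols, surv)], valid_labels,
           importance = q[surv], step = step, train_fun = train_fun,
           seed = seed)
  n_opt <- select_optimal(r$curve, epsilon = epsilon, criterion = criterion)
  structure(list(p_values = p, q_values = q, stage1_mask = keep,
                 alpha = alpha, curve = r$curve, ranking = r$ranking,
                 selected_columns = r$ranking[seq_len(n_opt)]),
            class = "csf_selection")
}

#' @export
print.csf_selection <- function(x, ...) {
  cat("<csf_selection> ", length(x$p_values), " features -> stage 1 kept ",
      sum(x$stage1_mask), " -> selected ", length(x$selected_columns),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.csf_selection <- function(x, ...) {
  tibble::tibble(column = names(x$p_values),
                 p_value = unname(x$p_values),
                 q_value = unname(x$q_values),
                 stage1_keep = unname(x$stage1_mask),
                 selected = names(x$p_values) %in% x$selected_columns)
}

#' @importFrom generics glance
#' @export
glance.csf_selection <- function(x, ...) {
  tibble::tibble(n_features = length(x$p_values),
                 n_stage1 = sum(x$stage1_mask),
                 n_selected = length(x$selected_columns),
                 best_auc = max(x$curve$auc),
                 best_f1 = max(x$curve$f1))
}
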