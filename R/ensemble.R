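# Positive-unlabeled bagging: the unlabeled pool is partitioned into T
# disjoint subsets, each paired with an equal-size random sample of
# positives, one network trained per pair, and predictions made by
# averaging only the members whose training data exclude the query
# protein (out-of-bag averaging).

#' Ensemble configuration
#'
#' Defaults: 16 members, three hidden layers of 128 ReLU units, dropout
#' 0.1, batch size 32, Adam at learning rate 0.001 for 20 epochs,
#' decision threshold 0.5.
#'
#' @param T Number of ensemble members.
#' @param hidden Hidden-layer widths.
#' @param dropout Dropout probability in [0, 1).
#' @param batch_size,learning_rate,epochs Optimizer settings.
#' @param seed Master seed; per-member seeds are derived from it.
#' @param threshold Probability cutoff for the positive call (strict:
#'   positive iff p > threshold).
#' @return Named list of settings.
#' @export
pu_config <- function(T = 16, hidden = c(128, 128, 128), dropout = 0.1,
                      batch_size = 32, learning_rate = 0.001, epochs = 20,
                      seed = 1, threshold = 0.5) {
  stopifnot(T >= 1, dropout >= 0, dropout < 1)
  list(T = T, hidden = hidden, dropout = dropout, batch_size = batch_size,
       learning_rate = learning_rate, epochs = epochs, seed = seed,
       threshold = threshold)
}

member_seed <- function(seed, t) {
  (seed + 7919L * t) %% .Machine$integer.max
}

#' Partition the unlabeled pool into T disjoint equal-size subsets
#'
#' Shuffles with the seed and cuts into T blocks of size
#' `floor(n / T)`; remainder ids are dropped (and reported).
#'
#' @param ids Unlabeled protein ids.
#' @param T Number of subsets.
#' @param seed RNG seed.
#' @return List of T character vectors; dropped ids in attribute
#'   `"dropped"`.
#' @export
partition_unlabeled <- function(ids, T, seed = 1) {
  n <- length(ids)
  if (n < T) stop("fewer unlabeled ids than subsets")
  set.seed(seed)
  perm <- sample(ids)
  size <- n %/% T
  keep <- perm[seq_len(size * T)]
  dropped <- perm[-seq_len(size * T)]
  if (length(dropped) > 0) {
    message("partition_unlabeled: dropped ", length(dropped),
            " remainder id(s)")
  }
  out <- split(keep, rep(seq_len(T), each = size))
  names(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Sample T positive subsets
#'
#' Each subset is drawn without replacement within itself and
#' independently of the other subsets, so a positive may appear in
#' several subsets.
#'
#' @param ids Positive protein ids.
#' @param T Number of subsets.
#' @param size Subset size (must not exceed `length(ids)`).
#' @param seed RNG seed.
#' @return List of T character vectors of length `size`.
#' @export
sample_positive_subsets <- function(ids, T, size, seed = 1) {
  if (length(ids) < size) stop("not enough positive ids for subset size")
  set.seed(seed)
  lapply(seq_len(T), function(t) sample(ids, size))
}

#' Fit the positive-unlabeled bagging ensemble
#'
#' @param features Preprocessed feature tibble with `protein_id` plus the
#'   selected feature columns (no missing values).
#' @param positive_ids,unlabeled_ids Protein ids of the two pools; every
#'   id must be present in `features`.
#' @param config See [pu_config()].
#' @return A `pu_ensemble`: member parameter sets, the membership index
#'   (which ids each member trained on), the config and feature columns.
#' @export
pu_fit <- function(features, positive_ids, unlabeled_ids,
                   config = pu_config()) {
  stopifnot("protein_id" %in% names(features))
  if (length(positive_ids) == 0 || length(unlabeled_ids) == 0) {
    stop("positive and unlabeled pools must be non-empty")
  }
  missing <- setdiff(c(positive_ids, unlabeled_ids), features$protein_id)
  if (length(missing) > 0) {
    stop("ids without feature rows: ", paste(utils::head(missing, 5),
                                             collapse = ", "))
  }
  cols <- setdiff(names(features), "protein_id")
  X <- as.matrix(features[, cols])
  rownames(X) <- features$protein_id
  u_parts <- partition_unlabeled(unlabeled_ids, config$T, config$seed)
  size <- length(u_parts[[1]])
  p_parts <- sample_positive_subsets(positive_ids, config$T, size,
                                     config$seed + 1L)
  models <- vector("list", config$T)
  membership <- vector("list", config$T)
  for (t in seq_len(config$T)) {
    pos <- p_parts[[t]]; unl <- u_parts[[t]]
    Xi <- X[c(pos, unl), , drop = FALSE]
    yi <- c(rep(1, length(pos)), rep(0, length(unl)))
    models[[t]] <- mlp_train(Xi, yi, hidden = config$hidden,
                             dropout = config$dropout,
                             batch_size = config$batch_size,
                             learning_rate = config$learning_rate,
                             epochs = config$epochs,
                             seed = member_seed(config$seed, t))
    membership[[t]] <- list(positive = pos, unlabeled = unl)
  }
  structure(list(config = config, models = models, membership = membership,
                 feature_columns = cols,
                 dropped_unlabeled = attr(u_parts, "dropped")),
            class = "pu_ensemble")
}

#' Out-of-bag ensemble prediction
#'
#' For each protein, averages the probabilities of the members whose
#' training subsets do not contain its id; ids unseen during training
#' average all members.  An id present in every member's training set
#' (possible only for positives) averages all members, with a warning.
#'
#' @param object A `pu_ensemble`.
#' @param features Feature tibble with `protein_id` and the ensemble's
#'   feature columns, preprocessed with the same scaler.
#' @param ... Unused.
#' @return Tibble `protein_id`, `probability`, `label` (strict
#'   `probability > threshold`), `n_models`.
#' @export
predict.pu_ensemble <- function(object, features, ...) {
  cols <- object$feature_columns
  stopifnot(all(cols %in% names(features)))
  X <- as.matrix(features[, cols])
  probs <- vapply(object$models, function(m) mlp_forward(m, X),
                  numeric(nrow(X)))
  probs <- matrix(probs, nrow = nrow(X))
  in_member <- vapply(object$membership, function(mb) {
    features$protein_id %in% c(mb$positive, mb$unlabeled)
  }, logical(nrow(X)))
  in_member <- matrix(in_member, nrow = nrow(X))
  everywhere <- rowSums(!in_member) == 0
  if (any(everywhere)) {
    warning(sum(everywhere), " protein(s) present in every training ",
            "subset; averaging all members")
    in_member[everywhere, ] <- FALSE
  }
  w <- !in_member
  probability <- rowSums(probs * w) / rowSums(w)
  tibble::tibble(protein_id = features$protein_id,
                 probability = probability,
                 label = probability > object$config$threshold,
                 n_models = rowSums(w))
}

#' Strict-threshold classification of probabilities
#'
#' @param probability Numeric vector in \[0, 1\].
#' @param threshold Cutoff (default 0.5); positive iff strictly greater.
#' @return Logical vector.
#' @export
classify <- function(probability, threshold = 0.5) {
  probability > threshold
}

#' @export
print.pu_ensemble <- function(x, ...) {
  cat("<pu_ensemble> T=", x$config$T, ", ", length(x$feature_columns),
      " features, hidden [", paste(x$config$hidden, collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.pu_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$models), function(t) {
    loss <- attr(x$models[[t]], "loss")
    tibble::tibble(model = t,
                   n_positive = length(x$membership[[t]]$positive),
                   n_unlabeled = length(x$membership[[t]]$unlabeled),
                   final_loss = loss[length(loss)])
  })
}

#' @importFrom generics glance
#' @export
glance.pu_ensemble <- function(x, ...) {
  tibble::tibble(T = x$config$T,
                 n_features = length(x$feature_columns),
                 epochs = x$config$epochs,
                 subset_size = length(x$membership[[1]]$unlabeled),
                 n_dropped_unlabeled = length(x$dropped_unlabeled))
}
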