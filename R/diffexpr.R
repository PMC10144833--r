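# Differential expression by rank-sum test + BH-FDR + fold change, gene to
# protein mapping, and the intersection with predicted CSF proteins that
# yields biomarker candidates.

expr_matrix <- function(expr) {
  stopifnot("gene_id" %in% names(expr))
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  m
}

expr_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' log2(x + 1) transform of an expression matrix
#'
#' @param expr Tibble with `gene_id` plus non-negative sample columns.
#' @return Transformed tibble of the same shape.
#' @export
log_transform <- function(expr) {
  m <- expr_matrix(expr)
  if (any(m < 0)) stop("expression values must be non-negative")
  expr_tibble(log2(m + 1))
}

#' Between-sample normalization of expression values
#'
#' Quantile normalization (each sample's sorted values replaced by the
#' cross-sample means of sorted values, ties assigned the mean of the
#' pooled quantiles) or identity.
#'
#' @param expr Expression tibble (typically log-transformed).
#' @param method `"quantile"` (default) or `"none"`.
#' @return Normalized tibble.
#' @export
normalize_expression <- function(expr, method = c("quantile", "none")) {
  method <- match.arg(method)
  if (method == "none") return(expr)
  m <- expr_matrix(expr)
  expr_tibble(limma::normalizeQuantiles(m, ties = TRUE))
}

#' Per-gene fold change
#'
#' Ratio of summed case expression to summed control expression,
#' computed on the untransformed scale.  Zero control sum with positive
#' case sum gives `Inf`; zero in both groups gives 1.  Both degenerate
#' cases are flagged.
#'
#' @param expr Raw (untransformed) expression tibble.
#' @param groups Tibble with `sample_id` and `group` (`"case"` /
#'   `"control"`) covering every sample column.
#' @return Tibble `gene_id`, `fc`, `fc_flag`.
#' @export
fold_change <- function(expr, groups) {
  m <- expr_matrix(expr)
  grp <- groups$group[match(colnames(m), groups$sample_id)]
  if (anyNA(grp)) stop("group labels missing for some samples")
  cs <- unname(rowSums(m[, grp == "case", drop = FALSE]))
  ns <- unname(rowSums(m[, grp == "control", drop = FALSE]))
  fc <- cs / ns
  flag <- rep(FALSE, length(fc))
  flag[ns == 0] <- TRUE
  fc[ns == 0 & cs > 0] <- Inf
  fc[ns == 0 & cs == 0] <- 1
  tibble::tibble(gene_id = rownames(m), fc = fc, fc_flag = flag)
}

#' Call regulation status from q-values and fold change
#'
#' Up-regulated iff `q <= alpha` and `fc > fc_cutoff`; down-regulated iff
#' `q <= alpha` and `fc < 1 / fc_cutoff`; otherwise unchanged.
#'
#' @param q,fc Aligned per-gene vectors.
#' @param alpha FDR cutoff (default 0.05).
#' @param fc_cutoff Fold-change cutoff (default 2).
#' @return Character vector `"up"` / `"down"` / `"unchanged"`.
#' @export
de_call <- function(q, fc, alpha = 0.05, fc_cutoff = 2) {
  dplyr::case_when(q <= alpha & fc > fc_cutoff ~ "up",
                   q <= alpha & fc < 1 / fc_cutoff ~ "down",
                   TRUE ~ "unchanged")
}

#' Differential-expression analysis
#'
#' log2(x+1) transform, between-sample normalization, per-gene two-sided
#' rank-sum test with BH q-values (on the transformed scale), fold change
#' on the raw scale, and status calls.
#'
#' @inheritParams fold_change
#' @param alpha,fc_cutoff Cutoffs for [de_call()].
#' @param normalize Normalization method, see [normalize_expression()].
#' @return Tibble `gene_id`, `p_value`, `q_value`, `fc`, `status`.
#' @export
de_analysis <- function(expr, groups, alpha = 0.05, fc_cutoff = 2,
                        normalize = "quantile") {
  norm <- normalize_expression(log_transform(expr), method = normalize)
  m <- expr_matrix(norm)
  grp <- groups$group[match(colnames(m), groups$sample_id)]
  # genes are rows here; reuse the per-column rank-sum test on the transpose
  p <- ranksum_pvalues(tibble::as_tibble(t(m)), grp == "case")
  q <- bh_qvalues(p)
  fcv <- fold_change(expr, groups)$fc
  tibble::tibble(gene_id = rownames(m), p_value = unname(p),
                 q_value = unname(q), fc = fcv,
                 status = de_call(q, fcv, alpha, fc_cutoff))
}

#' Map gene-level statuses to proteins
#'
#' Proteins inherit the status of their encoding genes (many-to-many
#' mappings allowed).  Proteins receiving both "up" and "down" from
#' different genes are ambiguous and excluded with a warning; unmapped
#' genes are dropped and counted.  Each protein keeps the fold change and
#' q-value of its most significant (smallest-q) differentially expressed
#' gene.
#'
#' @param de Tibble from [de_analysis()].
#' @param mapping Tibble with `gene_id`, `protein_id`.
#' @return Tibble `protein_id`, `fc`, `q_value`, `status` (up/down only).
#' @export
map_genes_to_proteins <- function(de, mapping) {
  sig <- dplyr::filter(de, .data$status != "unchanged")
  unmapped <- setdiff(sig$gene_id, mapping$gene_id)
  if (length(unmapped) > 0) {
    message("map_genes_to_proteins: ", length(unmapped),
            " differentially expressed gene(s) had no protein mapping")
  }
  joined <- dplyr::inner_join(sig, mapping, by = "gene_id",
                              relationship = "many-to-many")
  if (nrow(joined) == 0) {
    return(tibble::tibble(protein_id = character(0), fc = numeric(0),
                          q_value = numeric(0), status = character(0)))
  }
  per_prot <- joined |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(n_status = dplyr::n_distinct(.data$status),
                     fc = .data$fc[which.min(.data$q_value)],
                     q_value = min(.data$q_value),
                     status = .data$status[which.min(.data$q_value)],
                     .groups = "drop")
  conflicted <- per_prot$n_status > 1
  if (any(conflicted)) {
    warning(sum(conflicted), " protein(s) with conflicting up/down ",
            "statuses excluded")
  }
  per_prot[!conflicted, c("protein_id", "fc", "q_value", "status")]
}

#' Intersect differentially expressed proteins with CSF predictions
#'
#' Partitions the differentially expressed proteins into three
#' categories: `verified_CSF` (in the experimentally verified set,
#' regardless of the predicted probability), `predicted_candidate`
#' (probability above the threshold and not verified — the biomarker
#' candidates), and `not_CSF`.  Rows are ordered by decreasing
#' probability.
#'
#' @param protein_de Tibble from [map_genes_to_proteins()].
#' @param predictions Tibble with `protein_id`, `probability`.
#' @param verified_ids Character vector of verified CSF protein ids.
#' @param threshold Probability cutoff (default 0.5, strict).
#' @return Tibble `protein_id`, `fc`, `probability`, `q_value`, `status`,
#'   `category`.
#' @export
intersect_biomarkers <- function(protein_de, predictions, verified_ids,
                                 threshold = 0.5) {
  out <- dplyr::left_join(protein_de,
                          predictions[, c("protein_id", "probability")],
                          by = "protein_id")
  unpredicted <- is.na(out$probability) &
    !(out$protein_id %in% verified_ids)
  if (any(unpredicted)) {
    warning(sum(unpredicted), " differentially expressed protein(s) ",
            "without prediction or verification; categorized not_CSF")
  }
  out$category <- dplyr::case_when(
    out$protein_id %in% verified_ids ~ "verified_CSF",
    !is.na(out$probability) & out$probability > threshold ~
      "predicted_candidate",
    TRUE ~ "not_CSF")
  dplyr::arrange(out[, c("protein_id", "fc", "probability", "q_value",
                         "status", "category")],
                 dplyr::desc(.data$probability))
}
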