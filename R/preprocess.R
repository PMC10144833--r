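# Median imputation and standardization with training-only statistics.

#' Fit imputation / standardization statistics on training features
#'
#' Learns, per feature column: the median of observed values (used to fill
#' missing entries), then the mean and population standard deviation of
#' the post-imputation values.  Columns with no observed value get median
#' 0 and are flagged, with a warning.
#'
#' @param train Tibble with `protein_id` plus numeric feature columns
#'   (missing values as `NA`).
#' @return A `feature_scaler` object.
#' @export
fit_scaler <- function(train) {
  cols <- setdiff(names(train), "protein_id")
  stats_tbl <- purrr::map_dfr(cols, function(cl) {
    x <- train[[cl]]
    all_missing <- all(is.na(x))
    med <- if (all_missing) 0 else stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- med
    mu <- mean(x)
    sd <- sqrt(mean((x - mu)^2))
    tibble::tibble(column = cl, median = med, mean = mu, sd = sd,
                   all_missing = all_missing)
  })
  if (any(stats_tbl$all_missing)) {
    warning(sum(stats_tbl$all_missing),
            " column(s) had no observed values; median set to 0")
  }
  structure(list(stats = stats_tbl), class = "feature_scaler")
}

#' Apply a fitted scaler
#'
#' Fills missing values with the training medians, then standardizes with
#' the training mean and standard deviation.  Zero-variance columns map
#' to 0.  No statistic is re-estimated from `data`, so validation and
#' test partitions never leak into the transform.
#'
#' @param data Feature tibble whose columns match the scaler.
#' @param scaler A `feature_scaler` from [fit_scaler()].
#' @return Tibble of the same shape with no missing values.
#' @export
scaler_transform <- function(data, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  st <- scaler$stats
  cols <- setdiff(names(data), "protein_id")
  if (!identical(sort(cols), sort(st$column))) {
    stop("feature columns do not match the fitted scaler")
  }
  out <- data
  for (i in seq_len(nrow(st))) {
    cl <- st$column[i]
    x <- data[[cl]]
    x[is.na(x)] <- st$median[i]
    out[[cl]] <- if (st$sd[i] == 0) rep(0, length(x)) else
      (x - st$mean[i]) / st$sd[i]
  }
  out
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat("<feature_scaler> ", nrow(x$stats), " columns (",
      sum(x$stats$all_missing), " all-missing)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.feature_scaler <- function(x, ...) x$stats

#' Serialize a scaler to JSON
#' @param scaler A `feature_scaler`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scaler <- function(scaler, path) {
  jsonlite::write_json(scaler$stats, path, digits = NA)
  invisible(path)
}

#' Read a scaler from JSON
#' @param path JSON file written by [write_scaler()].
#' @return A `feature_scaler`.
#' @export
read_scaler <- function(path) {
  structure(list(stats = tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))),
            class = "feature_scaler")
}
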