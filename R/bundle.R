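# Model bundle directory: config, membership, per-member parameters and
# the selected-column list, all as JSON / plain text.

#' Save a PU ensemble to a bundle directory
#'
#' Writes `config.json`, `membership.json`, `models.json`,
#' `columns.txt` and, when supplied, `scaler.json`.
#'
#' @param ensemble A `pu_ensemble`.
#' @param dir Output directory (created if needed).
#' @param scaler Optional `feature_scaler` to store alongside.
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir, scaler = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(ensemble$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(ensemble$membership, file.path(dir, "membership.json"),
                       digits = NA)
  models <- lapply(ensemble$models, function(m) {
    list(input_dim = m$input_dim, hidden = m$hidden,
         layers = lapply(m$layers, function(ly) {
           list(W = ly$W, b = ly$b)
         }))
  })
  jsonlite::write_json(models, file.path(dir, "models.json"), digits = NA)
  writeLines(ensemble$feature_columns, file.path(dir, "columns.txt"))
  writeLines(ensemble$dropped_unlabeled, file.path(dir, "dropped.txt"))
  if (!is.null(scaler)) write_scaler(scaler, file.path(dir, "scaler.json"))
  invisible(dir)
}

#' Load a PU ensemble from a bundle directory
#'
#' @param dir Directory written by [save_ensemble()].
#' @return A `pu_ensemble`; a stored scaler, if any, is attached as
#'   attribute `"scaler"`.
#' @export
load_ensemble <- function(dir) {
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  config <- pu_config(T = config$T, hidden = config$hidden,
                      dropout = config$dropout,
                      batch_size = config$batch_size,
                      learning_rate = config$learning_rate,
                      epochs = config$epochs, seed = config$seed,
                      threshold = config$threshold)
  membership_raw <- jsonlite::read_json(file.path(dir, "membership.json"))
  membership <- lapply(membership_raw, function(mb) {
    list(positive = as.character(unlist(mb$positive)),
         unlabeled = as.character(unlist(mb$unlabeled)))
  })
  models_raw <- jsonlite::read_json(file.path(dir, "models.json"))
  models <- lapply(models_raw, function(m) {
    layers <- lapply(m$layers, function(ly) {
      W <- do.call(rbind, lapply(ly$W, function(row) as.numeric(unlist(row))))
      list(W = W, b = as.numeric(unlist(ly$b)))
    })
    structure(list(layers = layers,
                   input_dim = as.integer(unlist(m$input_dim)),
                   hidden = as.integer(unlist(m$hidden))),
              class = "csf_mlp")
  })
  out <- structure(list(config = config, models = models,
                        membership = membership,
                        feature_columns = readLines(file.path(dir, "columns.txt")),
                        dropped_unlabeled = readLines(file.path(dir, "dropped.txt"))),
                   class = "pu_ensemble")
  scaler_path <- file.path(dir, "scaler.json")
  if (file.exists(scaler_path)) attr(out, "scaler") <- read_scaler(scaler_path)
  out
}
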