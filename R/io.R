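# Readers and writers for FASTA, feature tables and id lists.

#' Read protein records from FASTA
#'
#' Wrapped sequence lines are joined; the record id is the first
#' whitespace token of the header.  Duplicate ids are an error, an empty
#' file yields an empty tibble with a warning.
#'
#' @param path FASTA file.
#' @return Tibble with `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    warning("no records in ", path)
    return(tibble::tibble(id = character(0), sequence = character(0)))
  }
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path)
  tibble::tibble(id = ids, sequence = unname(as.character(set)))
}

#' Write protein records to FASTA
#'
#' @param records Tibble with `id`, `sequence`.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a feature table from TSV
#'
#' Tab-separated, first column `protein_id`, empty cells read as missing.
#'
#' @param path TSV file.
#' @return Feature tibble.
#' @export
read_feature_table <- function(path) {
  out <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed table ", path, ": row ", probs$row[1], ", ",
         probs$expected[1])
  }
  names(out)[1] <- "protein_id"
  # a column that is entirely empty parses as logical; it is numeric here
  for (cl in names(out)[-1]) {
    if (is.logical(out[[cl]]) && all(is.na(out[[cl]]))) {
      out[[cl]] <- as.numeric(out[[cl]])
    }
  }
  out
}

#' Write a feature table to TSV
#'
#' Missing values are written as empty cells.
#'
#' @param data Feature tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  readr::write_tsv(data, path, na = "")
  invisible(path)
}

#' Read / write one-id-per-line label files
#'
#' @param path Text file with one protein id per line.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' @rdname read_id_list
#' @param ids Character vector to write.
#' @export
write_id_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
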