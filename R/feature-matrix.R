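# Block configuration and assembly of the proteins x 1610 feature matrix.

profile_scale_names <- function() {
  c("hydrophobicity", "vdw_volume", "polarity", "polarizability", "charge",
    "solvent_accessibility", "surface_tension", "molecular_weight",
    "solubility", "hbond_donors", "hbond_acceptors", "clogp", "flexibility",
    "ppi_hotspot_bogan", "ppi_propensity_ma", "dna_interface_schneider",
    "dna_interface_ahmad", "rna_interface_kim", "rna_interface_ellis",
    "rna_interface_phipps", "ligand_binding_khazanov",
    "ligand_valid_khazanov", "ligand_polar_imai")
}

#' Default descriptor parameters
#'
#' Tunable lags / tiers / weights of the sequence descriptors.  The
#' defaults reproduce the standard 1610-dimension configuration
#' (autocorrelation 3 scales x 30 lags, QSO maxlag 60 over two matrices,
#' pseudo-composition lambda 130, amphiphilic lambda 30).
#'
#' @param ac_maxlag,qso_maxlag,paac_lambda,apaac_lambda Integer settings.
#' @param qso_weight,paac_weight,apaac_weight Real weights.
#' @return Named list of parameters.
#' @export
feature_params <- function(ac_maxlag = 30, qso_maxlag = 60, qso_weight = 0.1,
                           paac_lambda = 130, paac_weight = 0.05,
                           apaac_lambda = 30, apaac_weight = 0.05) {
  list(ac_maxlag = ac_maxlag, qso_maxlag = qso_maxlag,
       qso_weight = qso_weight, paac_lambda = paac_lambda,
       paac_weight = paac_weight, apaac_lambda = apaac_lambda,
       apaac_weight = apaac_weight)
}

# internal: full block table for a parameter set
block_specs <- function(params = feature_params()) {
  n_ac <- 3 * params$ac_maxlag
  general <- tibble::tibble(
    block = c("sequence_length", "mass", "aac", "dpc", "moreau_broto",
              "moran", "geary", "qso", "paac", "apaac", "total_aa_property"),
    group = "general",
    length = c(1, 1, 20, 400, n_ac, n_ac, n_ac,
               2 * (20 + params$qso_maxlag), 20 + params$paac_lambda,
               20 + 2 * params$apaac_lambda, 3),
    source = "computed")
  phys <- tibble::tibble(
    block = c(profile_scale_names(), "isoelectric_point"),
    group = "physicochemical",
    length = c(rep(21, 23), 1),
    source = "computed")
  dm <- tibble::tibble(
    block = c("twin_arginine_signal", "transmembrane_domains",
              "signal_peptide", "n_glycosylation_sites",
              "glycosylation_presence", "phosphorylation_sites",
              "cleavage_site", "subcellular_location", "coil_content",
              "motif_sites", "transmembrane_helices"),
    group = "domain_motif",
    length = c(1, 1, 1, 1, 1, 1, 3, 3, 1, 1, 1),
    source = "external")
  struct <- tibble::tibble(
    block = c("secondary_structure", "unfoldability", "fldbin_charge",
              "n_disordered_regions", "longest_disordered_region",
              "n_disordered_residues"),
    group = "structural",
    length = c(21, 1, 1, 1, 1, 1),
    source = "external")
  dplyr::bind_rows(general, phys, dm, struct)
}

#' Feature block configuration
#'
#' One row per named feature block with its group, dimension count and
#' whether it is computed from the sequence or ingested from an external
#' predictor table.  The default configuration has 52 blocks totalling
#' 1610 dimensions.
#'
#' @param blocks Optional character vector restricting to a subset of
#'   block names (order preserved from the default table).
#' @param params Descriptor parameters, see [feature_params()].
#' @return Tibble with columns `block`, `group`, `length`, `source`.
#' @export
feature_config <- function(blocks = NULL, params = feature_params()) {
  cfg <- block_specs(params)
  if (!is.null(blocks)) {
    unknown <- setdiff(blocks, cfg$block)
    if (length(unknown) > 0) {
      stop("unknown feature block(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- cfg[cfg$block %in% blocks, ]
  }
  cfg
}

# column names of one block, qualified as "<block>.<dim>"; single-dimension
# blocks use the bare block name (this is also the external-table contract)
block_colnames <- function(block, length, params = feature_params()) {
  if (length == 1) return(block)
  inner <- switch(block,
    aac = aa_alphabet(),
    dpc = dpc_names(),
    moreau_broto = ,
    moran = ,
    geary = names(autocorrelation("ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWY",
                                  maxlag = params$ac_maxlag,
                                  kind = "moreau_broto")),
    qso = names(qso(paste(rep("A", params$qso_maxlag + 1), collapse = ""),
                    maxlag = params$qso_maxlag)),
    paac = c(aa_alphabet(), sprintf("lam%03d", seq_len(params$paac_lambda))),
    apaac = c(aa_alphabet(), sprintf("tau%03d", seq_len(2 * params$apaac_lambda))),
    total_aa_property = c("hydrophobicity", "charge", "polarity"),
    as.character(seq_len(length)))
  if (block %in% profile_scale_names()) inner <- c(aa_alphabet(), "mean")
  paste(block, inner, sep = ".")
}

all_feature_colnames <- function(cfg, params = feature_params()) {
  unlist(lapply(seq_len(nrow(cfg)), function(i) {
    block_colnames(cfg$block[i], cfg$length[i], params)
  }), use.names = FALSE)
}

compute_block <- function(block, seq, params) {
  scales <- aa_scales()
  switch(block,
    sequence_length = nchar(seq),
    mass = protein_mass(seq),
    aac = aac(seq),
    dpc = dpc(seq),
    moreau_broto = autocorrelation(seq, maxlag = params$ac_maxlag,
                                   kind = "moreau_broto"),
    moran = autocorrelation(seq, maxlag = params$ac_maxlag, kind = "moran"),
    geary = autocorrelation(seq, maxlag = params$ac_maxlag, kind = "geary"),
    qso = qso(seq, maxlag = params$qso_maxlag, weight = params$qso_weight),
    paac = paac(seq, lambda = params$paac_lambda,
                weight = params$paac_weight),
    apaac = apaac(seq, lambda = params$apaac_lambda,
                  weight = params$apaac_weight),
    total_aa_property = total_aa_property(seq),
    isoelectric_point = isoelectric_point(seq),
    property_profile(seq, scales[[block]]))
}

#' Ingest predictor-derived feature columns
#'
#' Copies externally computed feature values (signal peptide,
#' transmembrane, glycosylation, disorder, secondary structure, ...) into
#' the matching external blocks.  Column names must follow the block
#' naming contract (`block` for one-dimension blocks,
#' `block.1 ... block.k` otherwise); unknown columns are an error.
#' Proteins absent from the table keep `NA` in every external dimension.
#'
#' @param table Tibble with a `protein_id` column plus external feature
#'   columns.
#' @param cfg Feature configuration (default full configuration).
#' @return The validated table (invisibly usable with
#'   [build_feature_matrix()]'s `external` argument).
#' @export
ingest_external_features <- function(table, cfg = feature_config()) {
  stopifnot("protein_id" %in% names(table))
  if (anyDuplicated(table$protein_id)) stop("duplicate protein ids")
  ext <- cfg[cfg$source == "external", ]
  allowed <- all_feature_colnames(ext)
  unknown <- setdiff(setdiff(names(table), "protein_id"), allowed)
  if (length(unknown) > 0) {
    stop("unknown external feature column(s): ",
         paste(unknown, collapse = ", "))
  }
  table
}

#' Build the protein feature matrix
#'
#' Computes every configured sequence-derived block for each protein and
#' merges in externally supplied predictor columns.  Per-protein
#' infeasible blocks (sequence shorter than a lag or tier) are `NA`, never
#' silently zero.  The default configuration yields 52 blocks and 1610
#' feature columns.
#'
#' @param records Tibble with columns `id` and `sequence` (raw sequences
#'   are sanitized with `policy`).
#' @param cfg Feature configuration from [feature_config()].
#' @param external Optional external feature table, see
#'   [ingest_external_features()].
#' @param params Descriptor parameters matching `cfg`.
#' @param policy Sanitization policy, see [sanitize_sequence()].
#' @return Tibble with `protein_id` plus one column per feature dimension.
#' @export
build_feature_matrix <- function(records, cfg = feature_config(),
                                 external = NULL,
                                 params = feature_params(),
                                 policy = "strip") {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate protein ids in records")
  seqs <- vapply(records$sequence, sanitize_sequence, character(1),
                 policy = policy, USE.NAMES = FALSE)
  comp <- cfg[cfg$source == "computed", ]
  ext <- cfg[cfg$source == "external", ]
  comp_cols <- all_feature_colnames(comp, params)
  rows <- vapply(seqs, function(s) {
    unlist(lapply(seq_len(nrow(comp)), function(i) {
      compute_block(comp$block[i], s, params)
    }), use.names = FALSE)
  }, numeric(length(comp_cols)))
  mat <- t(matrix(rows, nrow = length(comp_cols)))
  colnames(mat) <- comp_cols
  out <- tibble::as_tibble(mat)
  if (nrow(ext) > 0) {
    ext_cols <- all_feature_colnames(ext, params)
    ext_mat <- matrix(NA_real_, nrow = length(seqs), ncol = length(ext_cols),
                      dimnames = list(NULL, ext_cols))
    if (!is.null(external)) {
      external <- ingest_external_features(external, cfg)
      hit <- match(external$protein_id, records$id)
      keep <- !is.na(hit)
      for (cl in setdiff(names(external), "protein_id")) {
        ext_mat[hit[keep], cl] <- as.numeric(external[[cl]])[keep]
      }
    }
    out <- dplyr::bind_cols(out, tibble::as_tibble(ext_mat))
  }
  # restore configured block order
  out <- out[, all_feature_colnames(cfg, params)]
  dplyr::bind_cols(tibble::tibble(protein_id = records$id), out)
}
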