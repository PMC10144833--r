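# Synthetic fixtures with the statistical structure the method assumes:
# PU-labeled sequence sets with hidden positives, labeled Gaussian feature
# tables, and expression matrices with planted fold changes.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a positive-unlabeled sequence dataset
#'
#' Positive and negative sequences differ in residue composition: the two
#' class distributions tilt a uniform base composition by
#' `exp(+/- composition_shift)` over a fixed alternating residue pattern,
#' and each sequence draws its own composition from a Dirichlet around
#' its class distribution.  A fraction of the unlabeled pool consists of
#' hidden positives (drawn from the positive distribution but labeled
#' unknown), which is the contamination structure positive-unlabeled
#' learning assumes.  The latent truth of every unlabeled sequence is
#' returned.
#'
#' @param n_pos,n_unlabeled Pool sizes (defaults 300 / 600).
#' @param hidden_positive_fraction Fraction of the unlabeled pool drawn
#'   from the positive distribution (default 0.2).
#' @param length_range Inclusive sequence-length range (default 50-300),
#'   uniform.
#' @param composition_shift Log-scale tilt separating the classes
#'   (default 0.5; 0 makes the classes indistinguishable).
#' @param seed RNG seed.
#' @return List: `records` (tibble `id`, `sequence`), `positive_ids`,
#'   `unlabeled_ids`, `truth` (tibble `id`, `latent_positive` for the
#'   unlabeled pool).
#' @export
gen_pu_sequences <- function(n_pos = 300, n_unlabeled = 600,
                             hidden_positive_fraction = 0.2,
                             length_range = c(50, 300),
                             composition_shift = 0.5, seed = 1) {
  stopifnot(n_pos > 0, n_unlabeled > 0,
            hidden_positive_fraction >= 0, hidden_positive_fraction < 1,
            length_range[1] >= 2, length_range[2] >= length_range[1])
  set.seed(seed)
  tilt <- rep(c(1, -1), 10)
  base <- rep(1 / 20, 20)
  f_pos <- base * exp(composition_shift * tilt)
  f_pos <- f_pos / sum(f_pos)
  f_neg <- base * exp(-composition_shift * tilt)
  f_neg <- f_neg / sum(f_neg)
  draw <- function(class_freq) {
    comp <- rdirichlet1(100 * class_freq)
    len <- sample(length_range[1]:length_range[2], 1)
    paste(sample(aa_alphabet(), len, replace = TRUE, prob = comp),
          collapse = "")
  }
  n_hidden <- round(hidden_positive_fraction * n_unlabeled)
  pos_seqs <- replicate(n_pos, draw(f_pos))
  hidden_seqs <- if (n_hidden > 0) replicate(n_hidden, draw(f_pos)) else character(0)
  neg_seqs <- replicate(n_unlabeled - n_hidden, draw(f_neg))
  pos_ids <- sprintf("POS%04d", seq_len(n_pos))
  unl_ids <- sprintf("UNL%04d", seq_len(n_unlabeled))
  latent <- c(rep(TRUE, n_hidden), rep(FALSE, n_unlabeled - n_hidden))
  # shuffle hidden positives through the unlabeled pool
  ord <- sample.int(n_unlabeled)
  unl_seqs <- c(hidden_seqs, neg_seqs)[ord]
  latent <- latent[ord]
  list(records = tibble::tibble(id = c(pos_ids, unl_ids),
                                sequence = c(pos_seqs, unl_seqs)),
       positive_ids = pos_ids,
       unlabeled_ids = unl_ids,
       truth = tibble::tibble(id = unl_ids, latent_positive = latent))
}

#' Generate a labeled Gaussian feature table
#'
#' Informative columns are mean-shifted by `effect_size` in the positive
#' class; noise columns are standard normal in both classes.
#'
#' @param n_pos,n_neg Class sizes (defaults 500 / 500).
#' @param n_informative,n_noise Column counts (defaults 50 / 450).
#' @param effect_size Mean shift of informative columns (default 1).
#' @param seed RNG seed.
#' @return List: `features` (tibble `protein_id` + columns
#'   `inf001...`/`noise001...`), `labels` (logical), `informative`
#'   (column names carrying signal).
#' @export
gen_feature_table <- function(n_pos = 500, n_neg = 500, n_informative = 50,
                              n_noise = 450, effect_size = 1, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  inf <- matrix(stats::rnorm(n * n_informative), nrow = n)
  inf[labels, ] <- inf[labels, ] + effect_size
  noise <- matrix(stats::rnorm(n * n_noise), nrow = n)
  inf_names <- sprintf("inf%03d", seq_len(n_informative))
  noise_names <- sprintf("noise%03d", seq_len(n_noise))
  m <- cbind(inf, noise)
  colnames(m) <- c(inf_names, noise_names)
  list(features = dplyr::bind_cols(
         tibble::tibble(protein_id = sprintf("P%04d", seq_len(n))),
         tibble::as_tibble(m)),
       labels = labels,
       informative = inf_names)
}

#' Generate an expression matrix with planted fold changes
#'
#' Baseline expression is log-normal per gene; planted up / down genes
#' are scaled by `effect_fc` / `1 / effect_fc` in the case group.  An
#' identity gene-to-protein mapping is returned for downstream biomarker
#' tests.
#'
#' @param n_genes,n_case,n_control Matrix dimensions (defaults 1000 /
#'   40 / 40).
#' @param n_up,n_down Planted gene counts (defaults 50 / 50, disjoint).
#' @param effect_fc Planted fold change > 1 (default 4).
#' @param noise_sd Log-scale noise standard deviation (default 0.5).
#' @param seed RNG seed.
#' @return List: `expr` (tibble `gene_id` + sample columns), `groups`
#'   (tibble `sample_id`, `group`), `truth` (tibble `gene_id`,
#'   `planted`), `mapping` (tibble `gene_id`, `protein_id`).
#' @export
gen_expression <- function(n_genes = 1000, n_case = 40, n_control = 40,
                           n_up = 50, n_down = 50, effect_fc = 4,
                           noise_sd = 0.5, seed = 1) {
  stopifnot(n_up + n_down <= n_genes, effect_fc > 1, noise_sd > 0)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- c(sprintf("case%03d", seq_len(n_case)),
               sprintf("ctrl%03d", seq_len(n_control)))
  grp <- c(rep("case", n_case), rep("control", n_control))
  mu <- stats::rnorm(n_genes, mean = 1.5, sd = 1)
  m <- exp(matrix(stats::rnorm(n_genes * length(samples), mean = mu,
                               sd = noise_sd), nrow = n_genes))
  up_idx <- seq_len(n_up)
  down_idx <- n_up + seq_len(n_down)
  m[up_idx, grp == "case"] <- m[up_idx, grp == "case"] * effect_fc
  m[down_idx, grp == "case"] <- m[down_idx, grp == "case"] / effect_fc
  colnames(m) <- samples
  planted <- rep("null", n_genes)
  planted[up_idx] <- "up"
  planted[down_idx] <- "down"
  list(expr = dplyr::bind_cols(tibble::tibble(gene_id = genes),
                               tibble::as_tibble(m)),
       groups = tibble::tibble(sample_id = samples, group = grp),
       truth = tibble::tibble(gene_id = genes, planted = planted),
       mapping = tibble::tibble(gene_id = genes,
                                protein_id = sub("^G", "PROT", genes)))
}
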