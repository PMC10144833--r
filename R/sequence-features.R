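# Sequence-derived protein descriptors: composition, dipeptides,
# autocorrelation, quasi-sequence-order, (amphiphilic) pseudo-amino-acid
# composition, physicochemical profiles and simple scalars.

seq_index <- function(seq) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], aa_alphabet())
  if (anyNA(idx)) stop("sequence contains non-standard letters; sanitize first")
  idx
}

#' Sanitize a raw amino-acid sequence
#'
#' Uppercases and restricts to the 20 standard letters.  Non-standard
#' letters (B, J, O, U, X, Z and anything else) are removed with a warning
#' under `policy = "strip"`, or raise an error under `policy = "reject"`.
#'
#' @param raw Character scalar, the raw sequence.
#' @param policy `"strip"` (default) or `"reject"`.
#' @return Sanitized sequence string.
#' @export
sanitize_sequence <- function(raw, policy = c("strip", "reject")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1 || !nzchar(raw)) {
    stop("raw sequence must be a non-empty character scalar")
  }
  s <- toupper(gsub("[[:space:]*]", "", raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% aa_alphabet())
  if (any(bad)) {
    if (policy == "reject") {
      stop("non-standard letters in sequence: ",
           paste(unique(chars[bad]), collapse = ", "))
    }
    warning("removed ", sum(bad), " non-standard letter(s) from sequence")
    chars <- chars[!bad]
  }
  if (length(chars) == 0) stop("sequence empty after sanitization")
  paste(chars, collapse = "")
}

#' Amino-acid composition
#'
#' @param seq Sanitized sequence.
#' @return Named 20-vector of residue fractions (sums to 1).
#' @export
aac <- function(seq) {
  idx <- seq_index(seq)
  stats::setNames(tabulate(idx, 20) / length(idx), aa_alphabet())
}

dpc_names <- function() {
  as.vector(t(outer(aa_alphabet(), aa_alphabet(), paste0)))
}

#' Dipeptide composition
#'
#' Frequencies of the 400 ordered adjacent residue pairs, normalized by the
#' number of pairs (length - 1).  Sequences of length 1 have no pairs and
#' yield an all-`NA` block.
#'
#' @param seq Sanitized sequence.
#' @return Named 400-vector summing to 1, or all `NA` when length < 2.
#' @export
dpc <- function(seq) {
  idx <- seq_index(seq)
  nm <- dpc_names()
  n <- length(idx)
  if (n < 2) return(stats::setNames(rep(NA_real_, 400), nm))
  pair <- (idx[-n] - 1L) * 20L + idx[-1L]
  stats::setNames(tabulate(pair, 400) / (n - 1), nm)
}

#' Property autocorrelation descriptors
#'
#' Normalized Moreau-Broto, Moran or Geary autocorrelation of z-normalized
#' physicochemical properties along the sequence, one value per
#' (scale, lag).  Lags with no feasible residue pair are `NA`.  Zero
#' property variance along the sequence yields 0 for Moran and Geary.
#'
#' @param seq Sanitized sequence.
#' @param scales Named list of property scales (defaults to the classic
#'   hydrophobicity / polarity / polarizability trio).
#' @param maxlag Largest lag (default 30).
#' @param kind One of `"moreau_broto"`, `"moran"`, `"geary"`.
#' @return Named vector of length `length(scales) * maxlag`.
#' @export
autocorrelation <- function(seq, scales = default_ac_scales(), maxlag = 30,
                            kind = c("moreau_broto", "moran", "geary")) {
  kind <- match.arg(kind)
  idx <- seq_index(seq)
  L <- length(idx)
  out <- numeric(0)
  for (nm in names(scales)) {
    z <- normalize_scale(scales[[nm]])
    p <- z[idx]
    pbar <- mean(p)
    centered <- p - pbar
    denom_moran <- mean(centered^2)
    denom_geary <- if (L > 1) sum(centered^2) / (L - 1) else 0
    vals <- vapply(seq_len(maxlag), function(d) {
      if (L <= d) return(NA_real_)
      a <- p[seq_len(L - d)]
      b <- p[seq.int(d + 1L, L)]
      switch(kind,
        moreau_broto = sum(a * b) / (L - d),
        moran = {
          if (denom_moran == 0) 0 else
            (sum((a - pbar) * (b - pbar)) / (L - d)) / denom_moran
        },
        geary = {
          if (denom_geary == 0) 0 else
            (sum((a - b)^2) / (2 * (L - d))) / denom_geary
        })
    }, numeric(1))
    names(vals) <- sprintf("%s.lag%02d", nm, seq_len(maxlag))
    out <- c(out, vals)
  }
  out
}

#' Default autocorrelation property trio
#' @return Named list of three scales.
#' @export
default_ac_scales <- function() {
  sc <- aa_scales()
  sc[c("hydrophobicity", "polarity", "polarizability")]
}

default_qso_matrices <- function() {
  list(grantham = grantham_distance_matrix(),
       physchem = physchem_distance_matrix())
}

#' Quasi-sequence-order descriptors
#'
#' Per distance matrix: 20 composition-derived terms plus `maxlag`
#' sequence-order-coupling terms \eqn{\tau_d = \sum_i d(R_i, R_{i+d})^2},
#' all sharing the denominator \eqn{\sum_a f_a + w \sum_d \tau_d}.  The
#' default two matrices and `maxlag = 60` give 160 dimensions.
#'
#' @param seq Sanitized sequence.
#' @param maxlag Largest coupling rank (default 60).
#' @param weight Coupling weight `w` (default 0.1).
#' @param matrices Named list of 20 x 20 residue-distance matrices.
#' @return Named vector of length `length(matrices) * (20 + maxlag)`; all
#'   `NA` when the sequence is not longer than `maxlag`.
#' @export
qso <- function(seq, maxlag = 60, weight = 0.1,
                matrices = default_qso_matrices()) {
  idx <- seq_index(seq)
  L <- length(idx)
  nm_all <- unlist(lapply(names(matrices), function(mn) {
    c(paste0(mn, ".", aa_alphabet()), sprintf("%s.tau%02d", mn, seq_len(maxlag)))
  }))
  if (L <= maxlag) {
    return(stats::setNames(rep(NA_real_, length(nm_all)), nm_all))
  }
  f <- tabulate(idx, 20) / L
  out <- numeric(0)
  for (mn in names(matrices)) {
    M2 <- matrices[[mn]][aa_alphabet(), aa_alphabet()]^2
    tau <- vapply(seq_len(maxlag), function(d) {
      a <- idx[seq_len(L - d)]
      b <- idx[seq.int(d + 1L, L)]
      sum(M2[(b - 1L) * 20L + a])
    }, numeric(1))
    denom <- sum(f) + weight * sum(tau)
    vals <- c(f / denom, weight * tau / denom)
    out <- c(out, vals)
  }
  stats::setNames(out, nm_all)
}

default_paac_scales <- function() {
  sc <- aa_scales()
  sc[c("hydrophobicity", "hydrophilicity", "side_chain_mass")]
}

.theta_corr <- function(zs, a, b) {
  # mean squared difference of normalized properties between two residues
  mean(vapply(zs, function(z) (z[a] - z[b])^2, numeric(1)))
}

#' Type-1 pseudo-amino-acid composition
#'
#' First 20 entries are composition terms, the last `lambda` entries are
#' tiered sequence-order factors
#' \eqn{\theta_k = \frac{1}{L-k}\sum_i \Theta(R_i, R_{i+k})} with
#' \eqn{\Theta} the mean squared difference of the z-normalized property
#' scales.  All entries share the denominator \eqn{1 + w\sum_k\theta_k}
#' and sum to 1.
#'
#' @param seq Sanitized sequence.
#' @param lambda Number of sequence-order tiers (default 130).
#' @param weight Tier weight (default 0.05).
#' @param scales Named list of property scales (default hydrophobicity,
#'   hydrophilicity, side-chain mass).
#' @return Named vector of length `20 + lambda`; all `NA` when the sequence
#'   is not longer than `lambda`.
#' @export
paac <- function(seq, lambda = 130, weight = 0.05,
                 scales = default_paac_scales()) {
  idx <- seq_index(seq)
  L <- length(idx)
  nm <- c(aa_alphabet(), sprintf("lam%03d", seq_len(lambda)))
  if (L <= lambda) return(stats::setNames(rep(NA_real_, 20 + lambda), nm))
  zs <- lapply(scales, normalize_scale)
  # pair correlation depends only on the residue pair: precompute 20 x 20
  TH <- Reduce(`+`, lapply(zs, function(z) outer(z, z, "-")^2)) / length(zs)
  f <- tabulate(idx, 20) / L
  theta <- vapply(seq_len(lambda), function(k) {
    a <- idx[seq_len(L - k)]
    b <- idx[seq.int(k + 1L, L)]
    mean(TH[(b - 1L) * 20L + a])
  }, numeric(1))
  denom <- sum(f) + weight * sum(theta)
  stats::setNames(c(f / denom, weight * theta / denom), nm)
}

#' Amphiphilic pseudo-amino-acid composition
#'
#' As [paac()] but with separate hydrophobicity and hydrophilicity
#' correlation factors \eqn{\tau_{2k-1}, \tau_{2k}}, giving
#' `20 + 2 * lambda` dimensions (80 at the default `lambda = 30`).
#'
#' @inheritParams paac
#' @param scales Named list of exactly two scales (hydrophobicity,
#'   hydrophilicity).
#' @return Named vector of length `20 + 2 * lambda`.
#' @export
apaac <- function(seq, lambda = 30, weight = 0.05,
                  scales = default_paac_scales()[1:2]) {
  stopifnot(length(scales) == 2)
  idx <- seq_index(seq)
  L <- length(idx)
  nm <- c(aa_alphabet(), sprintf("tau%03d", seq_len(2 * lambda)))
  if (L <= lambda) return(stats::setNames(rep(NA_real_, 20 + 2 * lambda), nm))
  z1 <- normalize_scale(scales[[1]])
  z2 <- normalize_scale(scales[[2]])
  P1 <- outer(z1, z1)
  P2 <- outer(z2, z2)
  f <- tabulate(idx, 20) / L
  tau <- numeric(2 * lambda)
  for (k in seq_len(lambda)) {
    a <- idx[seq_len(L - k)]
    b <- idx[seq.int(k + 1L, L)]
    flat <- (b - 1L) * 20L + a
    tau[2 * k - 1] <- sum(P1[flat]) / (L - k)
    tau[2 * k] <- sum(P2[flat]) / (L - k)
  }
  denom <- sum(f) + weight * sum(tau)
  stats::setNames(c(f / denom, weight * tau / denom), nm)
}

#' 21-dimension physicochemical profile
#'
#' Entries 1-20 are the amino-acid composition weighted by the scale value
#' of each residue type; entry 21 is the mean scale value over the
#' sequence.
#'
#' @param seq Sanitized sequence.
#' @param scale Named 20-value property scale.
#' @return Named 21-vector (`A` ... `Y`, `mean`).
#' @export
property_profile <- function(seq, scale) {
  scale <- scale[aa_alphabet()]
  idx <- seq_index(seq)
  f <- tabulate(idx, 20) / length(idx)
  stats::setNames(c(f * scale, mean(scale[idx])), c(aa_alphabet(), "mean"))
}

#' Average protein mass
#'
#' Sum of average residue masses plus one water mass.
#'
#' @param seq Sanitized sequence.
#' @return Mass in Daltons.
#' @export
protein_mass <- function(seq) {
  sum(residue_masses()[seq_index(seq)]) + water_mass()
}

# standard side-chain / terminus pKa values
.pka <- list(nterm = 9.69, cterm = 2.34,
             pos = c(K = 10.53, R = 12.48, H = 6.00),
             neg = c(D = 3.65, E = 4.25, C = 8.30, Y = 10.07))

net_charge_at_ph <- function(counts, ph) {
  pos <- 1 / (1 + 10^(ph - .pka$nterm)) +
    sum(counts[names(.pka$pos)] / (1 + 10^(ph - .pka$pos)))
  neg <- 1 / (1 + 10^(.pka$cterm - ph)) +
    sum(counts[names(.pka$neg)] / (1 + 10^(.pka$neg - ph)))
  pos - neg
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the chain (standard
#' side-chain and terminus pKa set) is zero, solved by bisection.
#'
#' @param seq Sanitized sequence.
#' @return Estimated pI.
#' @export
isoelectric_point <- function(seq) {
  idx <- seq_index(seq)
  counts <- stats::setNames(tabulate(idx, 20), aa_alphabet())
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Total amino-acid property sums
#'
#' Sequence sums of the hydrophobicity, charge and polarity scales.
#'
#' @param seq Sanitized sequence.
#' @return Named 3-vector.
#' @export
total_aa_property <- function(seq) {
  idx <- seq_index(seq)
  sc <- aa_scales()
  vapply(c("hydrophobicity", "charge", "polarity"),
         function(nm) sum(sc[[nm]][idx]), numeric(1))
}
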