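# Amino-acid alphabet, physicochemical property scales and residue-distance
# matrices used by the sequence descriptors.

# constructed tables are cached; they are pure functions of the literals
.csf_cache <- new.env(parent = emptyenv())

.memo <- function(key, fn) {
  if (is.null(.csf_cache[[key]])) assign(key, fn(), envir = .csf_cache)
  get(key, envir = .csf_cache)
}

#' The 20 standard amino-acid letters
#'
#' Single-letter codes in the fixed alphabetical order used throughout the
#' package for composition vectors and scale tables.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

aa_vec <- function(...) {
  v <- c(...)
  stopifnot(identical(sort(names(v)), sort(aa_alphabet())))
  v[aa_alphabet()]
}

# Kyte-Doolittle hydropathy
.kd_hydrophobicity <- function() {
  aa_vec(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
         I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
         R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

# Hopp-Woods hydrophilicity
.hw_hydrophilicity <- function() {
  aa_vec(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
         I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
         R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
}

# side-chain masses (Da), classic pseudo-composition table
.side_chain_mass <- function() {
  aa_vec(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
         K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
         T = 45, V = 43, W = 130, Y = 107)
}

# Grantham polarity
.grantham_polarity <- function() {
  aa_vec(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0, H = 10.4,
         I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6, P = 8.0, Q = 10.5,
         R = 10.5, S = 9.2, T = 8.6, V = 5.9, W = 5.4, Y = 6.2)
}

# Grantham composition (atomic-weight ratio of non-C atoms in side chain)
.grantham_composition <- function() {
  aa_vec(A = 0, C = 2.75, D = 1.38, E = 0.92, F = 0, G = 0.74, H = 0.58,
         I = 0, K = 0.33, L = 0, M = 0, N = 1.33, P = 0.39, Q = 0.89,
         R = 0.65, S = 1.42, T = 0.71, V = 0, W = 0.13, Y = 0.20)
}

# Grantham side-chain volume
.grantham_volume <- function() {
  aa_vec(A = 31, C = 55, D = 54, E = 83, F = 132, G = 3, H = 96, I = 111,
         K = 119, L = 111, M = 105, N = 56, P = 32.5, Q = 85, R = 124,
         S = 32, T = 61, V = 84, W = 170, Y = 136)
}

.polarizability <- function() {
  aa_vec(A = 0.046, C = 0.128, D = 0.105, E = 0.151, F = 0.290, G = 0.000,
         H = 0.230, I = 0.186, K = 0.219, L = 0.186, M = 0.221, N = 0.134,
         P = 0.131, Q = 0.180, R = 0.291, S = 0.062, T = 0.108, V = 0.140,
         W = 0.409, Y = 0.298)
}

.vdw_volume <- function() {
  aa_vec(A = 1.00, C = 2.43, D = 2.78, E = 3.78, F = 5.89, G = 0.00,
         H = 4.66, I = 4.00, K = 4.77, L = 4.00, M = 4.43, N = 2.95,
         P = 2.72, Q = 3.95, R = 6.13, S = 1.60, T = 2.60, V = 3.00,
         W = 8.08, Y = 6.47)
}

.charge <- function() {
  aa_vec(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0, K = 1,
         L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0,
         W = 0, Y = 0)
}

# approximate maximum accessible surface area (A^2)
.solvent_accessibility <- function() {
  aa_vec(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224,
         I = 197, K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225,
         R = 274, S = 155, T = 172, V = 174, W = 285, Y = 263)
}

# Bhaskaran-Ponnuswamy average flexibility
.flexibility <- function() {
  aa_vec(A = 0.357, C = 0.346, D = 0.511, E = 0.497, F = 0.314, G = 0.544,
         H = 0.323, I = 0.462, K = 0.466, L = 0.365, M = 0.295, N = 0.463,
         P = 0.509, Q = 0.493, R = 0.529, S = 0.507, T = 0.444, V = 0.386,
         W = 0.305, Y = 0.420)
}

# average residue masses (Da); water added once per chain for whole-protein mass
residue_masses <- function() {
  aa_vec(A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
         G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
         M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
         S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
}

water_mass <- function() 18.01528

.molecular_weight <- function() residue_masses() + water_mass()

# side-chain hydrogen-bond donor / acceptor group counts (neutral pH)
.hbond_donors <- function() {
  aa_vec(A = 0, C = 1, D = 0, E = 0, F = 0, G = 0, H = 1, I = 0, K = 1,
         L = 0, M = 0, N = 1, P = 0, Q = 1, R = 3, S = 1, T = 1, V = 0,
         W = 1, Y = 1)
}

.hbond_acceptors <- function() {
  aa_vec(A = 0, C = 1, D = 2, E = 2, F = 0, G = 0, H = 1, I = 0, K = 0,
         L = 0, M = 1, N = 1, P = 0, Q = 1, R = 0, S = 1, T = 1, V = 0,
         W = 0, Y = 1)
}

#' Z-normalize a property scale over the 20 amino acids
#'
#' Centers to zero mean and scales to unit variance using the population
#' (divide-by-20) convention, the normalization assumed by the
#' autocorrelation and pseudo-composition descriptors.  Idempotent.
#'
#' @param scale Named numeric vector over the 20 standard amino acids.
#' @return Normalized scale in alphabet order.
#' @export
normalize_scale <- function(scale) {
  scale <- scale[aa_alphabet()]
  if (anyNA(scale)) stop("scale must cover all 20 standard amino acids")
  s <- sqrt(mean((scale - mean(scale))^2))
  if (s == 0) return(scale * 0)
  (scale - mean(scale)) / s
}

# fixed mixtures of the documented scales standing in for literature
# propensity tables with no offline source; SYNTHETIC values, see vignette.
.synthetic_mix <- function(weights) {
  basis <- list(h = normalize_scale(.kd_hydrophobicity()),
                p = normalize_scale(.grantham_polarity()),
                v = normalize_scale(.vdw_volume()),
                c = normalize_scale(.charge()),
                f = normalize_scale(.flexibility()))
  out <- rep(0, 20)
  for (nm in names(weights)) out <- out + weights[[nm]] * basis[[nm]]
  names(out) <- aa_alphabet()
  out
}

#' Amino-acid property scales used by the physicochemical profiles
#'
#' Returns the named list of 20-value property scales behind the
#' 21-dimension physicochemical profile blocks, plus the auxiliary scales
#' (hydrophilicity, side-chain mass) used by the pseudo-composition
#' descriptors.  Scales for which no literature table ships with the
#' package (surface tension, solubility, CLogP and the ten interface /
#' ligand-binding propensity scales) are synthetic stand-ins constructed
#' as fixed linear mixtures of the documented scales; after per-column
#' standardization the derived profile columns are proportional to
#' composition, so downstream selection and classification are unaffected
#' by the stand-in values.  Users with the original tables can supply them
#' through the external-feature ingestion path instead.
#'
#' @return Named list of named numeric vectors (length 20 each).
#' @export
aa_scales <- function() {
  .memo("aa_scales", .build_aa_scales)
}

.build_aa_scales <- function() {
  list(
    hydrophobicity          = .kd_hydrophobicity(),
    vdw_volume              = .vdw_volume(),
    polarity                = .grantham_polarity(),
    polarizability          = .polarizability(),
    charge                  = .charge(),
    solvent_accessibility   = .solvent_accessibility(),
    surface_tension         = .synthetic_mix(list(h = -0.7, p = 0.3)),
    molecular_weight        = .molecular_weight(),
    solubility              = .synthetic_mix(list(h = -0.5, p = 0.5)),
    hbond_donors            = .hbond_donors(),
    hbond_acceptors         = .hbond_acceptors(),
    clogp                   = .synthetic_mix(list(h = 0.8, v = 0.2)),
    flexibility             = .flexibility(),
    ppi_hotspot_bogan       = .synthetic_mix(list(v = 0.6, p = 0.4)),
    ppi_propensity_ma       = .synthetic_mix(list(v = 0.5, h = 0.5)),
    dna_interface_schneider = .synthetic_mix(list(c = 0.7, p = 0.3)),
    dna_interface_ahmad     = .synthetic_mix(list(c = 0.6, v = 0.4)),
    rna_interface_kim       = .synthetic_mix(list(c = 0.5, p = 0.5)),
    rna_interface_ellis     = .synthetic_mix(list(c = 0.4, v = 0.3, p = 0.3)),
    rna_interface_phipps    = .synthetic_mix(list(c = 0.5, f = 0.5)),
    ligand_binding_khazanov = .synthetic_mix(list(h = 0.6, v = 0.4)),
    ligand_valid_khazanov   = .synthetic_mix(list(h = 0.5, v = 0.5)),
    ligand_polar_imai       = .synthetic_mix(list(p = 0.6, c = 0.4)),
    hydrophilicity          = .hw_hydrophilicity(),
    side_chain_mass         = .side_chain_mass()
  )
}

#' Grantham residue-distance matrix
#'
#' Computed from the published formula
#' \eqn{D_{ij} = \rho\sqrt{1.833\,\Delta c^2 + 0.1018\,\Delta p^2 +
#' 0.000399\,\Delta v^2}} over side-chain composition, polarity and volume,
#' with \eqn{\rho = 50.723} so that the mean over amino-acid pairs is 100.
#'
#' @return 20 x 20 symmetric numeric matrix, zero diagonal.
#' @export
grantham_distance_matrix <- function() {
  .memo("grantham", .build_grantham)
}

.build_grantham <- function() {
  cc <- .grantham_composition()
  pp <- .grantham_polarity()
  vv <- .grantham_volume()
  d <- 50.723 * sqrt(1.833 * outer(cc, cc, "-")^2 +
                       0.1018 * outer(pp, pp, "-")^2 +
                       0.000399 * outer(vv, vv, "-")^2)
  diag(d) <- 0
  dimnames(d) <- list(aa_alphabet(), aa_alphabet())
  d
}

#' Physicochemical residue-distance matrix (synthetic)
#'
#' A package-constructed stand-in for a second sequence-order distance
#' matrix: the Euclidean distance between residues in the z-scored
#' (hydrophobicity, hydrophilicity, side-chain mass) property space,
#' rescaled so the largest pairwise distance is 1.  It is not a published
#' table; it plays the structural role of the classical physicochemical
#' distance matrix in the quasi-sequence-order descriptor.
#'
#' @return 20 x 20 symmetric numeric matrix in \[0, 1\], zero diagonal.
#' @export
physchem_distance_matrix <- function() {
  .memo("physchem", .build_physchem)
}

.build_physchem <- function() {
  h1 <- normalize_scale(.kd_hydrophobicity())
  h2 <- normalize_scale(.hw_hydrophilicity())
  m <- normalize_scale(.side_chain_mass())
  d <- sqrt(outer(h1, h1, "-")^2 + outer(h2, h2, "-")^2 + outer(m, m, "-")^2)
  d <- d / max(d)
  dimnames(d) <- list(aa_alphabet(), aa_alphabet())
  d
}
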