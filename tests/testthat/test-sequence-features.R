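test_that("sanitization uppercases, strips or rejects non-standard letters", {
  expect_equal(sanitize_sequence("acdE"), "ACDE")
  expect_warning(s <- sanitize_sequence("ACXDE", policy = "strip"))
  expect_equal(s, "ACDE")
  expect_error(sanitize_sequence("ACXDE", policy = "reject"), "non-standard")
  expect_error(suppressWarnings(sanitize_sequence("XXX", policy = "strip")),
               "empty")
  expect_error(sanitize_sequence(""), "non-empty")
})

test_that("amino-acid composition gives fractions that sum to one", {
  a <- aac("AAAA")
  expect_equal(a[["A"]], 1)
  expect_equal(sum(a), 1)
  a <- aac("ACAC")
  expect_equal(a[["A"]], 0.5)
  expect_equal(a[["C"]], 0.5)
  expect_equal(sum(aac(random_seq(200, seed = 11))), 1, tolerance = 1e-12)
})

test_that("dipeptide composition counts adjacent pairs over length-1", {
  d <- dpc("ACAC")
  expect_equal(d[["AC"]], 2 / 3)
  expect_equal(d[["CA"]], 1 / 3)
  expect_equal(sum(d), 1)
  expect_equal(dpc("AA")[["AA"]], 1)
  expect_true(all(is.na(dpc("A"))))
  expect_equal(sum(dpc(random_seq(150, seed = 3))), 1, tolerance = 1e-12)
})

test_that("autocorrelation matches a direct-summation oracle", {
  seq <- "ACDEFGHIKLMNPQRSTVWY"
  sc <- aa_scales()["hydrophobicity"]
  for (kind in c("moreau_broto", "moran", "geary")) {
    got <- autocorrelation(seq, scales = sc, maxlag = 5, kind = kind)
    for (d in 1:5) {
      expect_equal(got[[sprintf("hydrophobicity.lag%02d", d)]],
                   oracle_ac(seq, sc[[1]], d, kind), tolerance = 1e-12,
                   info = paste(kind, d))
    }
  }
})

test_that("autocorrelation has the configured length and flags infeasible lags", {
  v <- autocorrelation(random_seq(60, seed = 5), maxlag = 30)
  expect_length(v, 90)
  expect_false(anyNA(v))
  # constant-property sequence: zero variance handled as 0
  expect_true(all(autocorrelation("AAAAAAAAAA", maxlag = 3,
                                  kind = "moran") == 0))
  expect_true(all(autocorrelation("AAAAAAAAAA", maxlag = 3,
                                  kind = "geary") == 0))
  # lags not shorter than the sequence are missing
  short <- autocorrelation("ACDEF", maxlag = 6)
  expect_true(all(is.na(short[grepl("lag0[5-6]", names(short))])))
  expect_false(anyNA(short[grepl("lag0[1-4]", names(short))]))
})

test_that("quasi-sequence-order matches a double-loop oracle and Table lengths", {
  expect_length(qso(random_seq(80, seed = 7)), 160)
  seq <- random_seq(25, seed = 8)
  mats <- list(grantham = grantham_distance_matrix(),
               physchem = physchem_distance_matrix())
  got <- qso(seq, maxlag = 2, weight = 0.1, matrices = mats)
  want <- c(oracle_qso_one(seq, mats$grantham, 2, 0.1),
            oracle_qso_one(seq, mats$physchem, 2, 0.1))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  # homopolymer: all coupling terms are zero because d(A, A) = 0
  homo <- qso(strrep("A", 100), maxlag = 60)
  expect_true(all(homo[grepl("tau", names(homo))] == 0))
  # short sequences flagged missing
  expect_true(all(is.na(qso(random_seq(30, seed = 9), maxlag = 60))))
})

test_that("pseudo-amino-acid composition matches oracle, sums to one, honors weight", {
  expect_length(paac(random_seq(200, seed = 10)), 150)
  seq <- random_seq(10, seed = 12)
  got <- paac(seq, lambda = 2, weight = 0.05)
  want <- oracle_paac(seq, 2, 0.05, default_paac_scales())
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)
  # weight 0 collapses to plain composition
  w0 <- paac(seq, lambda = 2, weight = 0)
  expect_equal(unname(w0[1:20]), unname(aac(seq)))
  expect_true(all(w0[21:22] == 0))
  expect_true(all(is.na(paac(random_seq(100, seed = 13), lambda = 130))))
})

test_that("amphiphilic pseudo-composition matches oracle and reduces to aac", {
  expect_length(apaac(random_seq(100, seed = 14)), 80)
  seq <- random_seq(5, seed = 15)
  got <- apaac(seq, lambda = 1, weight = 0.05)
  want <- oracle_apaac(seq, 1, 0.05, default_paac_scales()[1:2])
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)
  w0 <- apaac(seq, lambda = 1, weight = 0)
  expect_equal(unname(w0[1:20]), unname(aac(seq)))
})

test_that("physicochemical profile is weighted composition plus sequence mean", {
  sc <- aa_scales()$hydrophobicity
  p <- property_profile("AAAA", sc)
  expect_equal(p[["A"]], sc[["A"]])
  expect_equal(sum(p[1:20] != 0), 1)
  expect_equal(p[["mean"]], sc[["A"]])
  zero <- stats::setNames(rep(0, 20), aa_alphabet())
  expect_true(all(property_profile("ACDE", zero) == 0))
  seq <- random_seq(40, seed = 16)
  ch <- chars_of(seq)
  expect_equal(property_profile(seq, sc)[["mean"]],
               sum(sc[ch]) / length(ch), tolerance = 1e-12)
})

test_that("simple scalar descriptors are correct", {
  expect_equal(protein_mass("G"), 57.0519 + 18.01528, tolerance = 1e-6)
  # independent table-lookup sum for ACDE
  want <- 71.0788 + 103.1388 + 115.0886 + 129.1155 + 18.01528
  expect_equal(protein_mass("ACDE"), want, tolerance = 1e-6)
  expect_gt(isoelectric_point("KKKKKKKK"), isoelectric_point("DDDDDDDD"))
  tp <- total_aa_property("KK")
  expect_equal(tp[["charge"]], 2)
})

test_that("default configuration reproduces the 52-block, 1610-dimension layout", {
  cfg <- feature_config()
  expect_equal(nrow(cfg), 52)
  expect_equal(sum(cfg$length), 1610)
  expect_equal(cfg$length[cfg$block == "aac"], 20)
  expect_equal(cfg$length[cfg$block == "dpc"], 400)
  expect_equal(cfg$length[cfg$block == "qso"], 160)
  expect_equal(cfg$length[cfg$block == "paac"], 150)
  expect_equal(cfg$length[cfg$block == "apaac"], 80)
  expect_equal(sum(cfg$length[cfg$block %in% c("moreau_broto", "moran", "geary")]),
               270)
  # restricted configuration: composition blocks only
  expect_equal(sum(feature_config(c("aac", "dpc"))$length), 420)
  expect_error(feature_config("nonesuch"), "unknown")
})

test_that("feature matrix has block-qualified columns and per-protein NA flags", {
  recs <- tibble::tibble(
    id = c("long", "short"),
    sequence = c(random_seq(200, seed = 17), random_seq(10, seed = 18)))
  fm <- build_feature_matrix(recs)
  expect_equal(ncol(fm) - 1, 1610)
  expect_equal(nrow(fm), 2)
  # long sequence: only the 41 external dims are missing
  expect_equal(sum(is.na(fm[1, ])), 41)
  # short sequence: paac (150), qso (160), apaac (80) and long lags also NA
  expect_true(all(is.na(fm[2, grepl("^paac", names(fm))])))
  expect_true(all(is.na(fm[2, grepl("^qso", names(fm))])))
  expect_false(anyNA(fm[2, grepl("^aac", names(fm))]))
  expect_error(build_feature_matrix(recs[c(1, 1), ]), "duplicate")
})

test_that("featurization is deterministic and row-order equivariant", {
  recs <- tibble::tibble(id = c("p1", "p2", "p3"),
                         sequence = replicate(3, random_seq(80)))
  fm1 <- build_feature_matrix(recs, feature_config(c("aac", "dpc", "qso")))
  fm2 <- build_feature_matrix(recs, feature_config(c("aac", "dpc", "qso")))
  expect_identical(fm1, fm2)
  perm <- c(3, 1, 2)
  fm3 <- build_feature_matrix(recs[perm, ], feature_config(c("aac", "dpc", "qso")))
  expect_identical(fm3, fm1[perm, ])
})

test_that("external feature ingestion round-trips and rejects unknown columns", {
  recs <- tibble::tibble(id = c("p1", "p2"),
                         sequence = c("ACDEFGHIK", "MNPQRSTVWY"))
  ext <- tibble::tibble(protein_id = "p1", signal_peptide = 1,
                        transmembrane_domains = 0)
  fm <- build_feature_matrix(recs, external = ext)
  expect_equal(fm$signal_peptide, c(1, NA))
  expect_equal(fm$transmembrane_domains, c(0, NA))
  expect_true(all(is.na(fm$twin_arginine_signal)))
  bad <- tibble::tibble(protein_id = "p1", not_a_block = 1)
  expect_error(build_feature_matrix(recs, external = bad), "not_a_block")
  # round trip through the TSV writer/reader
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(fm, tmp)
  back <- read_feature_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(fm), tolerance = 1e-12)
})
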