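test_that("forward pass is symmetric at zero weights and numerically stable", {
  m <- mlp_init(4, c(8, 8), seed = 1)
  for (l in seq_along(m$layers)) {
    m$layers[[l]]$W[] <- 0
    m$layers[[l]]$b[] <- 0
  }
  expect_equal(mlp_forward(m, rep(1, 4)), 0.5)
  # huge positive logit for the positive unit: p -> 1 without overflow
  m$layers[[3]]$b <- c(0, 1e4)
  p <- mlp_forward(m, rep(1, 4))
  expect_true(is.finite(p))
  expect_equal(p, 1, tolerance = 1e-12)
  m$layers[[3]]$b <- c(1e4, 0)
  expect_equal(mlp_forward(m, rep(1, 4)), 0, tolerance = 1e-12)
})

test_that("forward pass matches an independent neuron-loop oracle", {
  set.seed(31)
  for (i in 1:3) {
    m <- mlp_init(5, c(7, 6), seed = 100 + i)
    x <- stats::rnorm(5)
    expect_equal(mlp_forward(m, x), oracle_forward(m, x), tolerance = 1e-6)
  }
  expect_error(mlp_forward(mlp_init(5, c(4), seed = 1), rep(0, 3)),
               "dimension")
})

test_that("cross-entropy has its closed forms and matches direct summation", {
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0, tolerance = 1e-6)
  expect_equal(cross_entropy(rep(0.5, 8), rep(c(0, 1), 4)), log(2))
  set.seed(32)
  p <- stats::runif(20, 0.05, 0.95)
  y <- stats::rbinom(20, 1, 0.5)
  acc <- 0
  for (i in 1:20) acc <- acc - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  expect_equal(cross_entropy(p, y), acc / 20, tolerance = 1e-12)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  sim <- gen_feature_table(n_pos = 100, n_neg = 100, n_informative = 2,
                           n_noise = 0, effect_size = 3, seed = 33)
  X <- as.matrix(sim$features[, -1])
  y <- as.numeric(sim$labels)
  m1 <- mlp_train(X, y, hidden = c(16, 16), epochs = 15, seed = 5)
  loss <- attr(m1, "loss")
  expect_lt(loss[length(loss)], loss[1])
  m2 <- mlp_train(X, y, hidden = c(16, 16), epochs = 15, seed = 5)
  expect_equal(mlp_forward(m1, X), mlp_forward(m2, X), tolerance = 1e-12)
})

test_that("unlabeled partitioning is disjoint, equal-size, seeded", {
  ids <- sprintf("u%05d", 1:11954)
  expect_message(parts <- partition_unlabeled(ids, 16, seed = 4), "dropped 2")
  expect_length(parts, 16)
  expect_true(all(lengths(parts) == 747))
  all_ids <- unlist(parts)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_setequal(c(all_ids, attr(parts, "dropped")), ids)
  # exact division leaves nothing behind
  p2 <- partition_unlabeled(letters[1:10], 5, seed = 1)
  expect_true(all(lengths(p2) == 2))
  expect_length(attr(p2, "dropped"), 0)
  expect_identical(partition_unlabeled(ids, 16, seed = 4)[[1]], parts[[1]])
  expect_false(identical(partition_unlabeled(ids, 16, seed = 5)[[1]],
                         parts[[1]]))
  expect_error(partition_unlabeled(letters[1:3], 5), "fewer")
})

test_that("positive subsets are sampled without replacement, independently", {
  full <- sample_positive_subsets(letters[1:5], 3, 5, seed = 1)
  for (s in full) expect_setequal(s, letters[1:5])
  singles <- sample_positive_subsets(letters[1:4], 3, 1, seed = 2)
  expect_true(all(lengths(singles) == 1))
  expect_error(sample_positive_subsets(letters[1:3], 2, 5), "not enough")
  # inclusion frequency of each positive across many half-size draws ~ 1/2
  ids <- sprintf("p%02d", 1:20)
  subs <- sample_positive_subsets(ids, 200, 10, seed = 3)
  freq <- vapply(ids, function(id) {
    mean(vapply(subs, function(s) id %in% s, logical(1)))
  }, numeric(1))
  expect_true(all(abs(freq - 0.5) < 0.12))
})

make_pu_fixture <- function(seed = 41, n_pos = 60, n_unl = 120) {
  set.seed(seed)
  feats <- tibble::tibble(protein_id = sprintf("pr%04d", seq_len(n_pos + n_unl)),
                          f1 = stats::rnorm(n_pos + n_unl),
                          f2 = stats::rnorm(n_pos + n_unl))
  pos <- feats$protein_id[seq_len(n_pos)]
  feats$f1[seq_len(n_pos)] <- feats$f1[seq_len(n_pos)] + 2
  unl <- feats$protein_id[n_pos + seq_len(n_unl)]
  list(features = feats, positives = pos, unlabeled = unl)
}

small_config <- function(T = 4, seed = 1) {
  pu_config(T = T, hidden = c(8, 8), dropout = 0.1, epochs = 5,
            batch_size = 16, seed = seed)
}

test_that("every ensemble member trains on an exactly class-balanced subset", {
  fx <- make_pu_fixture()
  ens <- pu_fit(fx$features, fx$positives, fx$unlabeled, small_config())
  for (mb in ens$membership) {
    expect_equal(length(mb$positive), length(mb$unlabeled))
  }
  u_all <- unlist(lapply(ens$membership, `[[`, "unlabeled"))
  expect_equal(anyDuplicated(u_all), 0)
  td <- tidy(ens)
  expect_equal(td$n_positive, td$n_unlabeled)
})

test_that("out-of-bag prediction averages exactly T-1 members for partitioned ids", {
  fx <- make_pu_fixture()
  ens <- pu_fit(fx$features, fx$positives, fx$unlabeled, small_config(T = 4))
  # positives drawn into every subset warn by design; the out-of-bag
  # contract under test concerns the partitioned unlabeled ids
  pred <- suppressWarnings(predict(ens, fx$features))
  trained_unl <- unlist(lapply(ens$membership, `[[`, "unlabeled"))
  expect_true(all(pred$n_models[pred$protein_id %in% trained_unl] == 3))
  # unseen proteins average all T members
  unseen <- tibble::tibble(protein_id = "novel", f1 = 0.2, f2 = -0.1)
  expect_equal(predict(ens, unseen)$n_models, 4)
})

test_that("prediction is invariant to member order and bounded by member outputs", {
  fx <- make_pu_fixture(seed = 43)
  ens <- pu_fit(fx$features, fx$positives, fx$unlabeled, small_config(T = 3))
  pred <- suppressWarnings(predict(ens, fx$features))
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  shuf <- ens
  ord <- c(3, 1, 2)
  shuf$models <- ens$models[ord]
  shuf$membership <- ens$membership[ord]
  expect_equal(suppressWarnings(predict(shuf, fx$features))$probability,
               pred$probability)
  # member-wise bounds
  X <- as.matrix(fx$features[, c("f1", "f2")])
  member_p <- sapply(ens$models, function(m) mlp_forward(m, X))
  expect_true(all(pred$probability >= apply(member_p, 1, min) - 1e-12))
  expect_true(all(pred$probability <= apply(member_p, 1, max) + 1e-12))
})

test_that("identical members make the ensemble equal a single forward pass", {
  fx <- make_pu_fixture(seed = 44)
  ens <- pu_fit(fx$features, fx$positives, fx$unlabeled, small_config(T = 3))
  for (t in 2:3) ens$models[[t]] <- ens$models[[1]]
  pred <- suppressWarnings(predict(ens, fx$features))
  single <- mlp_forward(ens$models[[1]],
                        as.matrix(fx$features[, c("f1", "f2")]))
  expect_equal(pred$probability, single, tolerance = 1e-12)
})

test_that("classification threshold is strict, matching the > 0.5 rule", {
  expect_false(classify(0.5))
  expect_true(classify(0.51))
  expect_equal(classify(c(0, 1e-9), threshold = 0), c(FALSE, TRUE))
})

test_that("a positive sampled into every subset triggers the all-member fallback", {
  fx <- make_pu_fixture(n_pos = 30, n_unl = 60)
  cfg <- small_config(T = 2)
  ens <- pu_fit(fx$features, fx$positives, fx$unlabeled, cfg)
  # force one positive into both memberships
  pid <- fx$positives[1]
  ens$membership[[1]]$positive[1] <- pid
  ens$membership[[2]]$positive[1] <- pid
  expect_warning(pred <- predict(ens, fx$features[fx$features$protein_id == pid, ]),
                 "every training")
  expect_equal(pred$n_models, 2)
})

test_that("same config and seed reproduce membership and predictions exactly", {
  fx <- make_pu_fixture(seed = 45)
  e1 <- pu_fit(fx$features, fx$positives, fx$unlabeled, small_config(seed = 9))
  e2 <- pu_fit(fx$features, fx$positives, fx$unlabeled, small_config(seed = 9))
  expect_identical(e1$membership, e2$membership)
  expect_equal(suppressWarnings(predict(e1, fx$features))$probability,
               suppressWarnings(predict(e2, fx$features))$probability,
               tolerance = 1e-12)
})

test_that("ensemble bundles round-trip through the on-disk format", {
  fx <- make_pu_fixture(seed = 46)
  scaler <- fit_scaler(fx$features)
  feats <- scaler_transform(fx$features, scaler)
  ens <- pu_fit(feats, fx$positives, fx$unlabeled, small_config(T = 2))
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir, scaler = scaler)
  back <- load_ensemble(dir)
  expect_equal(back$config, ens$config)
  expect_identical(back$membership, ens$membership)
  expect_equal(suppressWarnings(predict(back, feats))$probability,
               suppressWarnings(predict(ens, feats))$probability,
               tolerance = 1e-9)
  expect_equal(tidy(attr(back, "scaler")), tidy(scaler))
})
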