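test_that("the dense classifier outputs calibrated softmax probabilities", {
  blob <- blob_features(n_per = 100, d = 8, sep = 2, seed = 12)
  cfg <- fcn_config(seed = 1)
  expect_equal(cfg$hidden, c(64L, 32L, 32L))
  m <- fcn(blob$X, blob$y, cfg)
  probs <- predict(m, blob$X, type = "prob")
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  expect_equal(colnames(probs), c("a", "b", "c"))
  # weight shapes follow the four-dense-layer architecture
  expect_equal(dim(m$params$W1), c(8L, 64L))
  expect_equal(dim(m$params$W2), c(64L, 32L))
  expect_equal(dim(m$params$W3), c(32L, 32L))
  expect_equal(dim(m$params$W4), c(32L, 3L))

  expect_error(fcn(blob$X, rep("a", nrow(blob$X))), "two classes")
})

test_that("well-separated blobs are classified almost perfectly", {
  blob <- blob_features(n_per = 100, d = 8, sep = 2, seed = 13)
  tr <- c(1:80, 101:180, 201:280)
  te <- setdiff(seq_len(300), tr)
  m <- fcn(blob$X[tr, ], blob$y[tr], fcn_config(seed = 2))
  acc <- mean(predict(m, blob$X[te, ]) == blob$y[te])
  # nearest-centroid oracle on the same split
  cents <- vapply(levels(blob$y), function(l)
    colMeans(blob$X[tr, ][blob$y[tr] == l, ]), numeric(8))
  oracle <- mean(levels(blob$y)[apply(blob$X[te, ], 1, function(x)
    which.min(colSums((cents - x)^2)))] == blob$y[te])
  expect_gte(acc, 0.95)
  expect_gte(acc, oracle - 0.05)
})

test_that("repeated cross-validation isolates the holdout and reports per-class counts", {
  blob <- blob_features(n_per = 60, d = 6, sep = 1.5, seed = 14)
  rep <- classify_embedding(blob$X, blob$y, n_repetitions = 2, holdout = 40,
                            cv_folds = 5, seed = 3)
  expect_length(rep$accuracies, 2)
  expect_true(all(rep$accuracies >= 0 & rep$accuracies <= 1))
  expect_length(rep$holdout_idx, 40)
  # confusion rows sum to the holdout's true class counts
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(blob$y[rep$holdout_idx]))))
  # bit-identical reruns under the same seed
  rep2 <- classify_embedding(blob$X, blob$y, n_repetitions = 2, holdout = 40,
                             cv_folds = 5, seed = 3)
  expect_identical(rep$accuracies, rep2$accuracies)
  expect_identical(rep$holdout_idx, rep2$holdout_idx)

  expect_error(classify_embedding(blob$X[1:20, ], blob$y[1:20],
                                  holdout = 100), "too small")
})

test_that("the dimension sweep tabulates one report per latent dimension", {
  models <- toy_models()
  sw <- dimension_sweep(models$ds, dims = c(2L, 4L), n_repetitions = 2,
                        holdout = 30, cv_folds = 3, vae_epochs = 3,
                        seed = 4)
  expect_equal(nrow(sw$table), 2)
  expect_equal(sw$table$dim, c(2L, 4L))
  expect_true(all(sw$table$mean_accuracy >= 0 & sw$table$mean_accuracy <= 1))
  expect_true(sw$elbow %in% sw$table$dim)
  expect_error(dimension_sweep(models$ds, dims = c(0L, 2L)), "input_dim")
})

test_that("scrambled labels drop accuracy to chance", {
  blob <- blob_features(n_per = 60, d = 6, sep = 1.5, seed = 15)
  obs <- classify_embedding(blob$X, blob$y, n_repetitions = 2, holdout = 45,
                            cv_folds = 3, seed = 5)
  null <- scrambled_null(blob$X, blob$y, n_repetitions = 8, holdout = 45,
                         cv_folds = 3, seed = 6, observed = obs$mean)
  se <- sqrt((1 / 3) * (2 / 3) / 45)
  expect_lt(abs(null$mean - 1 / 3), 3 * se)
  expect_gt(obs$mean, stats::quantile(null$accuracies, 0.95))
  expect_lte(null$p_value, 0.125)
})

test_that("baseline classifier table covers supplied feature sets and skips missing", {
  blob <- blob_features(n_per = 40, d = 6, sep = 1.5, seed = 16)
  sets <- list(raw = list(features = blob$X, labels = blob$y),
               absent = NULL)
  expect_warning(
    baseline_classifiers(sets, n_repetitions = 1, holdout = 30, cv_folds = 3,
                         seed = 7),
    "absent")
  tab <- suppressWarnings(
    baseline_classifiers(sets, n_repetitions = 1, holdout = 30, cv_folds = 3,
                         seed = 7))
  expect_equal(tab$feature_set, "raw")
  expect_equal(tab$n_features, 6)
  expect_true(tab$mean_accuracy >= 0 && tab$mean_accuracy <= 1)
})

test_that("t-SNE class distance separates blobs and collapses under shuffling", {
  blob <- blob_features(n_per = 40, d = 10, sep = 3, seed = 17)
  d_true <- tsne_class_distance(blob$X, blob$y, seed = 8, n_iter = 250)
  emb <- attr(d_true, "embedding")
  within <- mean(vapply(levels(blob$y), function(l)
    mean(stats::dist(emb[blob$y == l, ])), numeric(1)))
  expect_gt(d_true, within)

  y_shuf <- with_seed_test(9, sample(blob$y))
  d_shuf <- tsne_class_distance(blob$X, y_shuf, seed = 8, n_iter = 250)
  expect_lt(d_shuf, d_true)

  same <- matrix(1, 40, 4)
  expect_lt(tsne_class_distance(same, rep(c("a", "b"), 20), seed = 10,
                                n_iter = 100), 0.1)
  expect_error(tsne_class_distance(blob$X, rep("a", 120)), "two classes")
})
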