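test_that("parcellation generation respects sizes, RSN coverage and determinism", {
  p <- generate_parcellation(115, 8, seed = 1)
  expect_equal(nrow(p), 115)
  expect_equal(sort(unique(p$rsn)), 1:8)
  expect_true(all(table(p$rsn) >= 1))
  expect_equal(p$region_id, 1:115)
  expect_true(all(p$hemisphere %in% c("left", "right", "midline")))

  # pigeonhole: as many RSNs as regions puts one region in each
  p1 <- generate_parcellation(8, 8, seed = 99)
  expect_equal(unname(as.vector(table(p1$rsn))), rep(1L, 8))

  expect_identical(generate_parcellation(115, 8, seed = 1),
                   generate_parcellation(115, 8, seed = 1))
  expect_error(generate_parcellation(5, 8), "invalid configuration")
})

test_that("synthetic connectome is symmetric, hollow, connected and modular", {
  p <- generate_parcellation(115, 8, seed = 1)
  C <- generate_sc(p, seed = 2)
  expect_equal(dim(C), c(115, 115))
  expect_identical(C, t(C))
  expect_true(all(diag(C) == 0))
  expect_true(all(C >= 0))
  expect_true(hopfbrain:::is_connected_graph(C))

  same <- outer(p$rsn, p$rsn, `==`) & upper.tri(C)
  diff <- outer(p$rsn, p$rsn, `!=`) & upper.tri(C)
  expect_gt(mean(C[same]), mean(C[diff]))
})

test_that("condition parameters follow the configured offsets", {
  p <- generate_parcellation(30, 8, seed = 5)
  labs <- c("control", "nonrelapsing", "relapsing")

  zero <- lapply(labs, generate_condition_parameters, parcellation = p,
                 effect_config = null_effects(), seed = 7)
  expect_identical(zero[[1]]$rsn_bifurcations, zero[[2]]$rsn_bifurcations)
  expect_identical(zero[[2]]$rsn_couplings, zero[[3]]$rsn_couplings)
  expect_identical(zero[[1]]$node_frequencies, zero[[3]]$node_frequencies)

  conds <- lapply(labs, generate_condition_parameters, parcellation = p,
                  effect_config = condition_effects(), seed = 7)
  for (i in 1:2) for (j in (i + 1):3) {
    d <- sqrt(sum((c(conds[[i]]$rsn_bifurcations, conds[[i]]$rsn_couplings) -
                   c(conds[[j]]$rsn_bifurcations, conds[[j]]$rsn_couplings))^2))
    expect_gt(d, 0)
  }
  expect_true(all(conds[[1]]$node_frequencies >= 0.04 &
                  conds[[1]]$node_frequencies <= 0.07))
  expect_error(generate_condition_parameters("unknown", p, seed = 1),
               "unknown condition label")
})

test_that("cohort generation produces labelled, reproducible recordings", {
  p <- generate_parcellation(10, 3, seed = 1)
  sc <- generate_sc(p, seed = 2)
  eff <- condition_effects(n_rsn = 3)
  labs <- c("control", "nonrelapsing", "relapsing")
  conds <- lapply(labs, generate_condition_parameters, parcellation = p,
                  effect_config = eff, seed = 3)
  names(conds) <- labs
  sizes <- c(control = 3L, nonrelapsing = 2L, relapsing = 2L)
  sim <- tiny_sim(40L)

  ch <- generate_cohort(sc, conds, p, group_sizes = sizes, sim = sim, seed = 4)
  expect_length(ch$subjects, 7)
  expect_equal(as.vector(table(cohort_labels(ch))[labs]), unname(sizes))
  expect_equal(dim(ch$subjects[[1]]$bold$data), c(40, 10))

  ch2 <- generate_cohort(sc, conds, p, group_sizes = sizes, sim = sim, seed = 4)
  expect_identical(ch$subjects[[5]]$bold$data, ch2$subjects[[5]]$bold$data)

  empty <- generate_cohort(sc, conds, p,
                           group_sizes = c(control = 0L, nonrelapsing = 0L,
                                           relapsing = 0L),
                           sim = sim, seed = 4)
  expect_length(empty$subjects, 0)
  expect_error(generate_cohort(sc, conds, p, group_sizes = c(ghost = 2L),
                               sim = sim, seed = 4),
               "unknown label")
})

test_that("default effects create learnable class structure; zero effects do not", {
  p <- generate_parcellation(30, 8, seed = 21)
  sc <- generate_sc(p, seed = 22)
  labs <- c("control", "nonrelapsing", "relapsing")
  sizes <- c(control = 18L, nonrelapsing = 18L, relapsing = 18L)
  sim <- tiny_sim(120L)

  loo_centroid_acc <- function(cohort) {
    y <- cohort_labels(cohort)
    X <- do.call(rbind, lapply(cohort$subjects, function(s)
      vectorize_fc(compute_fc(bandpass(s$bold)))))
    hits <- vapply(seq_along(y), function(i) {
      cents <- vapply(labs, function(l)
        colMeans(X[y == l & seq_along(y) != i, , drop = FALSE]),
        numeric(ncol(X)))
      labs[which.min(colSums((cents - X[i, ])^2))] == y[i]
    }, logical(1))
    mean(hits)
  }

  n <- sum(sizes)
  se <- sqrt((1 / 3) * (2 / 3) / n)

  conds <- lapply(labs, generate_condition_parameters, parcellation = p,
                  effect_config = condition_effects(), seed = 23)
  names(conds) <- labs
  acc <- loo_centroid_acc(generate_cohort(sc, conds, p, group_sizes = sizes,
                                          sim = sim, seed = 24))
  expect_gt(acc, 1 / 3 + 3 * se)

  conds0 <- lapply(labs, generate_condition_parameters, parcellation = p,
                   effect_config = null_effects(), seed = 23)
  names(conds0) <- labs
  acc0 <- loo_centroid_acc(generate_cohort(sc, conds0, p, group_sizes = sizes,
                                           sim = sim, seed = 24))
  expect_lt(abs(acc0 - 1 / 3), 3 * se)

  # between-condition FC distance exceeds within-condition distance
  ch <- generate_cohort(sc, conds, p,
                        group_sizes = c(control = 6L, nonrelapsing = 6L,
                                        relapsing = 6L),
                        sim = sim, seed = 25)
  y <- cohort_labels(ch)
  fcs <- lapply(ch$subjects, function(s) compute_fc(bandpass(s$bold)))
  dmat <- as.matrix(stats::dist(do.call(rbind, lapply(fcs, vectorize_fc))))
  same <- outer(y, y, `==`) & upper.tri(dmat)
  diff <- outer(y, y, `!=`) & upper.tri(dmat)
  expect_gt(mean(dmat[diff]), mean(dmat[same]))
})

test_that("matrix, parcellation and BOLD writers round-trip through disk", {
  p <- generate_parcellation(12, 3, seed = 1)
  tmp <- withr::local_tempdir()
  read_back <- read_parcellation(write_parcellation(p, file.path(tmp, "p.tsv")))
  expect_equal(read_back$rsn, p$rsn)

  sc <- generate_sc(p, seed = 2)
  sc2 <- read_matrix_tsv(write_matrix_tsv(sc, file.path(tmp, "sc.tsv")))
  expect_equal(unname(sc2), unname(sc), tolerance = 1e-12)

  rec <- bold_recording(matrix(rnorm(40), 10, 4), tr = 1.92)
  rec2 <- read_bold(write_bold(rec, file.path(tmp, "bold.tsv")))
  expect_equal(rec2$tr, 1.92)
  expect_equal(unname(rec2$data), unname(rec$data), tolerance = 1e-12)
})
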