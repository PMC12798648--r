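test_that("zero forcing reproduces the unperturbed simulation bit-exactly", {
  sys <- toy_system()
  pars <- expand_parameters(toy_truth(), sys$parc, sys$omega, tiny_sim())
  plain <- simulate_hopf(pars, sys$sc, seed = 60)
  forced0 <- simulate_hopf(pars, sys$sc,
                           forcing = forcing(3, 0, sys$omega[3]), seed = 60)
  expect_identical(plain$data, forced0$data)

  models <- toy_models()
  fit <- models$fits$relapsing
  res0 <- perturb_and_classify(fit, node = 3, amplitude = 0,
                               models$vae, models$clf, seed = 61)
  pars_fit <- expand_parameters(fit$best, fit$parcellation, fit$omega, fit$sim)
  fc_plain <- simulate_fc(pars_fit, fit$sc, n_realizations = 3, seed = 61)
  expect_identical(res0$fc, fc_plain)
  expect_equal(sum(res0$prob), 1, tolerance = 1e-6)
})

test_that("strong forcing entrains the forced node at the stimulation frequency", {
  sys <- toy_system()
  pars <- expand_parameters(toy_truth(), sys$parc, sys$omega, tiny_sim(240L))
  w0 <- 2 * pi * 0.055
  rec <- simulate_hopf(pars, sys$sc, forcing = forcing(5, 0.5, w0), seed = 62)
  pg <- hopfbrain:::periodogram(rec$data, pars$tr)
  peak <- pg$freq[which.max(pg$power[, 5])]
  bin <- pg$freq[2] - pg$freq[1]
  expect_lte(abs(peak - 0.055), bin)
})

test_that("forcing energy in the stimulated node grows with amplitude", {
  sys <- toy_system()
  pars <- expand_parameters(toy_truth(), sys$parc, sys$omega, tiny_sim(120L))
  var_at <- function(a) {
    mean(vapply(1:10, function(r) {
      rec <- simulate_hopf(pars, sys$sc,
                           forcing = forcing(2, a, sys$omega[2]),
                           seed = 700 + r)
      stats::var(rec$data[, 2])
    }, numeric(1)))
  }
  amps <- c(0, 0.1, 0.3, 0.5)
  vs <- vapply(amps, var_at, numeric(1))
  expect_true(all(diff(vs) > -0.01 * max(vs)))
  expect_gt(vs[4], vs[1])
})

test_that("the sweep enumerates the complete node-by-amplitude grid reproducibly", {
  models <- toy_models()
  fit <- models$fits$relapsing
  amps <- c(0.01, 0.3)
  nodes <- c(1L, 5L, 9L)
  grid <- perturbation_sweep(fit, models$vae, models$clf, amplitudes = amps,
                             nodes = nodes, n_realizations = 1, seed = 63)
  expect_equal(nrow(grid), length(nodes) * length(amps))
  expect_equal(unique(grid$node), nodes)
  expect_equal(sort(unique(grid$amplitude)), sort(amps))
  probs <- as.matrix(grid[, paste0("p_", toy_labels)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))

  grid2 <- perturbation_sweep(fit, models$vae, models$clf, amplitudes = amps,
                              nodes = nodes, n_realizations = 1, seed = 63)
  expect_identical(grid$predicted, grid2$predicted)
  expect_equal(probs, as.matrix(grid2[, paste0("p_", toy_labels)]),
               tolerance = 1e-12)
  expect_error(perturbation_sweep(fit, models$vae, models$clf,
                                  amplitudes = numeric(0)), "nonempty")
})

test_that("the perturbability map applies the confidence threshold rule", {
  # every confidence at 0.5: nothing clears the 0.6 default threshold
  flat <- hand_grid(list(
    list(1, 0.1, 0.5, 0.25, 0.25),
    list(2, 0.1, 0.25, 0.5, 0.25)))
  expect_equal(nrow(perturbability_map(flat)), 0)

  # one qualifying cell: node 7 reclassified with confidence 0.9
  g <- hand_grid(list(
    list(7, 0.05, 0.2, 0.7, 0.1),     # nonrelapsing at 0.7 < first amplitude?
    list(7, 0.02, 0.9, 0.05, 0.05),   # control at 0.9, smaller amplitude
    list(8, 0.05, 0.1, 0.3, 0.6)))    # original class: excluded
  map <- perturbability_map(g)
  expect_equal(nrow(map), 2)
  hit <- map[map$to == "control", ]
  expect_equal(hit$node, 7)
  expect_equal(hit$min_amplitude, 0.02)
  expect_equal(hit$confidence, 0.9)

  # boundary: 0.59 excluded, 0.61 included at the default 0.6 threshold
  edge <- hand_grid(list(
    list(1, 0.1, 0.59, 0.2, 0.21),
    list(2, 0.1, 0.61, 0.19, 0.2)))
  mape <- perturbability_map(edge)
  expect_equal(mape$node, 2)

  expect_error(perturbability_map(flat, threshold = 0.2), "threshold")
})

test_that("the map agrees with an independent brute-force scan of the grid", {
  models <- toy_models()
  fit <- models$fits$relapsing
  grid <- perturbation_sweep(fit, models$vae, models$clf,
                             amplitudes = c(0.02, 0.1, 0.4),
                             nodes = 1:10, n_realizations = 1, seed = 64)
  map <- perturbability_map(grid, threshold = 0.6)

  # oracle: enumerate cells directly
  classes <- attr(grid, "classes")
  original <- attr(grid, "original")
  expected <- list()
  for (i in seq_len(nrow(grid))) {
    conf <- max(grid[i, paste0("p_", classes)])
    if (grid$predicted[i] != original && conf > 0.6) {
      key <- paste(grid$node[i], grid$predicted[i])
      amp <- grid$amplitude[i]
      if (is.null(expected[[key]]) || amp < expected[[key]])
        expected[[key]] <- amp
    }
  }
  expect_equal(nrow(map), length(expected))
  for (key in names(expected)) {
    parts <- strsplit(key, " ")[[1]]
    row <- map[map$node == as.numeric(parts[1]) & map$to == parts[2], ]
    expect_equal(row$min_amplitude, expected[[key]])
  }
})
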