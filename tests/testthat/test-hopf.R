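test_that("RSN parameters expand to node-level vectors by membership", {
  p8 <- generate_parcellation(24, 8, seed = 1)
  rp <- rsn_params(a = seq(-0.2, 0.15, length.out = 8), g = rep(1, 8))
  expect_length(flatten_rsn_params(rp), 16)

  pars <- expand_parameters(rp, p8, rep(2 * pi * 0.05, 24), tiny_sim())
  expect_equal(pars$a, rp$a[p8$rsn])
  expect_equal(pars$g, rp$g[p8$rsn])

  homog <- expand_parameters(rsn_params(rep(-0.1, 8), rep(0.5, 8)), p8,
                             rep(2 * pi * 0.05, 24), tiny_sim())
  expect_equal(homog$a, rep(-0.1, 24))
  expect_equal(homog$g, rep(0.5, 24))

  # one region per RSN: node vectors equal RSN vectors
  p1 <- generate_parcellation(4, 4, seed = 2)
  rp4 <- rsn_params(a = c(-0.1, 0, 0.1, 0.2), g = 1:4 / 2)
  pars1 <- expand_parameters(rp4, p1, rep(2 * pi * 0.05, 4), tiny_sim())
  expect_equal(sort(pars1$a), sort(rp4$a))
  expect_equal(pars1$a, rp4$a[p1$rsn])

  expect_error(expand_parameters(rsn_params(-0.1, 1), p8,
                                 rep(2 * pi * 0.05, 24), tiny_sim()),
               "no parameter pair")
})

test_that("subcritical single node behaves as an Ornstein-Uhlenbeck process", {
  # linearised regime: Var(x) ~ beta^2 / (2|a|); small dt keeps the
  # Euler-Maruyama discretisation bias well below the tolerance
  pars <- hopf_params(a = -5, g = 0, omega = 2 * pi * 0.05, beta = 0.02,
                      dt = 0.02, tr = 0.02, n_volumes = 100000L, transient = 10)
  rec <- simulate_hopf(pars, matrix(0, 1, 1), seed = 1)
  v <- stats::var(rec$data[, 1])
  expect_lt(abs(v - 0.02^2 / 10) / (0.02^2 / 10), 0.2)
})

test_that("noise amplitude is recoverable from stationary variance for a <= -2", {
  pars <- hopf_params(a = -2, g = 0, omega = 2 * pi * 0.05, beta = 0.02,
                      dt = 0.02, tr = 0.02, n_volumes = 50000L, transient = 10)
  rec <- simulate_hopf(pars, matrix(0, 1, 1), seed = 2)
  beta_hat <- sqrt(2 * 2 * stats::var(rec$data[, 1]))
  expect_lt(abs(beta_hat - 0.02) / 0.02, 0.15)
})

test_that("supercritical node oscillates at its intrinsic frequency", {
  pars <- hopf_params(a = 0.2, g = 0, omega = 2 * pi * 0.05, beta = 1e-6,
                      dt = 0.096, tr = 1.92, n_volumes = 240L)
  rec <- simulate_hopf(pars, matrix(0, 1, 1), seed = 3)
  pg <- hopfbrain:::periodogram(rec$data, 1.92)
  peak <- pg$freq[which.max(pg$power[, 1])]
  bin <- pg$freq[2] - pg$freq[1]
  expect_lte(abs(peak - 0.05), bin)
})

test_that("limit-cycle amplitude grows as sqrt(a) above the bifurcation", {
  amp <- function(a) {
    pars <- hopf_params(a = a, g = 0, omega = 2 * pi * 0.05, beta = 0,
                        dt = 0.048, tr = 1.92, n_volumes = 300L,
                        transient = 200)
    rec <- simulate_hopf(pars, matrix(0, 1, 1), seed = 4)
    sqrt(2) * stats::sd(rec$data[, 1])
  }
  expect_lt(abs(amp(0.04) / amp(0.01) - 2), 0.2)
})

test_that("uncoupled nodes stay uncorrelated", {
  pars <- hopf_params(a = c(-0.1, -0.1), g = c(0, 0),
                      omega = 2 * pi * c(0.05, 0.06), beta = 0.02,
                      dt = 0.096, tr = 0.96, n_volumes = 8000L)
  rec <- simulate_hopf(pars, matrix(0, 2, 2), seed = 5)
  expect_lt(abs(compute_fc(rec$data)[1, 2]), 0.05)
})

test_that("difference coupling raises pairwise FC with coupling strength", {
  C <- matrix(c(0, 1, 1, 0), 2)
  fc_at_g <- function(g) {
    mean(vapply(1:20, function(r) {
      pars <- hopf_params(a = c(-0.05, -0.05), g = c(g, g),
                          omega = 2 * pi * c(0.05, 0.055), beta = 0.02,
                          dt = 0.096, tr = 1.92, n_volumes = 120L)
      compute_fc(simulate_hopf(pars, C, seed = 1000 * g + r)$data)[1, 2]
    }, numeric(1)))
  }
  gs <- seq(0, 1, by = 0.1)
  fcs <- vapply(gs, fc_at_g, numeric(1))
  expect_true(all(diff(fcs) > -0.05))   # nondecreasing up to noise
  expect_gt(fcs[length(fcs)], fcs[1] + 0.1)
})

test_that("simulation is deterministic under a fixed seed and guards blow-ups", {
  sys <- toy_system()
  pars <- expand_parameters(toy_truth(), sys$parc, sys$omega, tiny_sim())
  r1 <- simulate_hopf(pars, sys$sc, seed = 7)
  r2 <- simulate_hopf(pars, sys$sc, seed = 7)
  expect_identical(r1$data, r2$data)

  unstable <- hopf_params(a = 5, g = 0, omega = 2 * pi * 0.05, beta = 0,
                          dt = 10, tr = 10, n_volumes = 50L, transient = 0)
  expect_error(simulate_hopf(unstable, matrix(0, 1, 1), seed = 1),
               "blow-up")
})

test_that("simulate_fc averages realisations and reduces to the single-run pipeline", {
  sys <- toy_system()
  pars <- expand_parameters(toy_truth(), sys$parc, sys$omega, tiny_sim())
  one <- simulate_fc(pars, sys$sc, n_realizations = 1, seed = 9)
  manual <- compute_fc(bandpass(simulate_hopf(pars, sys$sc, seed = 9)))
  expect_equal(one, manual, tolerance = 1e-12)

  avg <- simulate_fc(pars, sys$sc, n_realizations = 3, seed = 10)
  expect_identical(avg, t(avg))
  expect_equal(diag(avg), rep(1, 20))
  expect_identical(avg, simulate_fc(pars, sys$sc, n_realizations = 3, seed = 10))
  expect_error(simulate_fc(pars, sys$sc, n_realizations = 0), ">= 1")
})
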