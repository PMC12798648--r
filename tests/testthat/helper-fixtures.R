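# Shared small fixtures, built in code.  Expensive objects are memoised in
# `.fixture_cache` so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# fast integration settings for toy networks
tiny_sim <- function(n_volumes = 60L) {
  sim_settings(n_volumes = n_volumes)
}

toy_labels <- c("control", "nonrelapsing", "relapsing")

# 20-node, 4-RSN toy system used across fitting/perturbation tests
toy_system <- function() {
  cached("toy_system", {
    parc <- generate_parcellation(20, 4, seed = 11)
    sc <- generate_sc(parc, seed = 12)
    omega <- with_seed_test(13, 2 * pi * runif(20, 0.04, 0.07))
    list(parc = parc, sc = sc, omega = omega)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  code
}

# ground-truth RSN parameters for the recovery toy (mixed dynamical regimes)
toy_truth <- function() rsn_params(a = c(0.05, -0.15, 0.02, -0.08),
                                   g = c(1.5, 0.8, 2.0, 1.2))

# a cheap fitted model for the toy system (small GA budget)
toy_fit <- function() {
  cached("toy_fit", {
    sys <- toy_system()
    pars <- expand_parameters(toy_truth(), sys$parc, sys$omega, tiny_sim())
    target <- simulate_fc(pars, sys$sc, n_realizations = 5, seed = 14)
    hopf_fit(target, sys$sc, sys$omega, sys$parc,
             config = ga_config(population_size = 8, max_generations = 3),
             sim = tiny_sim(), label = "relapsing", seed = 15)
  })
}

# small augmented dataset + VAE + classifier over the toy fit (three
# conditions derived from the toy system with distinct parameters)
toy_models <- function() {
  cached("toy_models", {
    sys <- toy_system()
    sim <- tiny_sim()
    eff <- condition_effects(n_rsn = 4)
    fits <- lapply(toy_labels, function(l) {
      cond <- generate_condition_parameters(l, sys$parc, eff, seed = 3)
      pars <- expand_parameters(rsn_params(cond$rsn_bifurcations,
                                           cond$rsn_couplings),
                                sys$parc, sys$omega, sim)
      target <- simulate_fc(pars, sys$sc, n_realizations = 5,
                            seed = 20 + match(l, toy_labels))
      hopf_fit(target, sys$sc, sys$omega, sys$parc,
               config = ga_config(population_size = 6, max_generations = 2),
               sim = sim, label = l, seed = 30 + match(l, toy_labels))
    })
    names(fits) <- toy_labels
    ds <- augment(fits, n_per_class = 40, seed = 40)
    feats <- fc_features(ds)
    vae <- fc_vae(feats, vae_config(latent_dim = 4, epochs = 40,
                                    batch_size = 32, hidden = c(64, 32),
                                    seed = 41))
    emb <- predict(vae, feats, type = "latent")
    clf <- fcn(emb, ds$labels, fcn_config(seed = 42))
    list(fits = fits, ds = ds, feats = feats, vae = vae, emb = emb, clf = clf)
  })
}

# three Gaussian blobs in d dimensions (toy classification data)
blob_features <- function(n_per = 100, d = 45, sep = 1.2, seed = 8) {
  with_seed_test(seed, {
    cents <- matrix(rnorm(3 * d, 0, sep), 3)
    X <- do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(rnorm(n_per * d), n_per), 2, cents[k, ], `+`)))
    list(X = X, y = factor(rep(c("a", "b", "c"), each = n_per)))
  })
}

# hand-built perturbation grid (node x amplitude cells with known probs)
hand_grid <- function(rows, classes = toy_labels, original = "relapsing") {
  grid <- as.data.frame(do.call(rbind, lapply(rows, unlist)))
  names(grid) <- c("node", "amplitude", paste0("p_", classes))
  pcols <- as.matrix(grid[, paste0("p_", classes)])
  grid$predicted <- classes[max.col(pcols)]
  grid <- grid[, c("node", "amplitude", "predicted", paste0("p_", classes))]
  attr(grid, "classes") <- classes
  attr(grid, "original") <- original
  class(grid) <- c("perturbation_grid", "data.frame")
  grid
}

# brute-force two-pass Pearson correlation, independent of stats::cor
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
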