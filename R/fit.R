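#' Goodness of fit between two functional connectivity matrices
#'
#' `GoF = 1 - corr(FC_emp, FC_sim)`, the Pearson correlation being taken over
#' the vectorised strict upper triangles.  0 means perfectly correlated,
#' 2 perfectly anti-correlated.
#'
#' @param fc_emp,fc_sim N x N matrices.
#' @return Scalar in `[0, 2]`.
#' @export
goodness_of_fit <- function(fc_emp, fc_sim) {
  u <- vectorize_fc(fc_emp)
  v <- vectorize_fc(fc_sim)
  if (length(u) != length(v)) stop("matrices must share dimensions")
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("zero-variance upper triangle: correlation undefined")
  1 - cor(u, v)
}

#' Genetic algorithm configuration
#'
#' Defaults follow the fitting protocol: a population of 20 individuals
#' evolved for at most 20 generations, stopping early when the
#' generation-mean GoF improves by less than `convergence_tol`.  Selection
#' is tournament (k = 2) with uniform crossover, Gaussian mutation with
#' standard deviation `mutation_sd_frac` of each coordinate's bound range,
#' and elitism.
#'
#' @param population_size individuals per generation (>= 2).
#' @param max_generations generation cap.
#' @param convergence_tol threshold on the change of generation-mean GoF.
#' @param elite number of best individuals copied unchanged.
#' @param crossover_rate probability a child is produced by crossover.
#' @param mutation_sd_frac mutation SD as a fraction of the bound range.
#' @param bounds_a,bounds_g search bounds for RSN bifurcation and coupling.
#' @param n_realizations noise realisations averaged per fitness evaluation.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 20L, max_generations = 20L,
                      convergence_tol = 1e-6, elite = 2L,
                      crossover_rate = 0.7, mutation_sd_frac = 0.05,
                      bounds_a = c(-0.3, 0.3), bounds_g = c(0, 3),
                      n_realizations = 5L) {
  if (population_size < 2L) stop("population_size must be >= 2")
  if (!all(is.finite(c(bounds_a, bounds_g)))) stop("bounds must be finite")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 convergence_tol = convergence_tol,
                 elite = as.integer(elite),
                 crossover_rate = crossover_rate,
                 mutation_sd_frac = mutation_sd_frac,
                 bounds_a = bounds_a, bounds_g = bounds_g,
                 n_realizations = as.integer(n_realizations)),
            class = "ga_config")
}

ga_bounds <- function(config, r) {
  lower <- c(rep(config$bounds_a[1], r), rep(config$bounds_g[1], r))
  upper <- c(rep(config$bounds_a[2], r), rep(config$bounds_g[2], r))
  cbind(lower = lower, upper = upper)
}

# Elitist GA over flattened RSN parameter vectors.  fitness_fn(v) must
# return list(gof = scalar, fc = matrix or NULL).  When `collect` is given
# (an environment with $fcs, $n_max), every successfully evaluated
# individual's FC is appended until n_max.  Uses the caller's RNG stream.
ga_run <- function(fitness_fn, r, config, init_population = NULL,
                   collect = NULL) {
  bounds <- ga_bounds(config, r)
  np <- config$population_size
  d <- 2L * r
  pop <- matrix(NA_real_, np, d)
  if (!is.null(init_population)) {
    init <- do.call(rbind, lapply(init_population, function(p)
      if (inherits(p, "rsn_params")) unname(flatten_rsn_params(p)) else as.numeric(p)))
    k <- min(nrow(init), np)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  for (i in seq_len(np)) {
    if (anyNA(pop[i, ]))
      pop[i, ] <- runif(d, bounds[, "lower"], bounds[, "upper"])
  }

  evaluate <- function(v) {
    res <- tryCatch(fitness_fn(v), error = function(e) NULL)
    if (is.null(res) || !is.finite(res$gof)) return(list(gof = Inf, fc = NULL))
    if (!is.null(collect) && length(collect$fcs) < collect$n_max &&
        !is.null(res$fc) && res$gof <= (collect$threshold %||% Inf)) {
      collect$fcs[[length(collect$fcs) + 1L]] <- res$fc
      collect$params[[length(collect$params) + 1L]] <- v
    }
    res
  }

  evals <- lapply(seq_len(np), function(i) evaluate(pop[i, ]))
  fit <- vapply(evals, `[[`, 0, "gof")
  if (all(!is.finite(fit))) stop("fitting failed: all candidates unstable")
  best_fc <- evals[[which.min(fit)]]$fc

  trace <- data.frame(generation = 1L, best = min(fit),
                      mean = mean(fit[is.finite(fit)]))
  mut_sd <- config$mutation_sd_frac * (bounds[, "upper"] - bounds[, "lower"])

  gen <- 1L
  while (gen < config$max_generations) {
    if (!is.null(collect) && length(collect$fcs) >= collect$n_max) break
    ord <- order(fit)
    new_pop <- pop
    n_elite <- min(config$elite, np)
    new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    new_fit <- rep(Inf, np)
    new_fit[seq_len(n_elite)] <- fit[ord[seq_len(n_elite)]]

    tournament <- function() {
      cand <- sample.int(np, 2L)
      cand[which.min(fit[cand])]
    }
    for (i in (n_elite + 1L):np) {
      p1 <- pop[tournament(), ]
      child <- if (runif(1) < config$crossover_rate) {
        p2 <- pop[tournament(), ]
        mask <- runif(d) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      child <- child + rnorm(d, 0, mut_sd)
      new_pop[i, ] <- pmin(pmax(child, bounds[, "lower"]), bounds[, "upper"])
    }

    for (i in (n_elite + 1L):np) {
      res <- evaluate(new_pop[i, ])
      new_fit[i] <- res$gof
      if (res$gof <= min(new_fit[seq_len(i)]) && !is.null(res$fc))
        best_fc <- res$fc
    }
    pop <- new_pop
    fit <- new_fit
    gen <- gen + 1L
    mean_gof <- mean(fit[is.finite(fit)])
    trace <- rbind(trace, data.frame(generation = gen,
                                     best = min(trace$best, min(fit)),
                                     mean = mean_gof))
    dmean <- abs(trace$mean[gen - 1L] - mean_gof)
    if (dmean < config$convergence_tol) break
  }

  ord <- order(fit)
  list(best = pop[ord[1L], ], best_gof = fit[ord[1L]], best_fc = best_fc,
       population = pop, fitness = fit, trace = trace)
}

#' Fit a whole-brain Hopf model to a target functional connectivity
#'
#' The central fitting routine.  RSN-level bifurcation and coupling
#' parameters (2R in total; 16 for the default 8 RSNs) are optimised by an
#' elitist genetic algorithm that minimises the goodness of fit
#' `1 - corr(FC_target, FC_simulated)`, each candidate being scored by
#' simulating the coupled Stuart-Landau system on the structural connectome
#' and computing the band-passed Pearson FC.
#'
#' @param fc_target N x N empirical (or group-average) FC matrix.
#' @param sc N x N structural connectome.
#' @param omega per-node angular frequencies (rad/s), typically from
#'   [estimate_frequencies()].
#' @param parcellation parcellation table defining the RSN grouping.
#' @param config a [ga_config()].
#' @param sim a [sim_settings()].
#' @param band band-pass edges (Hz) applied to simulated signals.
#' @param label optional condition label carried along (used by [augment()]).
#' @param init_population optional list of [rsn_params()] (or flattened
#'   vectors) seeding the first generation.
#' @param seed integer seed for the whole optimisation.
#' @return An object of class `"hopf_fit"` with components `best`
#'   ([rsn_params()]), `gof`, `gof_trace`, `final_population`,
#'   `population_gof`, `fitted_fc`, and the inputs needed to simulate from
#'   the fitted model.  Methods: `print`, `summary`, `coef`, `plot`,
#'   `fitted`, `residuals`, `simulate`.
#' @examples
#' \donttest{
#' p <- generate_parcellation(12, 3, seed = 1)
#' sc <- generate_sc(p, seed = 2)
#' cond <- generate_condition_parameters("control", p,
#'   condition_effects(n_rsn = 3), seed = 3)
#' sim <- sim_settings(n_volumes = 60L)
#' pars <- expand_parameters(rsn_params(cond$rsn_bifurcations,
#'   cond$rsn_couplings), p, 2 * pi * cond$node_frequencies, sim)
#' target <- simulate_fc(pars, sc, seed = 4)
#' fit <- hopf_fit(target, sc, 2 * pi * cond$node_frequencies, p,
#'   config = ga_config(population_size = 6, max_generations = 3),
#'   sim = sim, seed = 5)
#' fit
#' }
#' @export
hopf_fit <- function(fc_target, sc, omega, parcellation,
                     config = ga_config(), sim = sim_settings(),
                     band = c(0.04, 0.07), label = NULL,
                     init_population = NULL, seed = NULL) {
  validate_parcellation(parcellation)
  r <- n_rsn_of(parcellation)
  sc <- as.matrix(sc)
  fitness_fn <- function(v) {
    pars <- expand_parameters(unflatten_rsn_params(v), parcellation, omega, sim)
    fc <- simulate_fc(pars, sc, n_realizations = config$n_realizations,
                      band = band)
    list(gof = goodness_of_fit(fc_target, fc), fc = fc)
  }
  res <- with_seed(seed, ga_run(fitness_fn, r, config,
                                init_population = init_population))
  out <- list(best = unflatten_rsn_params(res$best),
              gof = res$best_gof,
              gof_trace = res$trace,
              final_population = lapply(seq_len(nrow(res$population)),
                                        function(i) unflatten_rsn_params(res$population[i, ])),
              population_gof = res$fitness,
              fitted_fc = res$best_fc,
              fc_target = fc_target, sc = sc, omega = omega,
              parcellation = parcellation, config = config, sim = sim,
              band = band, label = label)
  class(out) <- "hopf_fit"
  out
}

#' @export
print.hopf_fit <- function(x, ...) {
  r <- length(x$best$a)
  cat("Whole-brain Hopf model fit",
      if (!is.null(x$label)) sprintf("(condition: %s)", x$label), "\n")
  cat(sprintf("  %d regions, %d RSNs (%d free parameters)\n",
              nrow(x$parcellation), r, 2L * r))
  cat(sprintf("  GoF = %.4f  (FC correlation %.4f) after %d generations\n",
              x$gof, 1 - x$gof, nrow(x$gof_trace)))
  invisible(x)
}

#' @export
summary.hopf_fit <- function(object, ...) {
  out <- list(label = object$label, gof = object$gof,
              coef = coef(object), trace = object$gof_trace,
              population_gof = object$population_gof)
  class(out) <- "summary.hopf_fit"
  out
}

#' @export
print.summary.hopf_fit <- function(x, ...) {
  cat("Hopf model fit", if (!is.null(x$label)) sprintf("(%s)", x$label), "\n")
  cat(sprintf("GoF: best %.4f, final population mean %.4f\n",
              x$gof, mean(x$population_gof[is.finite(x$population_gof)])))
  cat("RSN-level parameters (best individual):\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
coef.hopf_fit <- function(object, ...) flatten_rsn_params(object$best)

#' @export
fitted.hopf_fit <- function(object, ...) object$fitted_fc

#' @export
residuals.hopf_fit <- function(object, ...) object$fc_target - object$fitted_fc

#' @export
plot.hopf_fit <- function(x, ...) {
  tr <- x$gof_trace
  graphics::plot(tr$generation, tr$best, type = "b", pch = 19,
                 xlab = "generation", ylab = "GoF",
                 ylim = range(c(tr$best, tr$mean)), ...)
  graphics::lines(tr$generation, tr$mean, lty = 2, col = "grey40")
  graphics::legend("topright", c("best", "generation mean"),
                   lty = c(1, 2), pch = c(19, NA), col = c("black", "grey40"),
                   bty = "n")
  invisible(x)
}

#' Simulate functional connectivity from a fitted Hopf model
#'
#' Draws `nsim` FC matrices from the best individual's parameters with fresh
#' noise realisations.
#'
#' @param object a [hopf_fit()] object.
#' @param nsim number of FC matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return List of N x N FC matrices.
#' @export
simulate.hopf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  pars <- expand_parameters(object$best, object$parcellation, object$omega,
                            object$sim)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_fc(pars, object$sc, band = object$band)))
}

#' Dynamical data augmentation from fitted models
#'
#' Mass-produces labelled surrogate FC matrices for each condition by
#' restarting the genetic algorithm from a fit's final population: every
#' accepted individual — one whose GoF is at least as good as the running
#' generation-median — contributes its simulated FC (fresh noise
#' realisation) to the pool, and restart rounds continue until the
#' per-class quota is met.  The acceptance bar keeps the surrogate pool
#' concentrated around the class's fitted optimum instead of diluting it
#' with unselected mutants.  The default quota, 1,000 per class over three
#' classes, yields a balanced dataset of 3,000 surrogates.
#'
#' @param fits named list of [hopf_fit()] objects, one per class.
#' @param n_per_class surrogates per class (default 1000).
#' @param seed integer seed.
#' @return An object of class `"augmented_fcs"`: list with `fc` (list of
#'   matrices), `labels` (factor), and `params` (matrix of the generating
#'   flattened RSN parameters, one row per surrogate).
#' @export
augment <- function(fits, n_per_class = 1000L, seed = NULL) {
  if (n_per_class < 0) stop("n_per_class must be nonnegative")
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  n_per_class <- as.integer(n_per_class)
  with_seed(seed, {
    all_fcs <- list(); all_labels <- character(0); all_params <- NULL
    for (lab in names(fits)) {
      fit <- fits[[lab]]
      stopifnot(inherits(fit, "hopf_fit"))
      r <- length(fit$best$a)
      fitness_fn <- function(v) {
        pars <- expand_parameters(unflatten_rsn_params(v), fit$parcellation,
                                  fit$omega, fit$sim)
        fc <- simulate_fc(pars, fit$sc, band = fit$band)
        list(gof = goodness_of_fit(fit$fc_target, fc), fc = fc)
      }
      collect <- new.env()
      collect$fcs <- list(); collect$params <- list()
      collect$n_max <- n_per_class
      # acceptance bar: a surrogate's individual must be at least as fit as
      # the worst member of the saved population, anchoring the pool to the
      # class optimum without stalling collection
      gofs <- fit$population_gof[is.finite(fit$population_gof)]
      collect$threshold <- if (length(gofs)) max(gofs) else Inf
      while (length(collect$fcs) < n_per_class) {
        ga_run(fitness_fn, r, fit$config,
               init_population = fit$final_population, collect = collect)
      }
      keep <- seq_len(n_per_class)
      all_fcs <- c(all_fcs, collect$fcs[keep])
      all_labels <- c(all_labels, rep(lab, n_per_class))
      if (n_per_class > 0L)
        all_params <- rbind(all_params, do.call(rbind, collect$params[keep]))
    }
    out <- list(fc = all_fcs, labels = factor(all_labels, levels = names(fits)),
                params = all_params)
    class(out) <- "augmented_fcs"
    out
  })
}

#' @export
print.augmented_fcs <- function(x, ...) {
  cat("Augmented FC dataset:", length(x$fc), "surrogates\n")
  print(table(x$labels))
  invisible(x)
}

#' Feature matrix of vectorised FCs from an augmented dataset
#' @param dataset an [augment()] object (or list with `fc`).
#' @return n x N(N-1)/2 numeric matrix.
#' @export
fc_features <- function(dataset) {
  do.call(rbind, lapply(dataset$fc, vectorize_fc))
}

#' Model-parameter features per fitted individual
#'
#' One row per individual of each fit's final population, columns the
#' flattened RSN parameter set (16 columns for 8 RSNs: a and G per RSN),
#' with the class label attached.
#'
#' @param fits named list of [hopf_fit()] objects.
#' @return `data.frame` with 2R feature columns plus a `label` column.
#' @export
parameter_features <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  rows <- list(); labels <- character(0)
  for (lab in names(fits)) {
    pop <- fits[[lab]]$final_population
    rows <- c(rows, lapply(pop, function(p) flatten_rsn_params(p)))
    labels <- c(labels, rep(lab, length(pop)))
  }
  r <- length(fits[[1]]$best$a)
  if (2L * r != 16L)
    warning(sprintf("feature vectors have length %d (expected 16 for 8 RSNs)",
                    2L * r))
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- factor(labels, levels = names(fits))
  out
}
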