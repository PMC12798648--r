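#' Default forcing-amplitude grid
#'
#' Twelve log-spaced amplitudes between 0.001 and 0.5 (signal units per
#' time), bracketing the range from imperceptible to strongly entraining
#' forcing.
#'
#' @param n number of amplitudes.
#' @param range two-element amplitude range.
#' @return Numeric vector.
#' @export
default_amplitudes <- function(n = 12L, range = c(0.001, 0.5)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Perturb one node of a fitted model and reclassify
#'
#' Simulates the fitted whole-brain model with an additive periodic forcing
#' `F0 cos(omega0 t)` on one node (at that node's intrinsic frequency),
#' averages the band-passed FC over `n_realizations` noise realisations,
#' encodes it to the latent space, and classifies the latent coordinates
#' with a trained dense classifier.
#'
#' @param fit a [hopf_fit()] for the condition being perturbed.
#' @param node region index to force.
#' @param amplitude forcing strength F0 (>= 0).
#' @param vae trained [fc_vae()].
#' @param clf trained [fcn()].
#' @param n_realizations noise realisations averaged (default 3).
#' @param seed integer seed.
#' @return List with `class` (predicted label), `prob` (named probability
#'   vector summing to 1) and `fc` (the perturbed FC).
#' @export
perturb_and_classify <- function(fit, node, amplitude, vae, clf,
                                 n_realizations = 3L, seed = NULL) {
  stopifnot(inherits(fit, "hopf_fit"), inherits(vae, "fc_vae"),
            inherits(clf, "fcn"))
  pars <- expand_parameters(fit$best, fit$parcellation, fit$omega, fit$sim)
  frc <- forcing(node, amplitude, fit$omega[node])
  fc <- simulate_fc(pars, fit$sc, n_realizations = n_realizations,
                    seed = seed, band = fit$band, forcing = frc)
  z <- predict(vae, matrix(vectorize_fc(fc), 1), type = "latent")
  prob <- predict(clf, z, type = "prob")[1, ]
  list(class = names(prob)[which.max(prob)], prob = prob, fc = fc)
}

#' Node-by-amplitude perturbation sweep
#'
#' Applies [perturb_and_classify()] over every node and every amplitude in
#' the grid, producing the full perturbation response surface of a
#' condition: predicted class and classification confidence per (node,
#' amplitude) cell.
#'
#' @inheritParams perturb_and_classify
#' @param amplitudes forcing amplitudes (default [default_amplitudes()]).
#' @param nodes nodes to perturb (default all regions).
#' @return An object of class `"perturbation_grid"`: a `data.frame` with
#'   columns `node`, `amplitude`, `predicted` and one probability column per
#'   class (`p_<class>`), plus attributes `classes` and `original`.
#' @export
perturbation_sweep <- function(fit, vae, clf,
                               amplitudes = default_amplitudes(),
                               nodes = seq_len(nrow(fit$parcellation)),
                               n_realizations = 3L, seed = 1L) {
  if (!length(amplitudes)) stop("amplitude grid must be nonempty")
  rows <- vector("list", length(nodes) * length(amplitudes))
  k <- 0L
  for (node in nodes) {
    for (a in amplitudes) {
      k <- k + 1L
      res <- perturb_and_classify(fit, node, a, vae, clf,
                                  n_realizations = n_realizations,
                                  seed = seed + 7L * k)
      rows[[k]] <- c(node = node, amplitude = a, res$prob)
    }
  }
  grid <- as.data.frame(do.call(rbind, rows))
  classes <- clf$classes
  names(grid) <- c("node", "amplitude", paste0("p_", classes))
  pcols <- as.matrix(grid[, paste0("p_", classes), drop = FALSE])
  grid$predicted <- classes[max.col(pcols)]
  grid <- grid[, c("node", "amplitude", "predicted", paste0("p_", classes))]
  attr(grid, "classes") <- classes
  attr(grid, "original") <- fit$label
  class(grid) <- c("perturbation_grid", "data.frame")
  grid
}

#' Distil a perturbation grid into a perturbability map
#'
#' A node enters the map iff some forcing amplitude reclassifies the
#' condition (predicted class differs from the original) with confidence
#' above `threshold`; the map records, per node and induced target class,
#' the minimal amplitude achieving this.  The default threshold 0.6 is
#' twice the three-class chance level.
#'
#' @param grid a [perturbation_sweep()] result.
#' @param threshold confidence threshold in `(1/n_classes, 1]`.
#' @param original the unperturbed condition label; defaults to the label
#'   stored on the grid.
#' @return A `data.frame` of class `"perturbability_map"` with columns
#'   `node`, `from`, `to`, `min_amplitude`, `confidence`.
#' @export
perturbability_map <- function(grid, threshold = 0.6,
                               original = attr(grid, "original")) {
  classes <- attr(grid, "classes")
  if (is.null(original)) stop("original condition label unknown")
  if (threshold <= 1 / length(classes) || threshold > 1)
    stop("threshold must lie in (1/n_classes, 1]")
  conf <- apply(as.matrix(grid[, paste0("p_", classes), drop = FALSE]), 1, max)
  hit <- grid$predicted != original & conf > threshold
  rows <- list()
  for (node in unique(grid$node)) {
    for (to in setdiff(classes, original)) {
      sel <- hit & grid$node == node & grid$predicted == to
      if (!any(sel)) next
      amp <- min(grid$amplitude[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        node = node, from = original, to = to, min_amplitude = amp,
        confidence = conf[sel][which.min(grid$amplitude[sel])])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), from = character(0), to = character(0),
               min_amplitude = numeric(0), confidence = numeric(0))
  class(out) <- c("perturbability_map", "data.frame")
  out
}
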