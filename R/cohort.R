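#' Generate a synthetic brain parcellation
#'
#' Builds a ground-truth-known parcellation table: `n_regions` regions, each
#' assigned to exactly one of `n_rsn` resting-state networks (RSNs) and to a
#' hemisphere.  The default sizes emulate a 115-region cortical/subcortical
#' parcellation grouped into 8 RSNs.  Every RSN is guaranteed nonempty.
#'
#' @param n_regions number of regions (default 115).
#' @param n_rsn number of resting-state networks (default 8).
#' @param seed integer seed; fixed seed gives an identical table.
#' @return A `data.frame` of class `"parcellation"` with columns
#'   `region_id`, `name`, `hemisphere` and `rsn`.
#' @examples
#' p <- generate_parcellation(20, 4, seed = 1)
#' table(p$rsn)
#' @export
generate_parcellation <- function(n_regions = 115L, n_rsn = 8L, seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_rsn <- as.integer(n_rsn)
  if (n_rsn < 1L || n_regions < n_rsn)
    stop("invalid configuration: need n_regions >= n_rsn >= 1")
  with_seed(seed, {
    # first one region per RSN (nonempty guarantee), remainder at random
    rsn <- c(seq_len(n_rsn),
             sample.int(n_rsn, n_regions - n_rsn, replace = TRUE))
    rsn <- rsn[sample.int(n_regions)]
    hemi <- rep(c("left", "right"), length.out = n_regions)
    if (n_regions >= 5L) {
      # a few midline (subcortical-like) regions, as in real parcellations
      mid <- sample.int(n_regions, max(1L, round(n_regions / 23)))
      hemi[mid] <- "midline"
    }
    out <- data.frame(
      region_id = seq_len(n_regions),
      name = sprintf("region_%03d_%s", seq_len(n_regions), substr(hemi, 1, 1)),
      hemisphere = hemi,
      rsn = as.integer(rsn),
      stringsAsFactors = FALSE
    )
    class(out) <- c("parcellation", "data.frame")
    out
  })
}

validate_parcellation <- function(p) {
  stopifnot(is.data.frame(p),
            all(c("region_id", "name", "hemisphere", "rsn") %in% names(p)))
  n <- nrow(p)
  if (!identical(as.integer(p$region_id), seq_len(n)))
    stop("region ids must be unique and contiguous 1..N")
  if (anyNA(p$rsn) || any(p$rsn < 1L))
    stop("every region needs exactly one RSN assignment")
  invisible(p)
}

n_rsn_of <- function(p) max(as.integer(p$rsn))

#' Generate a modular synthetic structural connectome
#'
#' Draws a symmetric, nonnegative, zero-diagonal weight matrix over the
#' regions of a parcellation.  Edges within an RSN are more probable and
#' carry heavier (log-normal) weights than edges between RSNs, mimicking the
#' modular community structure of empirical fibre-density connectomes.  The
#' graph is forced to be connected and the matrix is normalised so the mean
#' node strength (row sum) is 1, which keeps coupling scales of order one.
#'
#' @param parcellation a [generate_parcellation()] table.
#' @param seed integer seed.
#' @param p_within,p_between edge probabilities within / between RSNs.
#' @param w_within multiplicative weight boost for within-RSN edges.
#' @return An N x N numeric matrix.
#' @export
generate_sc <- function(parcellation, seed = 1L,
                        p_within = 0.6, p_between = 0.25, w_within = 3) {
  validate_parcellation(parcellation)
  n <- nrow(parcellation)
  rsn <- parcellation$rsn
  with_seed(seed, {
    C <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        same <- rsn[i] == rsn[j]
        if (runif(1) < (if (same) p_within else p_between)) {
          w <- rlnorm(1, meanlog = 0, sdlog = 0.5)
          C[i, j] <- C[j, i] <- if (same) w_within * w else w
        }
      }
    }
    # stitch disconnected components together (rare at default densities)
    comp <- graph_components(C)
    while (max(comp) > 1L) {
      a <- sample(which(comp == 1L), 1L)
      b <- sample(which(comp == 2L), 1L)
      C[a, b] <- C[b, a] <- rlnorm(1, 0, 0.5)
      comp <- graph_components(C)
    }
    C / mean(rowSums(C))
  })
}

validate_sc <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (any(C < 0)) stop("structural connectome must be nonnegative")
  if (!isTRUE(all.equal(C, t(C)))) stop("structural connectome must be symmetric")
  if (any(diag(C) != 0)) stop("structural connectome must have a zero diagonal")
  if (!is_connected_graph(C)) stop("structural connectome must be connected")
  invisible(C)
}

#' Default condition effect configuration
#'
#' RSN-level offsets added to the baseline bifurcation (`da`) and coupling
#' (`dg`) parameters for each clinical condition.  Controls sit at the most
#' strongly subcritical baseline; each patient condition shifts a *disjoint
#' subset* of RSNs toward the bifurcation with weakened coupling
#' (odd-numbered RSNs for nonrelapsing, even-numbered for relapsing).
#' Patterned network involvement — different networks dysregulated in
#' different conditions — makes the conditions distinguishable in FC
#' pattern rather than merely in overall FC level.  Scalars are recycled
#' across RSNs.
#'
#' @param base_a baseline RSN bifurcation parameters (length `n_rsn` or 1).
#' @param base_g baseline RSN coupling scales (length `n_rsn` or 1).
#' @param offsets named list per condition with elements `da` and `dg`.
#' @param n_rsn number of RSNs (default 8).
#' @return A list of class `"effect_config"`.
#' @export
condition_effects <- function(
    base_a = seq(-0.10, -0.05, length.out = n_rsn),
    base_g = 2.0,
    offsets = NULL,
    n_rsn = 8L) {
  n_rsn <- as.integer(n_rsn)
  if (is.null(offsets)) {
    odd <- rep_len(c(1, 0), n_rsn)
    even <- 1 - odd
    offsets <- list(
      control      = list(da = 0,          dg = 0),
      nonrelapsing = list(da = 0.07 * odd,  dg = -1.2 * odd),
      relapsing    = list(da = 0.07 * even, dg = -1.2 * even))
  }
  out <- list(
    base_a = rep_len(base_a, n_rsn),
    base_g = rep_len(base_g, n_rsn),
    offsets = lapply(offsets, function(o)
      list(da = rep_len(o$da, n_rsn), dg = rep_len(o$dg, n_rsn))),
    n_rsn = n_rsn
  )
  class(out) <- "effect_config"
  out
}

#' Zero-effect configuration (all conditions identical)
#' @inheritParams condition_effects
#' @return A list of class `"effect_config"` whose offsets are all zero.
#' @export
null_effects <- function(n_rsn = 8L) {
  condition_effects(
    offsets = list(control      = list(da = 0, dg = 0),
                   nonrelapsing = list(da = 0, dg = 0),
                   relapsing    = list(da = 0, dg = 0)),
    n_rsn = n_rsn)
}

#' Ground-truth Hopf parameters for one clinical condition
#'
#' Combines the baseline RSN parameters with the condition's offsets,
#' samples per-node intrinsic frequencies uniformly inside the analysis
#' band (0.04-0.07 Hz), and draws a static node-level bifurcation offset
#' map (a "regional excitability map", standard deviation `hetero_sd`).
#' Both the frequencies and the excitability map depend on the seed but not
#' on the label, so conditions generated with the same seed share them and
#' differ only through their RSN-level (a, G) parameters.  Node-level
#' heterogeneity below the RSN resolution mirrors the regional gradients of
#' real cortex and prevents the ground truth from being perfectly
#' expressible by any RSN-level parameterisation.
#'
#' @param label condition label (must appear in `effect_config$offsets`).
#' @param parcellation a [generate_parcellation()] table.
#' @param effect_config a [condition_effects()] object.
#' @param seed integer seed (controls frequency and excitability sampling).
#' @param band frequency band in Hz.
#' @param hetero_sd SD of the node-level bifurcation offsets (default 0.05).
#' @return A list of class `"hopf_condition"` with elements `label`,
#'   `rsn_bifurcations`, `rsn_couplings`, `node_frequencies` (Hz) and
#'   `node_bifurcation_offsets`.
#' @export
generate_condition_parameters <- function(label, parcellation,
                                          effect_config = condition_effects(n_rsn = n_rsn_of(parcellation)),
                                          seed = 1L,
                                          band = c(0.04, 0.07),
                                          hetero_sd = 0.05) {
  validate_parcellation(parcellation)
  if (!label %in% names(effect_config$offsets))
    stop(sprintf("unknown condition label '%s'", label))
  if (effect_config$n_rsn != n_rsn_of(parcellation))
    stop("effect configuration and parcellation disagree on the number of RSNs")
  off <- effect_config$offsets[[label]]
  n <- nrow(parcellation)
  shared <- with_seed(seed, list(f = runif(n, band[1], band[2]),
                                 h = rnorm(n, 0, hetero_sd)))
  out <- list(
    label = label,
    rsn_bifurcations = effect_config$base_a + off$da,
    rsn_couplings = pmax(effect_config$base_g + off$dg, 0),
    node_frequencies = shared$f,
    node_bifurcation_offsets = shared$h
  )
  class(out) <- "hopf_condition"
  out
}

#' Simulation settings for synthetic BOLD recordings
#'
#' Defaults emulate the acquisition the generator mimics: repetition time
#' 1.92 s and a roughly eight-minute recording (240 volumes), integrated at
#' dt = 0.096 s (20 integration steps per volume) with a 19.2 s transient
#' discarded.
#'
#' @param dt integration step (s); must divide `tr` exactly.
#' @param tr repetition time (s).
#' @param n_volumes number of retained volumes.
#' @param transient initial transient to discard (s).
#' @param beta additive Gaussian noise standard deviation (default 0.02).
#' @return A list of class `"sim_settings"`.
#' @export
sim_settings <- function(dt = 0.096, tr = 1.92, n_volumes = 240L,
                         transient = 19.2, beta = 0.02) {
  stopifnot_scalar(dt, "dt"); stopifnot_scalar(tr, "tr")
  if (dt <= 0) stop("dt must be positive")
  decim <- tr / dt
  if (abs(decim - round(decim)) > 1e-8)
    stop("tr must be an integer multiple of dt")
  if (beta < 0) stop("beta must be nonnegative")
  out <- list(dt = dt, tr = tr, n_volumes = as.integer(n_volumes),
              transient = transient, beta = beta,
              decim = as.integer(round(decim)))
  class(out) <- "sim_settings"
  out
}

#' Generate a synthetic cohort of BOLD recordings
#'
#' Simulates one whole-brain Hopf recording per subject.  Each subject
#' inherits its condition's RSN-level parameters, perturbed by multiplicative
#' Gaussian jitter on the bifurcation parameters (between-subject
#' variability), and an independent noise realisation.  Default group sizes
#' are 128 controls, 37 nonrelapsing and 31 relapsing subjects (196 total).
#'
#' @param sc structural connectome matrix.
#' @param conditions named list of [generate_condition_parameters()] objects,
#'   one per requested label.
#' @param parcellation the parcellation the conditions refer to.
#' @param group_sizes named integer vector of subjects per label.
#' @param sim a [sim_settings()] object.
#' @param jitter_sd subject jitter on RSN bifurcations, as a fraction of the
#'   parameter magnitude (default 0.05).
#' @param seed integer seed; fixed seed reproduces the cohort bit-identically.
#' @return A list of class `"synthetic_cohort"`: `subjects` (each with
#'   `subject_id`, `condition`, `bold`), plus the `parcellation`, `sc` and
#'   `sim` used.
#' @export
generate_cohort <- function(sc, conditions, parcellation,
                            group_sizes = c(control = 128L, nonrelapsing = 37L,
                                            relapsing = 31L),
                            sim = sim_settings(), jitter_sd = 0.05,
                            seed = 1L) {
  validate_parcellation(parcellation)
  if (any(group_sizes < 0)) stop("group sizes must be nonnegative")
  missing_lab <- setdiff(names(group_sizes), names(conditions))
  if (length(missing_lab))
    stop(sprintf("unknown label '%s': no condition parameters supplied",
                 missing_lab[1]))
  rsn <- parcellation$rsn
  with_seed(seed, {
    subjects <- vector("list", sum(group_sizes))
    k <- 0L
    for (lab in names(group_sizes)) {
      cond <- conditions[[lab]]
      for (s in seq_len(group_sizes[[lab]])) {
        k <- k + 1L
        a_rsn <- cond$rsn_bifurcations *
          (1 + rnorm(length(cond$rsn_bifurcations), 0, jitter_sd))
        h <- cond$node_bifurcation_offsets %||% 0
        pars <- hopf_params(
          a = a_rsn[rsn] + h,
          g = cond$rsn_couplings[rsn],
          omega = 2 * pi * cond$node_frequencies,
          beta = sim$beta, dt = sim$dt, tr = sim$tr,
          n_volumes = sim$n_volumes, transient = sim$transient)
        subjects[[k]] <- list(
          subject_id = sprintf("sub-%03d", k),
          condition = lab,
          bold = simulate_hopf(pars, sc))
      }
    }
    out <- list(subjects = subjects, parcellation = parcellation,
                sc = sc, sim = sim)
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, "", "condition")
  cat("Synthetic cohort:", length(x$subjects), "subjects,",
      nrow(x$parcellation), "regions\n")
  print(table(condition = labs))
  invisible(x)
}

#' Condition labels of a cohort
#' @param cohort a [generate_cohort()] object.
#' @return Character vector of per-subject labels.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, `[[`, "", "condition")
}
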