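#' Node-level Hopf model parameters
#'
#' Full per-node parameterisation of the coupled Stuart-Landau system: for
#' node j, bifurcation parameter `a[j]` (noise-driven fixed point for a < 0,
#' limit cycle of amplitude sqrt(a) for a > 0), coupling scale `g[j]`
#' applied to the incoming difference coupling, and angular frequency
#' `omega[j]` (rad/s).  Additive Gaussian noise has standard deviation
#' `beta` (default 0.02).
#'
#' @param a,g,omega numeric vectors of equal length N.
#' @param beta noise standard deviation (signal units).
#' @param dt integration step (s); must divide `tr`.
#' @param tr output sampling interval (s).
#' @param n_volumes retained output samples.
#' @param transient initial time span discarded (s).
#' @return A list of class `"hopf_params"`.
#' @export
hopf_params <- function(a, g, omega, beta = 0.02, dt = 0.096, tr = 1.92,
                        n_volumes = 240L, transient = 19.2) {
  n <- length(a)
  if (length(g) != n || length(omega) != n)
    stop("a, g and omega must have equal length")
  if (beta < 0) stop("beta must be nonnegative")
  if (dt <= 0) stop("dt must be positive")
  duration <- transient + n_volumes * tr
  if (duration <= transient) stop("duration must exceed the transient")
  decim <- tr / dt
  if (abs(decim - round(decim)) > 1e-8)
    stop("tr must be an integer multiple of dt")
  structure(list(a = as.numeric(a), g = as.numeric(g),
                 omega = as.numeric(omega), beta = beta, dt = dt, tr = tr,
                 n_volumes = as.integer(n_volumes), transient = transient,
                 decim = as.integer(round(decim))),
            class = "hopf_params")
}

#' RSN-level parameter set
#'
#' One (bifurcation, coupling) pair per resting-state network; the model's
#' free parameters during fitting.  With the default 8 RSNs the flattened
#' vector has 16 entries.
#'
#' @param a,g numeric vectors of length R (number of RSNs).
#' @return A list of class `"rsn_params"`.
#' @export
rsn_params <- function(a, g) {
  if (length(a) != length(g)) stop("a and g must have equal length")
  structure(list(a = as.numeric(a), g = as.numeric(g)), class = "rsn_params")
}

#' Flatten an RSN parameter set to a named vector
#' @param x an [rsn_params()] object.
#' @return Numeric vector of length 2R, names `a_rsn1..., g_rsn1...`.
#' @export
flatten_rsn_params <- function(x) {
  r <- length(x$a)
  stats::setNames(c(x$a, x$g),
                  c(sprintf("a_rsn%d", seq_len(r)), sprintf("g_rsn%d", seq_len(r))))
}

unflatten_rsn_params <- function(v) {
  r <- length(v) / 2L
  rsn_params(v[seq_len(r)], v[r + seq_len(r)])
}

#' Expand RSN-level parameters to node-level Hopf parameters
#'
#' Every node inherits the (a, g) pair of its RSN: `a_j = a_rsn(j)`,
#' `g_j = g_rsn(j)`.
#'
#' @param rsn_params an [rsn_params()] object.
#' @param parcellation a [generate_parcellation()] table.
#' @param omega per-node angular frequencies (rad/s), length N.
#' @param sim a [sim_settings()] object supplying integration settings.
#' @return A [hopf_params()] object.
#' @export
expand_parameters <- function(rsn_params, parcellation, omega,
                              sim = sim_settings()) {
  validate_parcellation(parcellation)
  rsn <- as.integer(parcellation$rsn)
  if (max(rsn) > length(rsn_params$a))
    stop("region mapped to an RSN with no parameter pair")
  if (length(omega) != nrow(parcellation))
    stop("omega must have one entry per region")
  hopf_params(a = rsn_params$a[rsn], g = rsn_params$g[rsn], omega = omega,
              beta = sim$beta, dt = sim$dt, tr = sim$tr,
              n_volumes = sim$n_volumes, transient = sim$transient)
}

#' Periodic forcing specification
#'
#' Additive perturbation `F0 cos(omega0 t)` applied to the real part of one
#' node's dynamics — a conceptual model of external periodic stimulation at
#' that node's resonant frequency.
#'
#' @param node region index (1-based).
#' @param amplitude forcing strength F0 (signal units per time), >= 0.
#' @param frequency angular frequency omega0 (rad/s).
#' @return A list of class `"forcing"`.
#' @export
forcing <- function(node, amplitude, frequency) {
  if (amplitude < 0) stop("forcing amplitude must be nonnegative")
  if (node < 1) stop("invalid node index")
  structure(list(node = as.integer(node), amplitude = amplitude,
                 frequency = frequency), class = "forcing")
}

#' Simulate a whole-brain Hopf recording
#'
#' Euler-Maruyama integration of the coupled Stuart-Landau system on a
#' structural connectome, with difference coupling
#' `g_j * sum_i C_ij (x_i - x_j)` and optional additive periodic forcing on
#' one node.  The real parts x_j, decimated to the repetition time after
#' discarding the transient, form the BOLD-like output.  A fixed seed gives
#' bit-identical output.
#'
#' @param params a [hopf_params()] object.
#' @param sc N x N structural connectome.
#' @param forcing optional [forcing()] object.
#' @param seed optional integer seed.
#' @return A [bold_recording()] of dimension `n_volumes` x N.
#' @export
simulate_hopf <- function(params, sc, forcing = NULL, seed = NULL) {
  stopifnot(inherits(params, "hopf_params"))
  sc <- as.matrix(sc)
  n <- length(params$a)
  if (!all(dim(sc) == n)) stop("structural connectome must be N x N")
  n_burn <- as.integer(round(params$transient / params$dt))
  fnode <- 0L; famp <- 0; ffreq <- 0
  if (!is.null(forcing)) {
    if (forcing$node > n) stop("forced node index out of range")
    fnode <- forcing$node; famp <- forcing$amplitude; ffreq <- forcing$frequency
  }
  x <- with_seed(seed, .hopf_integrate(params$a, params$g, params$omega, sc,
                                       params$beta, params$dt, n_burn,
                                       params$n_volumes, params$decim,
                                       fnode, famp, ffreq))
  bold_recording(x, params$tr)
}

#' Simulated functional connectivity under a Hopf model
#'
#' Runs `n_realizations` independent simulations, band-passes each, computes
#' the Pearson FC, and returns the entrywise average.
#'
#' @inheritParams simulate_hopf
#' @param n_realizations number of noise realisations to average (>= 1).
#' @param band band-pass edges in Hz.
#' @return N x N functional connectivity matrix.
#' @export
simulate_fc <- function(params, sc, n_realizations = 1L, seed = NULL,
                        band = c(0.04, 0.07), forcing = NULL) {
  if (n_realizations < 1L) stop("n_realizations must be >= 1")
  with_seed(seed, {
    fcs <- lapply(seq_len(n_realizations), function(i)
      compute_fc(bandpass(simulate_hopf(params, sc, forcing = forcing),
                          band[1], band[2])))
    group_average_fc(fcs)
  })
}
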