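#' BOLD-like recording container
#'
#' @param data T x N numeric matrix (time by region).
#' @param tr repetition time in seconds.
#' @return A list of class `"bold_recording"`.
#' @export
bold_recording <- function(data, tr) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("a recording needs at least two time points")
  stopifnot_scalar(tr, "tr")
  structure(list(data = data, tr = tr), class = "bold_recording")
}

#' @export
print.bold_recording <- function(x, ...) {
  cat(sprintf("BOLD recording: %d volumes x %d regions, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

as_bold_matrix <- function(rec) {
  if (inherits(rec, "bold_recording")) rec$data else as.matrix(rec)
}

#' Band-pass filter a recording
#'
#' Detrends (linear) and demeans each regional signal, then applies a
#' zero-phase forward-backward order-2 Butterworth band-pass.  The default
#' band, 0.04-0.07 Hz, is the narrowband in which resting-state BOLD carries
#' the most reliable signal.  The output is demeaned.
#'
#' @param rec a [bold_recording()].
#' @param low,high band edges in Hz; `high` must lie below the Nyquist
#'   frequency `1 / (2 tr)`.
#' @return A filtered [bold_recording()].
#' @export
bandpass <- function(rec, low = 0.04, high = 0.07) {
  stopifnot(inherits(rec, "bold_recording"))
  nyq <- 1 / (2 * rec$tr)
  if (!(0 < low && low < high)) stop("need 0 < low < high")
  if (high >= nyq)
    stop(sprintf("invalid band: high edge %.4g Hz >= Nyquist %.4g Hz", high, nyq))
  x <- rec$data
  tt <- seq_len(nrow(x))
  x <- stats::lm.fit(cbind(1, tt), x)$residuals   # detrend + demean, all columns
  bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
  y <- .iir_filtfilt(as.numeric(bf$b), as.numeric(bf$a), as.matrix(x))
  y <- sweep(y, 2, colMeans(y))
  if (any(!is.finite(y))) stop("non-finite values after filtering")
  bold_recording(y, rec$tr)
}

#' Functional connectivity of a recording
#'
#' Pearson correlation between all pairs of regional signals.
#'
#' @param rec a [bold_recording()] or a T x N matrix.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(rec) {
  x <- as_bold_matrix(rec)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop(sprintf("degenerate signal: region(s) %s constant over time",
                 paste(bad, collapse = ", ")))
  }
  fc <- cor(x)
  diag(fc) <- 1
  fc
}

#' Average functional connectivity over subjects
#'
#' Entrywise mean of a list of FC matrices with the diagonal reset to 1
#' (Pearson self-correlation).
#'
#' @param fcs nonempty list of N x N matrices.
#' @return N x N matrix.
#' @export
group_average_fc <- function(fcs) {
  m <- average_matrices(fcs)
  diag(m) <- 1
  m
}

#' Average structural connectomes over subjects
#'
#' Entrywise mean of a list of SC matrices (edgewise averaging; the zero
#' diagonal is preserved by construction).
#'
#' @param scs nonempty list of N x N matrices.
#' @return N x N matrix.
#' @export
group_average_sc <- function(scs) {
  average_matrices(scs)
}

average_matrices <- function(ms) {
  if (!length(ms)) stop("cannot average an empty list of matrices")
  dims <- vapply(ms, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all matrices must share dimensions")
  Reduce(`+`, ms) / length(ms)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Hann-windowed periodogram; returns list(freq, power) with power a
# n_bins x N matrix (positive frequencies, excluding DC)
periodogram <- function(x, tr) {
  x <- as.matrix(x)
  n <- nrow(x)
  w <- hann_window(n)
  xw <- sweep(x, 2, colMeans(x)) * w
  sp <- Mod(stats::mvfft(xw))^2
  nb <- floor(n / 2)
  list(freq = (1:nb) / (n * tr), power = sp[2:(nb + 1L), , drop = FALSE])
}

#' Estimate intrinsic node frequencies from a set of recordings
#'
#' For each subject and region, the spectral peak is located as the argmax of
#' the Hann-windowed periodogram over the in-band bins (ties resolved toward
#' the lower frequency); the per-region intrinsic frequency is the mean peak
#' frequency across subjects.  Recordings are expected to be band-passed to
#' `band` already.
#'
#' @param recs list of [bold_recording()] objects (same N and TR).
#' @param band analysis band in Hz.
#' @return A list of class `"intrinsic_frequencies"` with `f` (Hz) and
#'   `omega` (= 2 pi f, rad/s).
#' @export
estimate_frequencies <- function(recs, band = c(0.04, 0.07)) {
  if (!length(recs)) stop("no recordings supplied")
  peaks <- vapply(recs, function(rec) {
    stopifnot(inherits(rec, "bold_recording"))
    pg <- periodogram(rec$data, rec$tr)
    inb <- which(pg$freq >= band[1] & pg$freq <= band[2])
    if (!length(inb)) stop("no spectral bins inside the analysis band")
    pw <- pg$power[inb, , drop = FALSE]
    if (all(pw == 0)) stop("flat spectra: cannot locate a peak")
    pg$freq[inb][apply(pw, 2, which.max)]
  }, numeric(ncol(recs[[1]]$data)))
  f <- if (is.matrix(peaks)) rowMeans(peaks) else mean(peaks)
  structure(list(f = f, omega = 2 * pi * f), class = "intrinsic_frequencies")
}

#' Vectorise a functional connectivity matrix
#'
#' Strict upper triangle in fixed row-major order: (1,2), (1,3), ...,
#' (1,N), (2,3), ...  This layout is frozen because it defines the input
#' ordering of the latent-space encoder.
#'
#' @param fc N x N matrix.
#' @return Numeric vector of length N(N-1)/2.
#' @seealso [devectorize_fc()]
#' @export
vectorize_fc <- function(fc) {
  fc <- as.matrix(fc)
  t(fc)[lower.tri(fc)]
}

#' Rebuild a symmetric matrix from its vectorised upper triangle
#'
#' Inverse of [vectorize_fc()]; the diagonal is set to 1.
#'
#' @param v vector of length N(N-1)/2.
#' @param n matrix dimension N.
#' @return N x N symmetric matrix with unit diagonal.
#' @export
devectorize_fc <- function(v, n) {
  if (length(v) != n * (n - 1) / 2)
    stop("vector length does not match n(n-1)/2")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v     # row-major upper triangle = column-major lower of t
  m <- t(m)
  m[lower.tri(m)] <- v
  diag(m) <- 1
  m
}
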