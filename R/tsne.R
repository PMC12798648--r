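# Exact (O(n^2)) t-SNE with perplexity calibration by binary search --
# sufficient for the dataset sizes handled here (hundreds to a few thousand
# samples).  Follows the standard recipe: conditional Gaussians in input
# space matched to the target perplexity, symmetrised joint P, Student-t
# kernel in the embedding, early exaggeration, gradient descent with
# momentum and adaptive per-coordinate gains.

tsne_p_matrix <- function(X, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(X)
  ss <- rowSums(X^2)
  D2 <- pmax(outer(ss, ss, `+`) - 2 * tcrossprod(X), 0)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; p <- w } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Two-dimensional t-SNE embedding
#'
#' Exact t-SNE (no tree approximation) over the rows of a feature matrix.
#' Inputs with more than 50 columns are first reduced to their leading 50
#' principal components.
#'
#' @param x n x d numeric matrix.
#' @param perplexity effective neighbourhood size (default 30, reduced
#'   automatically when n is small).
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed.
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, n_iter = 400L, seed = 1L) {
  X <- as.matrix(x)
  n <- nrow(X)
  if (n < 4L) stop("t-SNE needs at least 4 samples")
  perplexity <- min(perplexity, (n - 1) / 3)
  if (all(abs(sweep(X, 2, X[1, ])) < 1e-12))
    return(matrix(0, n, 2))   # degenerate input: all samples identical
  with_seed(seed, {
    if (ncol(X) > 50L) {
      X <- stats::prcomp(X, rank. = 50L, center = TRUE)$x
    }
    P <- tsne_p_matrix(X, perplexity)
    Y <- matrix(rnorm(n * 2, 0, 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exag_until <- min(100L, n_iter)
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= exag_until) P * 4 else P
      ss <- rowSums(Y^2)
      num <- 1 / (1 + pmax(outer(ss, ss, `+`) - 2 * tcrossprod(Y), 0))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it <= 250L) 0.5 else 0.8
      gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
      dY <- mom * dY - 200 * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Mean class-centroid distance in a t-SNE embedding
#'
#' Embeds the samples in two dimensions with [tsne_embed()] and returns the
#' mean pairwise Euclidean distance between class centroids — a scalar
#' summary of how separated the classes are in the embedding.
#'
#' @param x FC matrices (list or [augment()] dataset) or a feature matrix.
#' @param labels class labels (ignored when `x` is an augmented dataset
#'   carrying its own).
#' @param seed integer seed.
#' @param perplexity,n_iter passed to [tsne_embed()].
#' @return Scalar mean centroid distance, with the embedding attached as
#'   attribute `"embedding"`.
#' @export
tsne_class_distance <- function(x, labels = NULL, seed = 1L,
                                perplexity = 30, n_iter = 400L) {
  if (inherits(x, "augmented_fcs")) {
    labels <- labels %||% x$labels
    x <- fc_features(x)
  } else if (is.list(x) && !is.matrix(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, vectorize_fc))
  }
  X <- as.matrix(x)
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2L) stop("need at least two classes")
  Y <- tsne_embed(X, perplexity = perplexity, n_iter = n_iter, seed = seed)
  cents <- do.call(rbind, lapply(levels(y), function(l)
    colMeans(Y[y == l, , drop = FALSE])))
  out <- mean(stats::dist(cents))
  attr(out, "embedding") <- Y
  out
}
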