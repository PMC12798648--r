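#' Dense classifier configuration
#'
#' Defaults follow the classification protocol used throughout the package:
#' four sequentially linked dense layers of 64, 32 and 32 units plus a
#' class-sized softmax output, trained for 30 cycles at batch size 32 with
#' Adam at learning rate 0.001, holding out 20% of the training rows for
#' validation.
#'
#' @param hidden hidden-layer widths.
#' @param epochs training cycles.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac fraction of the training rows used for validation.
#' @param seed integer seed.
#' @return A list of class `"fcn_config"`.
#' @export
fcn_config <- function(hidden = c(64L, 32L, 32L), epochs = 30L,
                       batch_size = 32L, lr = 1e-3, val_frac = 0.2,
                       seed = 1L) {
  if (any(hidden < 1L)) stop("hidden widths must be positive")
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 val_frac = val_frac, seed = seed),
            class = "fcn_config")
}

fcn_init <- function(input_dim, hidden, n_classes) {
  sizes <- c(input_dim, hidden, n_classes)
  p <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    d <- nn_dense_init(sizes[i], sizes[i + 1L])
    p[[paste0("W", i)]] <- d$W
    p[[paste0("b", i)]] <- d$b
  }
  p
}

fcn_forward <- function(p, X) {
  nl <- length(p) / 2L
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- X
  for (i in seq_len(nl)) {
    z <- sweep(acts[[i]] %*% p[[paste0("W", i)]], 2, p[[paste0("b", i)]], `+`)
    acts[[i + 1L]] <- if (i < nl) relu(z) else z
  }
  list(acts = acts, probs = softmax_rows(acts[[nl + 1L]]))
}

fcn_step <- function(p, st, X, y_onehot, lr) {
  B <- nrow(X)
  nl <- length(p) / 2L
  fw <- fcn_forward(p, X)
  loss <- -sum(y_onehot * log(pmax(fw$probs, 1e-12))) / B
  delta <- (fw$probs - y_onehot) / B
  g <- list()
  for (i in nl:1) {
    g[[paste0("W", i)]] <- crossprod(fw$acts[[i]], delta)
    g[[paste0("b", i)]] <- colSums(delta)
    if (i > 1L)
      delta <- (delta %*% t(p[[paste0("W", i)]])) * (fw$acts[[i]] > 0)
  }
  upd <- adam_step(p, g, st, lr = lr)
  list(params = upd$params, state = upd$state, loss = loss)
}

#' Train a dense (fully connected) classifier
#'
#' Softmax classifier over latent coordinates or any feature matrix, with
#' ReLU hidden layers and cross-entropy loss.  An internal 80/20
#' train/validation split tracks validation accuracy per epoch.
#'
#' @param x n x d numeric feature matrix.
#' @param y factor (or coercible) of class labels, length n; at least two
#'   classes must be present.
#' @param config an [fcn_config()].
#' @return An object of class `"fcn"` with the trained weights, `classes`,
#'   `loss_trace` and `val_accuracy`.  Methods: `print`, `predict`
#'   (classes or class probabilities).
#' @export
fcn <- function(x, y, config = fcn_config()) {
  X <- as.matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("need at least two classes to train a classifier")
  if (nrow(X) != length(y)) stop("feature rows and labels differ in length")
  classes <- levels(y)
  k <- length(classes)
  Y <- diag(k)[as.integer(y), , drop = FALSE]

  with_seed(config$seed, {
    n <- nrow(X)
    n_val <- max(1L, round(config$val_frac * n))
    perm <- sample.int(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    if (!length(tr_idx)) { tr_idx <- val_idx }

    p <- fcn_init(ncol(X), config$hidden, k)
    st <- adam_init(p)
    trace <- numeric(config$epochs)
    val_acc <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      batches <- minibatch_indices(length(tr_idx), config$batch_size)
      ep_loss <- 0
      for (bi in batches) {
        rows <- tr_idx[bi]
        res <- fcn_step(p, st, X[rows, , drop = FALSE],
                        Y[rows, , drop = FALSE], config$lr)
        p <- res$params; st <- res$state
        ep_loss <- ep_loss + res$loss * length(rows)
      }
      trace[ep] <- ep_loss / length(tr_idx)
      pv <- fcn_forward(p, X[val_idx, , drop = FALSE])$probs
      val_acc[ep] <- mean(classes[max.col(pv)] == y[val_idx])
    }
    structure(list(params = p, classes = classes, config = config,
                   input_dim = ncol(X), loss_trace = trace,
                   val_accuracy = val_acc),
              class = "fcn")
  })
}

#' @export
print.fcn <- function(x, ...) {
  cat(sprintf("Dense classifier: %d -> %s -> %d classes\n", x$input_dim,
              paste(x$config$hidden, collapse = " -> "), length(x$classes)))
  cat(sprintf("  final validation accuracy %.3f\n",
              x$val_accuracy[length(x$val_accuracy)]))
  invisible(x)
}

#' Predict classes or class probabilities
#'
#' @param object an [fcn()] model.
#' @param newdata n x d feature matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return Factor of predicted classes, or an n x k matrix of class
#'   probabilities (rows sum to 1).
#' @export
predict.fcn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (is.null(dim(newdata)) && length(newdata) == object$input_dim) X <- t(X)
  if (ncol(X) != object$input_dim)
    stop(sprintf("input has %d features; the classifier expects %d",
                 ncol(X), object$input_dim))
  probs <- fcn_forward(object$params, X)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}
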