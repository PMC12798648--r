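#' Variational autoencoder configuration
#'
#' Defaults follow the training protocol the package implements throughout:
#' 10 training cycles (epochs) at batch size 128, Adam with learning rate
#' 1e-3, and a symmetric fully connected architecture
#' `input -> 512 -> 128 -> (mu, log sigma^2)` mirrored in the decoder.
#'
#' @param latent_dim dimension of the latent space (>= 1).
#' @param epochs training cycles over the data.
#' @param batch_size minibatch size.
#' @param hidden encoder hidden-layer widths (decoder mirrors them).
#' @param lr Adam learning rate.
#' @param normalize standardise each input feature (z-score) before
#'   training; reconstructions are mapped back to the original units.
#'   Without it the variance of the overall FC level dominates the
#'   reconstruction loss and drowns the pattern structure the embedding is
#'   meant to capture.
#' @param seed integer seed controlling initialisation, shuffling and the
#'   reparameterisation noise.
#' @return A list of class `"vae_config"`.
#' @export
vae_config <- function(latent_dim, epochs = 10L, batch_size = 128L,
                       hidden = c(512L, 128L), lr = 1e-3, normalize = TRUE,
                       seed = 1L) {
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 hidden = as.integer(hidden), lr = lr,
                 normalize = isTRUE(normalize), seed = seed),
            class = "vae_config")
}

vae_init <- function(input_dim, hidden, latent_dim) {
  h1 <- hidden[1]; h2 <- hidden[2]
  e1 <- nn_dense_init(input_dim, h1)
  e2 <- nn_dense_init(h1, h2)
  em <- nn_dense_init(h2, latent_dim)
  ev <- nn_dense_init(h2, latent_dim)
  d1 <- nn_dense_init(latent_dim, h2)
  d2 <- nn_dense_init(h2, h1)
  d3 <- nn_dense_init(h1, input_dim)
  list(W1 = e1$W, b1 = e1$b, W2 = e2$W, b2 = e2$b,
       Wm = em$W, bm = em$b, Wv = ev$W, bv = ev$b,
       W4 = d1$W, b4 = d1$b, W5 = d2$W, b5 = d2$b, W6 = d3$W, b6 = d3$b)
}

vae_encode_raw <- function(p, X) {
  h1 <- relu(sweep(X %*% p$W1, 2, p$b1, `+`))
  h2 <- relu(sweep(h1 %*% p$W2, 2, p$b2, `+`))
  mu <- sweep(h2 %*% p$Wm, 2, p$bm, `+`)
  lv <- pmin(pmax(sweep(h2 %*% p$Wv, 2, p$bv, `+`), -10), 10)
  list(h1 = h1, h2 = h2, mu = mu, lv = lv)
}

vae_decode_raw <- function(p, Z) {
  d1 <- relu(sweep(Z %*% p$W4, 2, p$b4, `+`))
  d2 <- relu(sweep(d1 %*% p$W5, 2, p$b5, `+`))
  xh <- sweep(d2 %*% p$W6, 2, p$b6, `+`)
  list(d1 = d1, d2 = d2, xh = xh)
}

# one training step on batch X; returns params/state plus the two loss terms
vae_step <- function(p, st, X, lr) {
  B <- nrow(X)
  enc <- vae_encode_raw(p, X)
  eps <- matrix(rnorm(B * ncol(enc$mu)), B)
  sdv <- exp(enc$lv / 2)
  Z <- enc$mu + sdv * eps
  dec <- vae_decode_raw(p, Z)

  recon <- 0.5 * sum((dec$xh - X)^2) / B
  kl <- -0.5 * sum(1 + enc$lv - enc$mu^2 - exp(enc$lv)) / B

  g <- list()
  dxh <- (dec$xh - X) / B
  g$W6 <- crossprod(dec$d2, dxh); g$b6 <- colSums(dxh)
  dd2 <- (dxh %*% t(p$W6)) * (dec$d2 > 0)
  g$W5 <- crossprod(dec$d1, dd2); g$b5 <- colSums(dd2)
  dd1 <- (dd2 %*% t(p$W5)) * (dec$d1 > 0)
  g$W4 <- crossprod(Z, dd1); g$b4 <- colSums(dd1)
  dZ <- dd1 %*% t(p$W4)
  dmu <- dZ + enc$mu / B
  dlv <- dZ * (0.5 * sdv * eps) + 0.5 * (exp(enc$lv) - 1) / B
  g$Wm <- crossprod(enc$h2, dmu); g$bm <- colSums(dmu)
  g$Wv <- crossprod(enc$h2, dlv); g$bv <- colSums(dlv)
  dh2 <- (dmu %*% t(p$Wm) + dlv %*% t(p$Wv)) * (enc$h2 > 0)
  g$W2 <- crossprod(enc$h1, dh2); g$b2 <- colSums(dh2)
  dh1 <- (dh2 %*% t(p$W2)) * (enc$h1 > 0)
  g$W1 <- crossprod(X, dh1); g$b1 <- colSums(dh1)

  upd <- adam_step(p, g, st, lr = lr)
  list(params = upd$params, state = upd$state, recon = recon, kl = kl)
}

#' Train a variational autoencoder on functional connectivity features
#'
#' Learns a low-dimensional probabilistic embedding of vectorised FC
#' matrices.  The encoder maps each FC upper triangle to a Gaussian in
#' latent space (mean and log-variance heads); the mirrored decoder maps
#' latent samples back to the input space; training minimises the usual
#' evidence lower bound (squared reconstruction error plus the KL divergence
#' to a standard normal) with Adam.
#'
#' @param x an [augment()] dataset, a list of FC matrices, or an
#'   n x D numeric matrix of already-vectorised features.
#' @param config a [vae_config()].
#' @return An object of class `"fc_vae"` with the trained weights, the
#'   config, `input_dim`, `n_regions` (when inputs were matrices) and a
#'   per-epoch `loss_trace` (`recon`, `kl`, `total`).  Methods: `print`,
#'   `predict` (latent means or reconstructions).
#' @export
fc_vae <- function(x, config) {
  stopifnot(inherits(config, "vae_config"))
  n_regions <- NA_integer_
  if (inherits(x, "augmented_fcs") || (is.list(x) && !is.matrix(x) && !is.data.frame(x))) {
    fcs <- if (inherits(x, "augmented_fcs")) x$fc else x
    n_regions <- nrow(fcs[[1]])
    X <- do.call(rbind, lapply(fcs, vectorize_fc))
  } else {
    X <- as.matrix(x)
  }
  if (!nrow(X)) stop("empty training set")
  input_dim <- ncol(X)
  if (is.na(n_regions)) {
    # infer the matrix size when the features are a vectorised upper triangle
    n_guess <- (1 + sqrt(1 + 8 * input_dim)) / 2
    if (abs(n_guess - round(n_guess)) < 1e-9) n_regions <- as.integer(round(n_guess))
  }
  if (config$latent_dim >= input_dim)
    stop("latent_dim must be smaller than the input dimension")

  if (config$normalize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale, `/`)
  } else {
    center <- rep(0, input_dim)
    scale <- rep(1, input_dim)
  }

  with_seed(config$seed, {
    p <- vae_init(input_dim, config$hidden, config$latent_dim)
    st <- adam_init(p)
    trace <- data.frame(epoch = integer(0), recon = numeric(0),
                        kl = numeric(0), total = numeric(0))
    for (ep in seq_len(config$epochs)) {
      batches <- minibatch_indices(nrow(X), config$batch_size)
      ep_recon <- 0; ep_kl <- 0
      for (bi in batches) {
        res <- vae_step(p, st, X[bi, , drop = FALSE], config$lr)
        p <- res$params; st <- res$state
        ep_recon <- ep_recon + res$recon * length(bi)
        ep_kl <- ep_kl + res$kl * length(bi)
      }
      trace <- rbind(trace, data.frame(epoch = ep,
                                       recon = ep_recon / nrow(X),
                                       kl = ep_kl / nrow(X),
                                       total = (ep_recon + ep_kl) / nrow(X)))
    }
    structure(list(params = p, config = config, input_dim = input_dim,
                   n_regions = n_regions, center = center, scale = scale,
                   loss_trace = trace),
              class = "fc_vae")
  })
}

#' @export
print.fc_vae <- function(x, ...) {
  cat(sprintf("Variational autoencoder: %d -> %s -> %d (latent)\n",
              x$input_dim, paste(x$config$hidden, collapse = " -> "),
              x$config$latent_dim))
  n <- nrow(x$loss_trace)
  cat(sprintf("  trained %d epochs; ELBO loss %.3f -> %.3f\n",
              n, x$loss_trace$total[1], x$loss_trace$total[n]))
  invisible(x)
}

vae_features <- function(object, newdata) {
  X <- if (is.matrix(newdata) && nrow(newdata) == ncol(newdata) &&
           nrow(newdata) * (nrow(newdata) - 1) / 2 == object$input_dim) {
    matrix(vectorize_fc(newdata), 1)
  } else if (is.list(newdata) && !is.matrix(newdata)) {
    fcs <- if (inherits(newdata, "augmented_fcs")) newdata$fc else newdata
    do.call(rbind, lapply(fcs, vectorize_fc))
  } else {
    m <- as.matrix(newdata)
    if (is.null(dim(newdata)) && length(newdata) == object$input_dim) t(m) else m
  }
  if (ncol(X) != object$input_dim)
    stop(sprintf("input has %d features; the encoder expects %d",
                 ncol(X), object$input_dim))
  X
}

#' Encode or reconstruct with a trained VAE
#'
#' @param object an [fc_vae()] model.
#' @param newdata FC matrix/matrices or a feature matrix.
#' @param type `"latent"` returns the variational mean vectors
#'   (deterministic — no sampling at inference); `"reconstruction"` returns
#'   decoded feature vectors.
#' @param ... unused.
#' @return n x latent_dim matrix, or n x input_dim matrix of
#'   reconstructions.
#' @export
predict.fc_vae <- function(object, newdata,
                           type = c("latent", "reconstruction"), ...) {
  type <- match.arg(type)
  X <- vae_features(object, newdata)
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  enc <- vae_encode_raw(object$params, X)
  if (type == "latent") return(enc$mu)
  xh <- vae_decode_raw(object$params, enc$mu)$xh
  sweep(sweep(xh, 2, object$scale, `*`), 2, object$center, `+`)
}

#' Latent coordinates of FC matrices
#' @inheritParams predict.fc_vae
#' @return n x latent_dim matrix of variational means.
#' @export
encode_fc <- function(object, newdata) predict(object, newdata, type = "latent")

#' Reconstruct a functional connectivity matrix through the VAE
#'
#' Encodes to the latent mean, decodes, and rebuilds a valid FC matrix:
#' symmetric, unit diagonal, entries clipped to `[-1, 1]`.
#'
#' @param object an [fc_vae()] model.
#' @param fc a single N x N FC matrix.
#' @return N x N reconstructed FC matrix.
#' @export
reconstruct_fc <- function(object, fc) {
  v <- predict(object, fc, type = "reconstruction")
  n <- object$n_regions
  if (is.na(n)) n <- (1 + sqrt(1 + 8 * ncol(v))) / 2
  devectorize_fc(pmin(pmax(as.numeric(v[1, ]), -1), 1), as.integer(round(n)))
}
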