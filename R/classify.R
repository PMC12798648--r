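#' Repeated cross-validated classification with a fixed holdout
#'
#' The evaluation protocol used for every feature set in the package: a
#' holdout of `holdout` samples is isolated once and never enters any
#' training fold; the remaining rows are split into `cv_folds` folds; for
#' each fold a fresh dense classifier is trained on the other folds (with
#' its internal 80/20 train/validation split) and evaluated on the holdout;
#' a repetition's accuracy is the mean over folds, and the whole procedure
#' is repeated `n_repetitions` times with different shuffles and
#' initialisations.
#'
#' @param features n x d numeric matrix.
#' @param labels factor of length n.
#' @param n_repetitions repetitions (default 100).
#' @param holdout number of samples isolated for testing (default 100).
#' @param cv_folds folds (default 5).
#' @param config an [fcn_config()].
#' @param seed master seed; repetition i derives its seed as `seed + i`.
#' @return An object of class `"classifier_report"`: `accuracies` (one per
#'   repetition), `mean`, `sd`, `confusion` (holdout confusion matrix of the
#'   final repetition's final fold; rows = true classes), `holdout_idx`.
#' @export
classify_embedding <- function(features, labels, n_repetitions = 100L,
                               holdout = 100L, cv_folds = 5L,
                               config = fcn_config(), seed = 1L) {
  X <- as.matrix(features)
  y <- droplevels(factor(labels))
  n <- nrow(X)
  if (n != length(y)) stop("feature rows and labels differ in length")
  if (holdout + cv_folds > n)
    stop("dataset too small for the requested holdout and folds")
  holdout_idx <- with_seed(seed, sample.int(n, holdout))
  rest <- setdiff(seq_len(n), holdout_idx)
  accs <- numeric(n_repetitions)
  confusion <- NULL
  for (i in seq_len(n_repetitions)) {
    rep_seed <- seed + i
    fold_of <- with_seed(rep_seed,
                         sample(rep_len(seq_len(cv_folds), length(rest))))
    fold_acc <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- rest[fold_of != f]
      cfg <- config
      cfg$seed <- rep_seed * 101L + f
      model <- fcn(X[tr, , drop = FALSE], y[tr], cfg)
      pred <- predict(model, X[holdout_idx, , drop = FALSE])
      fold_acc[f] <- mean(as.character(pred) == as.character(y[holdout_idx]))
      if (i == n_repetitions && f == cv_folds)
        confusion <- table(true = y[holdout_idx],
                           predicted = factor(pred, levels = levels(y)))
    }
    accs[i] <- mean(fold_acc)
  }
  structure(list(accuracies = accs, mean = mean(accs), sd = stats::sd(accs),
                 confusion = confusion, holdout_idx = holdout_idx,
                 n = n, classes = levels(y)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Classifier report: accuracy %.3f +/- %.3f over %d repetitions\n",
              x$mean, x$sd, length(x$accuracies)))
  if (!is.null(x$confusion)) {
    cat("Holdout confusion matrix (final repetition):\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Latent-dimension sweep
#'
#' For each latent dimension, trains a VAE on the full dataset, encodes every
#' sample to its latent mean, and evaluates classification accuracy with
#' [classify_embedding()].  Reports the per-dimension accuracy distribution
#' and an elbow estimate: the smallest dimension whose mean accuracy comes
#' within one standard deviation of the best mean.
#'
#' @param dataset an [augment()] object (or any list with `fc` and `labels`).
#' @param dims latent dimensions to evaluate (default 2:12).
#' @param n_repetitions,holdout,cv_folds see [classify_embedding()].
#' @param vae_epochs,vae_batch_size VAE training settings.
#' @param config an [fcn_config()].
#' @param seed master seed.
#' @return An object of class `"dimension_sweep"`: `table`
#'   (`data.frame(dim, mean_accuracy, sd_accuracy)`), `reports` (per-dim
#'   [classify_embedding()] reports), `elbow`.
#' @export
dimension_sweep <- function(dataset, dims = 2:12, n_repetitions = 100L,
                            holdout = 100L, cv_folds = 5L,
                            vae_epochs = 10L, vae_batch_size = 128L,
                            config = fcn_config(), seed = 1L) {
  features <- fc_features(dataset)
  labels <- dataset$labels
  if (any(dims < 1L) || any(dims >= ncol(features)))
    stop("latent dimensions must lie in [1, input_dim)")
  reports <- vector("list", length(dims))
  names(reports) <- as.character(dims)
  for (k in seq_along(dims)) {
    d <- dims[k]
    vae <- fc_vae(features, vae_config(latent_dim = d, epochs = vae_epochs,
                                       batch_size = vae_batch_size,
                                       seed = seed + 1000L * d))
    emb <- predict(vae, features, type = "latent")
    reports[[k]] <- classify_embedding(emb, labels,
                                       n_repetitions = n_repetitions,
                                       holdout = holdout, cv_folds = cv_folds,
                                       config = config, seed = seed)
  }
  tab <- data.frame(
    dim = dims,
    mean_accuracy = vapply(reports, `[[`, 0, "mean"),
    sd_accuracy = vapply(reports, `[[`, 0, "sd"))
  best <- which.max(tab$mean_accuracy)
  elbow <- min(tab$dim[tab$mean_accuracy >=
                         tab$mean_accuracy[best] - tab$sd_accuracy[best]])
  structure(list(table = tab, reports = reports, elbow = elbow),
            class = "dimension_sweep")
}

#' @export
print.dimension_sweep <- function(x, ...) {
  cat("Latent-dimension sweep:\n")
  print(x$table, row.names = FALSE)
  cat("Elbow (smallest dimension within 1 SD of the best):", x$elbow, "\n")
  invisible(x)
}

#' @export
plot.dimension_sweep <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$dim, tab$mean_accuracy, type = "b", pch = 19,
                 xlab = "latent dimension", ylab = "holdout accuracy", ...)
  graphics::arrows(tab$dim, tab$mean_accuracy - tab$sd_accuracy,
                   tab$dim, tab$mean_accuracy + tab$sd_accuracy,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(v = x$elbow, lty = 3)
  invisible(x)
}

#' Scrambled-label null distribution of classification accuracy
#'
#' Re-runs the classification protocol with labels randomly permuted for
#' each repetition, yielding the chance-level accuracy distribution.  For a
#' balanced three-class problem the null mean sits at 1/3.
#'
#' @inheritParams classify_embedding
#' @param observed observed mean accuracy to test (optional); the p-value is
#'   the fraction of null accuracies at or above it.
#' @return An object of class `"null_report"`: `accuracies`, `mean`, `sd`,
#'   `p_value` (or `NA`).
#' @export
scrambled_null <- function(features, labels, n_repetitions = 100L,
                           holdout = 100L, cv_folds = 5L,
                           config = fcn_config(), seed = 1L,
                           observed = NULL) {
  X <- as.matrix(features)
  y <- droplevels(factor(labels))
  accs <- numeric(n_repetitions)
  for (i in seq_len(n_repetitions)) {
    y_perm <- with_seed(seed + 31L * i, sample(y))
    rep <- classify_embedding(X, y_perm, n_repetitions = 1L,
                              holdout = holdout, cv_folds = cv_folds,
                              config = config, seed = seed + 31L * i)
    accs[i] <- rep$mean
  }
  p <- if (is.null(observed)) NA_real_ else mean(accs >= observed)
  structure(list(accuracies = accs, mean = mean(accs), sd = stats::sd(accs),
                 p_value = p, observed = observed %||% NA_real_),
            class = "null_report")
}

#' @export
print.null_report <- function(x, ...) {
  cat(sprintf("Scrambled-label null: accuracy %.3f +/- %.3f\n", x$mean, x$sd))
  if (!is.na(x$p_value))
    cat(sprintf("  observed %.3f, p = %.3f\n", x$observed, x$p_value))
  invisible(x)
}

#' Baseline classifiers over alternative feature sets
#'
#' Applies the [classify_embedding()] protocol to each supplied feature set
#' (for example raw vectorised FCs, VAE-encoded empirical FCs, or the 2R
#' model-parameter features) and tabulates the accuracies.  Feature sets
#' given as `NULL` are skipped with a warning.
#'
#' @param feature_sets named list; each element is a list with `features`
#'   (matrix) and `labels` (factor).
#' @inheritParams classify_embedding
#' @return `data.frame` with columns `feature_set`, `n_features`,
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
baseline_classifiers <- function(feature_sets, n_repetitions = 100L,
                                 holdout = 100L, cv_folds = 5L,
                                 config = fcn_config(), seed = 1L) {
  rows <- list()
  for (nm in names(feature_sets)) {
    fs <- feature_sets[[nm]]
    if (is.null(fs) || is.null(fs$features)) {
      warning(sprintf("feature set '%s' missing; skipped", nm))
      next
    }
    rep <- classify_embedding(fs$features, fs$labels,
                              n_repetitions = n_repetitions,
                              holdout = holdout, cv_folds = cv_folds,
                              config = config, seed = seed)
    rows[[nm]] <- data.frame(feature_set = nm,
                             n_features = ncol(as.matrix(fs$features)),
                             mean_accuracy = rep$mean,
                             sd_accuracy = rep$sd)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
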