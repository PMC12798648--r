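#' Pipeline configuration
#'
#' Bundles every stage's settings with a single master seed that fans out to
#' per-stage seeds by fixed offsets.  Defaults reproduce the full study
#' conditions (115 regions / 8 RSNs, cohort 128/37/31, 1,000 surrogates per
#' class, latent dimensions 2-12, 100 classifier repetitions); smaller
#' values give a fast smoke run.
#'
#' @param n_regions,n_rsn parcellation size.
#' @param group_sizes named subjects-per-condition vector.
#' @param n_per_class surrogates per class in the augmentation stage.
#' @param dims latent dimensions to sweep.
#' @param n_repetitions,holdout,cv_folds classifier protocol.
#' @param band analysis band (Hz).
#' @param sim a [sim_settings()] list.
#' @param ga a [ga_config()] list.
#' @param fcn an [fcn_config()] list.
#' @param amplitudes perturbation amplitude grid.
#' @param perturb_conditions labels whose fitted models are perturbed.
#' @param perturb_dim latent dimension used for perturbation classification.
#' @param stages character vector of stages to run, in order.
#' @param seed master seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_regions = 115L, n_rsn = 8L,
                            group_sizes = c(control = 128L,
                                            nonrelapsing = 37L,
                                            relapsing = 31L),
                            n_per_class = 1000L,
                            dims = 2:12, n_repetitions = 100L,
                            holdout = 100L, cv_folds = 5L,
                            band = c(0.04, 0.07),
                            sim = sim_settings(), ga = ga_config(),
                            fcn = fcn_config(),
                            amplitudes = default_amplitudes(),
                            perturb_conditions = c("relapsing", "nonrelapsing"),
                            perturb_dim = 8L,
                            stages = c("cohort", "prep", "fit", "augment",
                                       "vae", "classify", "perturb"),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override [pipeline_config()] defaults;
#' nested blocks `sim`, `ga` and `fcn` override the corresponding
#' constructor arguments.
#'
#' @param path YAML file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  direct <- intersect(names(y), setdiff(names(formals(pipeline_config)),
                                        c("sim", "ga", "fcn")))
  args[direct] <- y[direct]
  if (!is.null(y$group_sizes)) args$group_sizes <- unlist(y$group_sizes)
  if (!is.null(y$sim)) args$sim <- do.call(sim_settings, y$sim)
  if (!is.null(y$ga)) args$ga <- do.call(ga_config, y$ga)
  if (!is.null(y$fcn)) args$fcn <- do.call(fcn_config, y$fcn)
  do.call(pipeline_config, args)
}

log_stage <- function(con, stage, msg) {
  line <- jsonlite::toJSON(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                stage = stage, message = msg),
                           auto_unbox = TRUE)
  writeLines(as.character(line), con)
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: synthetic cohort generation, preprocessing
#' (band-pass, FC, group averages, intrinsic frequencies), per-condition
#' model fitting, data augmentation, VAE training, classification
#' (dimension sweep plus scrambled-label null), and the in-silico
#' perturbation sweep with perturbability maps.  Artifacts are written as
#' TSV/CSV/JSON under `out_dir`, together with a manifest recording the
#' config hash and derived seeds.  Any stage failure halts with the stage
#' name and cause.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "pipeline.log.jsonl")
  con <- file(logfile, open = "a")
  on.exit(close(con))

  seeds <- list(cohort = config$seed, prep = config$seed + 100L,
                fit = config$seed + 200L, augment = config$seed + 300L,
                vae = config$seed + 400L, classify = config$seed + 500L,
                perturb = config$seed + 600L)
  state <- list()
  labels <- names(config$group_sizes)

  run_stage <- function(stage, body) {
    if (!stage %in% config$stages) {
      log_stage(con, stage, "skipped")
      return(invisible(NULL))
    }
    log_stage(con, stage, "started")
    tryCatch(body(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  run_stage("cohort", function() {
    parc <- generate_parcellation(config$n_regions, config$n_rsn,
                                  seed = seeds$cohort)
    sc <- generate_sc(parc, seed = seeds$cohort + 1L)
    eff <- condition_effects(n_rsn = config$n_rsn)
    conds <- lapply(labels, function(l)
      generate_condition_parameters(l, parc, eff, seed = seeds$cohort + 2L,
                                    band = config$band))
    names(conds) <- labels
    cohort <- generate_cohort(sc, conds, parc,
                              group_sizes = config$group_sizes,
                              sim = config$sim, seed = seeds$cohort + 3L)
    write_parcellation(parc, file.path(out_dir, "parcellation.tsv"))
    write_matrix_tsv(sc, file.path(out_dir, "sc.tsv"))
    state[c("parc", "sc", "conds", "cohort")] <<-
      list(parc, sc, conds, cohort)
    log_stage(con, "cohort", sprintf("%d subjects", length(cohort$subjects)))
  })

  run_stage("prep", function() {
    cohort <- state$cohort
    labs <- cohort_labels(cohort)
    filtered <- lapply(cohort$subjects, function(s)
      bandpass(s$bold, config$band[1], config$band[2]))
    fcs <- lapply(filtered, compute_fc)
    group_fc <- lapply(labels, function(l) group_average_fc(fcs[labs == l]))
    names(group_fc) <- labels
    freqs <- lapply(labels, function(l)
      estimate_frequencies(filtered[labs == l], band = config$band))
    names(freqs) <- labels
    for (l in labels)
      write_matrix_tsv(group_fc[[l]],
                       file.path(out_dir, sprintf("fc_group_%s.tsv", l)))
    state[c("group_fc", "freqs")] <<- list(group_fc, freqs)
    log_stage(con, "prep", "group FCs and intrinsic frequencies computed")
  })

  run_stage("fit", function() {
    fits <- lapply(labels, function(l)
      hopf_fit(state$group_fc[[l]], state$sc, state$freqs[[l]]$omega,
               state$parc, config = config$ga, sim = config$sim,
               band = config$band, label = l,
               seed = seeds$fit + match(l, labels)))
    names(fits) <- labels
    for (l in labels)
      jsonlite::write_json(as.list(coef(fits[[l]])),
                           file.path(out_dir, sprintf("fit_%s.json", l)),
                           auto_unbox = TRUE, digits = NA)
    state$fits <<- fits
    log_stage(con, "fit", paste("GoF:", paste(sprintf(
      "%s=%.3f", labels, vapply(fits, `[[`, 0, "gof")), collapse = " ")))
  })

  run_stage("augment", function() {
    dataset <- augment(state$fits, n_per_class = config$n_per_class,
                       seed = seeds$augment)
    utils::write.csv(data.frame(index = seq_along(dataset$fc),
                                label = dataset$labels),
                     file.path(out_dir, "augmented_labels.csv"),
                     row.names = FALSE)
    state$dataset <<- dataset
    log_stage(con, "augment", sprintf("%d surrogate FCs", length(dataset$fc)))
  })

  run_stage("vae", function() {
    features <- fc_features(state$dataset)
    vaes <- lapply(config$dims, function(d)
      fc_vae(features, vae_config(latent_dim = d, seed = seeds$vae + d)))
    names(vaes) <- as.character(config$dims)
    state[c("features", "vaes")] <<- list(features, vaes)
    log_stage(con, "vae", sprintf("trained %d VAEs (dims %s)",
                                  length(vaes),
                                  paste(range(config$dims), collapse = "-")))
  })

  run_stage("classify", function() {
    sweep <- dimension_sweep(state$dataset, dims = config$dims,
                             n_repetitions = config$n_repetitions,
                             holdout = config$holdout,
                             cv_folds = config$cv_folds,
                             config = config$fcn, seed = seeds$classify)
    utils::write.csv(sweep$table, file.path(out_dir, "dimension_sweep.csv"),
                     row.names = FALSE)
    state$sweep <<- sweep
    log_stage(con, "classify", sprintf("elbow at dimension %d", sweep$elbow))
  })

  run_stage("perturb", function() {
    targets <- intersect(config$perturb_conditions, labels)
    if (!length(targets)) {
      log_stage(con, "perturb", "no conditions requested; nothing to do")
      return(invisible(NULL))
    }
    d <- as.character(config$perturb_dim)
    vae <- state$vaes[[d]]
    if (is.null(vae)) {   # perturbation dimension not part of the sweep
      vae <- fc_vae(state$features,
                    vae_config(latent_dim = config$perturb_dim,
                               seed = seeds$vae + config$perturb_dim))
    }
    emb <- predict(vae, state$features, type = "latent")
    cfg <- config$fcn
    cfg$seed <- seeds$perturb
    clf <- fcn(emb, state$dataset$labels, cfg)
    maps <- list()
    for (l in targets) {
      grid <- perturbation_sweep(state$fits[[l]], vae, clf,
                                 amplitudes = config$amplitudes,
                                 seed = seeds$perturb + match(l, labels))
      utils::write.csv(grid, file.path(out_dir, sprintf("grid_%s.csv", l)),
                       row.names = FALSE)
      map <- perturbability_map(grid)
      utils::write.csv(map, file.path(out_dir, sprintf("map_%s.csv", l)),
                       row.names = FALSE)
      maps[[l]] <- list(grid = grid, map = map)
    }
    state$perturb <<- maps
    log_stage(con, "perturb", "perturbation grids and maps written")
  })

  cfg_path <- file.path(out_dir, "config.json")
  cfg_json <- config
  cfg_json$stages <- as.list(cfg_json$stages)
  jsonlite::write_json(lapply(unclass(cfg_json), unclass), cfg_path,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    package = "hopfbrain",
    version = as.character(utils::packageVersion("hopfbrain")),
    config_hash = unname(tools::md5sum(cfg_path)),
    master_seed = config$seed,
    stage_seeds = seeds,
    stages_run = intersect(config$stages,
                           c("cohort", "prep", "fit", "augment", "vae",
                             "classify", "perturb")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  log_stage(con, "pipeline", "finished")
  invisible(c(state, list(manifest = manifest)))
}
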