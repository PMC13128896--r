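#' Build the model design matrix (selected CpGs + sex)
#'
#' Rows follow `meta` order; columns are the feature-set CpGs in contract
#' order followed by a binary sex indicator (0 = female, 1 = male).
#'
#' @param m probes x samples beta matrix (imputed; no missing values among
#'   the selected features)
#' @param meta sample sheet; `sample_id` must index columns of `m`
#' @param features a `feature_set` or character vector of CpG IDs
#' @return samples x (features + 1) numeric matrix with a `"sex"` column
#' @export
make_design <- function(m, meta, features) {
  if (inherits(features, "feature_set")) features <- features$features
  missing_feat <- setdiff(features, rownames(m))
  if (length(missing_feat))
    stop("features absent from the beta matrix: ",
         paste(missing_feat[1:min(5, length(missing_feat))], collapse = ", "),
         call. = FALSE)
  missing_samp <- setdiff(meta$sample_id, colnames(m))
  if (length(missing_samp))
    stop("samples absent from the beta matrix: ",
         paste(missing_samp[1:min(5, length(missing_samp))], collapse = ", "),
         call. = FALSE)
  if (anyNA(meta$sex))
    stop("missing sex for samples ",
         paste(meta$sample_id[is.na(meta$sex)][1:min(5, sum(is.na(meta$sex)))],
               collapse = ", "), call. = FALSE)
  X <- t(m[features, meta$sample_id, drop = FALSE])
  X <- cbind(X, sex = as.numeric(meta$sex))
  rownames(X) <- meta$sample_id
  X
}

#' Train a leave-one-cohort-out ensemble
#'
#' One submodel per held-out cohort: the submodel never sees any sample of
#' its excluded cohort. Within each fold's training pool an 80:20 split is
#' drawn (seeded); the 80 percent side trains the network and the 20 percent
#' side gives an internal test MAE. The excluded cohort provides the fold's
#' held-out MAE.
#'
#' @param design samples x features matrix from [make_design()]
#' @param ages numeric response aligned with rows
#' @param cohorts cohort label per sample
#' @param config a [model_config()]
#' @param always_train optional cohort label(s) never held out (they stay in
#'   every training pool, mirroring a large in-house cohort)
#' @param split training fraction of the pool (default 0.8)
#' @return object of class `loco_ensemble`
#' @export
loco_train <- function(design, ages, cohorts, config = small_model_config(),
                       always_train = NULL, split = 0.8) {
  cohorts <- as.character(cohorts)
  .assert(length(unique(cohorts)) >= 2L,
          "LOCO needs at least 2 cohorts (got 1)")
  holdouts <- setdiff(unique(cohorts), always_train)
  .assert(length(holdouts) >= 1L, "no cohort eligible for holdout")
  models <- list(); fold <- list()
  for (i in seq_along(holdouts)) {
    co <- holdouts[i]
    pool <- which(cohorts != co)
    test_idx <- which(cohorts == co)
    split_seed <- derive_seed(config$seed, paste0("loco_split_", co))
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(split_seed)
    train_idx <- sort(sample(pool, floor(split * length(pool))))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    inner_idx <- setdiff(pool, train_idx)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("loco_fit_", co))
    mod <- train_mlp(design[train_idx, , drop = FALSE], ages[train_idx], cfg)
    pred_out <- predict(mod, design[test_idx, , drop = FALSE])
    pred_in <- if (length(inner_idx))
      predict(mod, design[inner_idx, , drop = FALSE]) else numeric(0)
    models[[co]] <- mod
    fold[[co]] <- data.frame(
      excluded_cohort = co,
      n_train = length(train_idx), n_holdout = length(test_idx),
      holdout_mae = mean(abs(pred_out - ages[test_idx])),
      internal_test_mae = if (length(inner_idx))
        mean(abs(pred_in - ages[inner_idx])) else NA_real_,
      split_seed = split_seed, stringsAsFactors = FALSE)
  }
  structure(list(models = models, excluded = holdouts,
                 folds = do.call(rbind, c(fold, list(make.row.names = FALSE))),
                 features = colnames(design), config = config),
            class = "loco_ensemble")
}

#' @export
print.loco_ensemble <- function(x, ...) {
  cat("loco_ensemble:", length(x$models), "submodels; mean holdout MAE",
      signif(mean(x$folds$holdout_mae), 4), "years\n")
  invisible(x)
}

#' Predict ages from a model or LOCO ensemble
#'
#' Ensemble predictions are the unweighted mean across submodels. The design
#' must match the feature contract exactly; a permuted column order is an
#' error, never silently reordered.
#'
#' @param object an `mlp_model` or `loco_ensemble`
#' @param design samples x features matrix
#' @return numeric predicted ages, named by row names of `design`
#' @export
predict_age <- function(object, design) {
  if (inherits(object, "mlp_model")) {
    p <- predict(object, design)
  } else if (inherits(object, "loco_ensemble")) {
    .check_contract(object$features, colnames(design))
    preds <- vapply(object$models, function(mod) predict(mod, design),
                    numeric(nrow(design)))
    p <- if (is.matrix(preds)) rowMeans(preds) else mean(preds)
  } else {
    stop("object must be an mlp_model or loco_ensemble", call. = FALSE)
  }
  stats::setNames(as.numeric(p), rownames(design))
}

#' Random-search hyperparameter tuning over LOCO folds
#'
#' Draws `n_trials` configurations from the search space and returns the one
#' minimizing mean held-out MAE across LOCO folds (ties: first trial). The
#' default space mirrors the production search (hidden layers 2-8, widths
#' 128-1024, dropout 0.15-0.5, L2 1e-6 to 0.1 and learning rate 1e-5 to
#' 1e-3 log-uniform, epochs 10-5000); pass a narrower space for desk-scale
#' runs.
#'
#' @param design,ages,cohorts as in [loco_train()]
#' @param space list of ranges: n_hidden (min,max), width (choices), dropout
#'   (min,max), l2 (min,max, log-uniform), lr (min,max, log-uniform),
#'   epochs (min,max)
#' @param n_trials number of random trials (>= 1)
#' @param seed RNG seed controlling the trial sequence
#' @param always_train passed to [loco_train()]
#' @return list with `best_config`, `best_mae` and the full `trials` log
#' @export
tune_hyperparameters <- function(design, ages, cohorts,
                                 space = list(n_hidden = c(2L, 8L),
                                              width = c(128L, 256L, 512L, 1024L),
                                              dropout = c(0.15, 0.5),
                                              l2 = c(1e-6, 0.1),
                                              lr = c(1e-5, 1e-3),
                                              epochs = c(10L, 5000L)),
                                 n_trials = 10L, seed = 1L,
                                 always_train = NULL) {
  .assert(n_trials >= 1L, "n_trials must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  draws <- lapply(seq_len(n_trials), function(i) {
    list(n_hidden = sample(space$n_hidden[1]:space$n_hidden[2], 1L),
         width = sample(space$width, 1L),
         dropout = stats::runif(1, space$dropout[1], space$dropout[2]),
         l2 = exp(stats::runif(1, log(space$l2[1]), log(space$l2[2]))),
         lr = exp(stats::runif(1, log(space$lr[1]), log(space$lr[2]))),
         epochs = sample(space$epochs[1]:space$epochs[2], 1L))
  })
  rows <- list(); errs <- character(0)
  for (i in seq_len(n_trials)) {
    d <- draws[[i]]
    cfg <- model_config(n_hidden = d$n_hidden, width = d$width,
                        dropout = d$dropout, l2 = d$l2, lr = d$lr,
                        epochs = d$epochs,
                        seed = derive_seed(seed, paste0("trial_", i)))
    res <- tryCatch(
      loco_train(design, ages, cohorts, cfg, always_train = always_train),
      error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("trial %d: %s", i, conditionMessage(res)))
      rows[[i]] <- data.frame(trial = i, n_hidden = d$n_hidden,
                              width = d$width, dropout = d$dropout,
                              l2 = d$l2, lr = d$lr, epochs = d$epochs,
                              mean_loco_mae = NA_real_)
    } else {
      rows[[i]] <- data.frame(trial = i, n_hidden = d$n_hidden,
                              width = d$width, dropout = d$dropout,
                              l2 = d$l2, lr = d$lr, epochs = d$epochs,
                              mean_loco_mae = mean(res$folds$holdout_mae))
    }
  }
  trials <- do.call(rbind, rows)
  if (all(is.na(trials$mean_loco_mae)))
    stop("all tuning trials failed:\n", paste(errs, collapse = "\n"), call. = FALSE)
  best <- which.min(trials$mean_loco_mae)
  d <- draws[[best]]
  best_config <- model_config(n_hidden = d$n_hidden, width = d$width,
                              dropout = d$dropout, l2 = d$l2, lr = d$lr,
                              epochs = d$epochs,
                              seed = derive_seed(seed, paste0("trial_", best)))
  list(best_config = best_config, best_mae = trials$mean_loco_mae[best],
       trials = trials)
}

#' Save / load a model bundle
#'
#' The bundle directory holds the configuration and feature contract as
#' JSON/plain text plus the weight arrays in R's binary serialization.
#'
#' @param object an `mlp_model` or `loco_ensemble`
#' @param dir bundle directory (created if needed)
#' @export
save_model <- function(object, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feats <- if (inherits(object, "loco_ensemble")) object$features else object$features
  writeLines(feats, file.path(dir, "features.txt"))
  cfg <- if (inherits(object, "loco_ensemble")) object$config else object$config
  jsonlite::write_json(
    list(class = class(object)[1], config = unclass(cfg)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(object, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}

#' Write predictions as CSV (sample_id, predicted_age)
#'
#' @param predictions named numeric vector from [predict_age()]
#' @param path output CSV
#' @export
write_predictions <- function(predictions, path) {
  data.table::fwrite(data.table::data.table(
    sample_id = names(predictions), predicted_age = as.numeric(predictions)),
    path, quote = FALSE)
  invisible(path)
}
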