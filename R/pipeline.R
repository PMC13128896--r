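# End-to-end orchestration: simulate/load -> select -> LOCO train ->
# predict -> explain -> bin -> cluster/bootstrap -> phase cut -> evaluate.

#' Configure a pipeline run
#'
#' Exactly one of `sim` (synthetic mode) or `beta_path` + `meta_path`
#' (real-input mode) must be given. The global `seed` fans out to per-stage
#' seeds via [derive_seed()], so every stage is independently reproducible.
#'
#' @param sim a [sim_config()] for synthetic mode, or NULL
#' @param beta_path,meta_path input files for real mode (TSV beta matrix,
#'   CSV sample sheet), or NULL
#' @param scheme stratification scheme for feature selection
#' @param fraction per-stratum top fraction (default 0.01)
#' @param model a [model_config()]; defaults to the desk-scale network
#' @param attribution list: n_steps, n_background
#' @param bootstrap list: scales, B
#' @param cut list with `k` (default 4) or `height`
#' @param bins age-bin scheme for attribution profiles
#' @param outdir artifact directory
#' @param seed global integer seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(sim = NULL, beta_path = NULL, meta_path = NULL,
                            scheme = stratum_scheme(),
                            fraction = 0.01,
                            model = small_model_config(),
                            attribution = list(n_steps = 100L, n_background = 50L),
                            bootstrap = list(scales = seq(0.5, 1.4, 0.1), B = 200L),
                            cut = list(k = 4L),
                            bins = age_bin_scheme(),
                            outdir = tempfile("methylwave_run_"),
                            seed = 1L) {
  synthetic <- !is.null(sim)
  real <- !is.null(beta_path) || !is.null(meta_path)
  if (synthetic == real)
    stop("exactly one of synthetic (sim) or real (beta_path + meta_path) ",
         "inputs must be configured", call. = FALSE)
  if (real)
    .assert(!is.null(beta_path) && !is.null(meta_path),
            "real mode needs both beta_path and meta_path")
  if (synthetic) .assert(inherits(sim, "sim_config"), "sim must be a sim_config")
  .assert(xor(is.null(cut$height), is.null(cut$k)),
          "cut must give exactly one of height or k")
  structure(list(sim = sim, beta_path = beta_path, meta_path = meta_path,
                 scheme = scheme, fraction = fraction, model = model,
                 attribution = attribution, bootstrap = bootstrap,
                 cut = cut, bins = bins, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_json <- function(stage, event, ...) {
  message(jsonlite::toJSON(c(list(stage = stage, event = event), list(...)),
                           auto_unbox = TRUE))
}

# run one stage with structured error reporting
.stage <- function(name, expr) {
  .log_json(name, "start")
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  .log_json(name, "done")
  out
}

# restrict an age_bin_profile to a subset of bin labels (shared across sexes)
.subset_profile <- function(profile, labels) {
  keep <- rownames(profile$signed) %in% labels
  structure(list(signed = profile$signed[keep, , drop = FALSE],
                 magnitude = profile$magnitude[keep, , drop = FALSE],
                 counts = profile$counts[keep],
                 bins = profile$bins[keep, , drop = FALSE]),
            class = "age_bin_profile")
}

#' Run the full pipeline
#'
#' Emits, under `config$outdir`: the selected feature list and correlation
#' table, the LOCO model bundle, ensemble predictions, a calibration report,
#' the attribution matrix, age-bin profiles, supported dendrograms (combined
#' and per sex when both sexes are present), phase tables, and a JSON run
#' manifest with per-stage seeds and artifact hashes. Rerunning with the
#' same config and seed reproduces all numeric artifacts.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list of in-memory stage results (including
#'   `outdir`)
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(simulate = derive_seed(config$seed, "simulate"),
                train = derive_seed(config$seed, "train"),
                explain = derive_seed(config$seed, "explain"),
                bootstrap = derive_seed(config$seed, "bootstrap"))

  dat <- .stage("load", {
    if (!is.null(config$sim)) {
      sc <- config$sim; sc$seed <- seeds$simulate
      sim <- simulate_cohort(sc)
      jsonlite::write_json(
        list(class_counts = as.list(table(sim$truth$class)),
             phase_boundaries = sim$truth$phase_boundaries),
        file.path(config$outdir, "truth_summary.json"),
        auto_unbox = TRUE, digits = NA)
      sim
    } else {
      m <- read_beta_matrix(config$beta_path)
      m <- collapse_epicv2(m)
      meta <- read_sample_meta(config$meta_path)
      .assert(all(meta$sample_id %in% colnames(m)),
              "sample sheet contains samples absent from the beta matrix")
      list(beta = impute_missing(m[, meta$sample_id, drop = FALSE]),
           meta = meta, truth = NULL)
    }
  })

  features <- .stage("select", {
    tab <- stratified_correlations(dat$beta, dat$meta, config$scheme)
    fs <- select_features(tab, config$fraction)
    data.table::fwrite(fs$table, file.path(config$outdir, "correlations_selected.tsv"),
                       sep = "\t", quote = FALSE)
    write_feature_list(fs, file.path(config$outdir, "features.txt"))
    fs
  })

  design <- .stage("design", make_design(dat$beta, dat$meta, features))

  ensemble <- .stage("train", {
    cfg <- config$model; cfg$seed <- seeds$train
    ens <- loco_train(design, dat$meta$age, dat$meta$cohort, cfg)
    save_model(ens, file.path(config$outdir, "model"))
    data.table::fwrite(ens$folds, file.path(config$outdir, "loco_folds.csv"),
                       quote = FALSE)
    ens
  })

  preds <- .stage("predict", {
    p <- predict_age(ensemble, design)
    write_predictions(p, file.path(config$outdir, "predictions.csv"))
    p
  })

  report <- .stage("evaluate", {
    rep <- calibration_metrics(preds, dat$meta$age)
    jsonlite::write_json(unclass(rep), file.path(config$outdir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })

  attr <- .stage("explain", {
    a <- explain(ensemble, design,
                 n_steps = config$attribution$n_steps,
                 n_background = config$attribution$n_background,
                 seed = seeds$explain)
    write_attributions(a, file.path(config$outdir, "attributions.tsv"))
    a
  })

  profiles <- .stage("bin", {
    all <- bin_profiles(attr, dat$meta, config$bins)
    write_bin_profile(all, file.path(config$outdir, "bin_profile_signed.tsv"))
    write_bin_profile(all, file.path(config$outdir, "bin_profile_magnitude.tsv"),
                      which = "magnitude")
    by_sex <- NULL
    if (length(unique(dat$meta$sex)) == 2L) {
      fem <- dat$meta$sex == 0L
      pf <- bin_profiles(.subset_attr(attr, fem), dat$meta[fem, ], config$bins)
      pm <- bin_profiles(.subset_attr(attr, !fem), dat$meta[!fem, ], config$bins)
      shared <- intersect(rownames(pf$signed), rownames(pm$signed))
      by_sex <- list(female = .subset_profile(pf, shared),
                     male = .subset_profile(pm, shared))
    }
    list(all = all, by_sex = by_sex)
  })

  phases <- .stage("phases", {
    sd_all <- multiscale_bootstrap(profiles$all,
                                   scales = config$bootstrap$scales,
                                   B = config$bootstrap$B,
                                   seed = seeds$bootstrap)
    pa <- if (!is.null(config$cut$k))
      cut_phases(sd_all, k = config$cut$k)
    else cut_phases(sd_all, height = config$cut$height)
    write_dendrogram_json(sd_all, file.path(config$outdir, "dendrogram_all.json"))
    write_dendrogram_newick(sd_all, file.path(config$outdir, "dendrogram_all.nwk"))
    write_phase_table(pa, file.path(config$outdir, "phases_all.csv"))
    by_sex <- NULL
    if (!is.null(profiles$by_sex)) {
      by_sex <- compare_sex_phases(profiles$by_sex, cut_height = pa$cut_height,
                                   scales = config$bootstrap$scales,
                                   B = config$bootstrap$B,
                                   seed = seeds$bootstrap)
      for (g in names(by_sex)) {
        write_dendrogram_json(by_sex[[g]]$dendrogram,
                              file.path(config$outdir, sprintf("dendrogram_%s.json", g)))
        write_phase_table(by_sex[[g]]$phases,
                          file.path(config$outdir, sprintf("phases_%s.csv", g)))
      }
    }
    list(all = pa, dendrogram = sd_all, by_sex = by_sex)
  })

  .stage("manifest", {
    arts <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
    arts <- arts[basename(arts) != "manifest.json"]
    hashes <- tools::md5sum(arts)
    names(hashes) <- substring(names(hashes), nchar(config$outdir) + 2L)
    inputs <- c(config$beta_path, config$meta_path)
    jsonlite::write_json(list(
      package_version = as.character(utils::packageVersion("methylwave")),
      r_version = R.version.string,
      global_seed = config$seed, stage_seeds = seeds,
      input_hashes = if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL,
      artifact_hashes = as.list(hashes)),
      file.path(config$outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  })

  invisible(list(outdir = config$outdir, data = dat, features = features,
                 ensemble = ensemble, predictions = preds, report = report,
                 attributions = attr, profiles = profiles, phases = phases))
}

# row-subset an attribution matrix (keeps class and metadata)
.subset_attr <- function(attr, idx) {
  structure(list(phi = attr$phi[idx, , drop = FALSE],
                 baseline = attr$baseline,
                 background_ids = attr$background_ids,
                 n_steps = attr$n_steps, seed = attr$seed),
            class = "attribution_matrix")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `sim` is a mapping of [sim_config()] arguments, `model` of
#' [model_config()] arguments, `scheme` of [stratum_scheme()] arguments.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$n_cpgs)) y$sim$n_cpgs <- unlist(y$sim$n_cpgs)
    args$sim <- do.call(sim_config, y$sim)
  }
  for (k in c("beta_path", "meta_path", "fraction", "outdir", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$scheme)) args$scheme <- do.call(stratum_scheme, y$scheme)
  if (!is.null(y$model)) args$model <- do.call(model_config, y$model)
  for (k in c("attribution", "bootstrap", "cut"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}
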