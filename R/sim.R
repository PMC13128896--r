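#' Configure a synthetic methylome simulation
#'
#' Defines the "stated world" for the synthetic cohorts used to exercise the
#' whole pipeline with planted ground truth. Beta-values are generated on the
#' logit scale as per-CpG age trajectories plus sex effects, cohort mean
#' shifts and Gaussian noise, then mapped through the inverse logit so every
#' value lies in (0, 1) without clipping.
#'
#' Five CpG classes are planted:
#' \describe{
#'   \item{linear}{constant logit slope across the whole age range.}
#'   \item{logistic}{sigmoidal trajectory with a random midlife midpoint.}
#'   \item{piecewise_phase}{a sharp transition centred exactly on one of the
#'     `phase_boundaries` (boundaries are cycled over the class): a steep
#'     logistic step of full amplitude completing within a few years, flat
#'     plateaus elsewhere. The slope is maximal exactly at the boundary, so
#'     age bins within a phase share a methylation level while bins across
#'     a boundary are offset — the planted, clustering-recoverable analogue
#'     of punctuated "wave" transitions. (A continuous piecewise-linear
#'     ramp cannot plant recoverable phases: it stretches within-phase
#'     distances instead of creating between-phase offsets.)}
#'   \item{sex_modulated}{sex-specific slopes plus a sex mean offset.}
#'   \item{null}{baseline plus noise only; no age association.}
#' }
#'
#' @param n_per_cohort samples per cohort (default 200)
#' @param n_cohorts number of cohorts (default 3)
#' @param age_range numeric length-2, min < max, in years (default c(13, 95),
#'   mirroring blood cohorts spanning adolescence to the tenth decade)
#' @param sex_ratio fraction male; sexes are coded 0 = female, 1 = male
#'   everywhere in the package
#' @param n_cpgs named counts for classes linear, logistic, piecewise_phase,
#'   sex_modulated, null
#' @param phase_boundaries strictly increasing ages interior to `age_range`
#'   (default 35, 45, 65: early life, early midlife, late midlife, late life)
#' @param effects list of per-class effect sizes on the logit scale; see
#'   Details for defaults
#' @param noise_sd logit-scale Gaussian noise sd (default 0.3)
#' @param cohort_offsets per-cohort logit mean shifts (default symmetric
#'   around 0, step 0.2)
#' @param seed integer RNG seed
#'
#' @details Default effect sizes: linear slopes are drawn uniformly from
#' \eqn{\pm}[0.01, 0.03] logit/year (roughly 1-3 beta percentage points per
#' decade at beta = 0.5); logistic amplitude 1.2 logits with steepness
#' 0.1/year (a genuinely gradual transition spanning roughly three decades;
#' every age-trajectory class gets the same per-CpG amplitude budget so no
#' class dominates by fiat); piecewise amplitude 1.2 logits per boundary
#' step (four times
#' the default noise sd) with a 2-year transition width; sex-modulated CpGs
#' have a female slope like the
#' linear class, a male slope scaled by -0.5, and a 0.5 logit sex offset.
#'
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_per_cohort = 200L,
                       n_cohorts = 3L,
                       age_range = c(13, 95),
                       sex_ratio = 0.5,
                       n_cpgs = c(linear = 300L, logistic = 150L,
                                  piecewise_phase = 300L,
                                  sex_modulated = 150L, null = 600L),
                       phase_boundaries = c(35, 45, 65),
                       effects = list(),
                       noise_sd = 0.3,
                       cohort_offsets = NULL,
                       seed = 1L) {
  classes <- c("linear", "logistic", "piecewise_phase", "sex_modulated", "null")
  n_full <- stats::setNames(integer(5L), classes)
  n_full[names(n_cpgs)] <- as.integer(n_cpgs)
  .assert(all(n_full >= 0L), "CpG class counts must be >= 0")
  .assert(length(age_range) == 2L && age_range[1] < age_range[2],
          "age_range must be [min, max] with min < max")
  .assert(n_per_cohort >= 0L && n_cohorts >= 0L, "counts must be >= 0")
  if (length(phase_boundaries)) {
    .assert(all(diff(phase_boundaries) > 0), "phase_boundaries must be strictly increasing")
    .assert(all(phase_boundaries > age_range[1] & phase_boundaries < age_range[2]),
            "phase_boundaries must lie inside age_range")
  }
  .assert(sex_ratio >= 0 && sex_ratio <= 1, "sex_ratio must be in [0, 1]")
  .assert(noise_sd >= 0, "noise_sd must be >= 0")
  eff <- utils::modifyList(list(
    linear_slope = c(0.01, 0.03),
    logistic_amplitude = 1.2,
    logistic_steepness = 0.1,
    piecewise_amplitude = 1.2,
    piecewise_width = 2,
    sex_slope_ratio = -0.5,
    sex_offset = 0.5,
    baseline_sd = 1.0
  ), effects)
  if (is.null(cohort_offsets)) {
    cohort_offsets <- (seq_len(n_cohorts) - (n_cohorts + 1) / 2) * 0.2
  }
  .assert(length(cohort_offsets) == n_cohorts,
          "cohort_offsets must have one entry per cohort")
  structure(list(n_per_cohort = as.integer(n_per_cohort),
                 n_cohorts = as.integer(n_cohorts),
                 age_range = as.numeric(age_range),
                 sex_ratio = sex_ratio, n_cpgs = n_full,
                 phase_boundaries = as.numeric(phase_boundaries),
                 effects = eff, noise_sd = noise_sd,
                 cohort_offsets = as.numeric(cohort_offsets),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# evaluate the noiseless logit trajectory for one CpG at given ages/sexes
.trajectory_logit <- function(par, ages, sexes) {
  base <- rep(par$baseline, length(ages))
  switch(par$class,
    linear = base + par$slope * (ages - par$center),
    logistic = base + par$amplitude *
      (stats::plogis(par$steepness * (ages - par$midpoint)) - 0.5),
    piecewise_phase = base + par$amplitude *
      stats::plogis((ages - par$boundary) / (par$width / 4)),
    sex_modulated = {
      slope <- ifelse(sexes == 1L, par$slope_male, par$slope_female)
      base + slope * (ages - par$center) + par$sex_offset * (sexes == 1L)
    },
    null = base,
    stop("unknown CpG class: ", par$class)
  )
}

#' Simulate a multi-cohort methylome with planted ground truth
#'
#' @param config a [sim_config()]
#' @return list with components
#'   \describe{
#'     \item{beta}{probes x samples matrix of beta-values in (0, 1)}
#'     \item{meta}{data.frame with sample_id, age (decimal years), sex
#'       (0 = female, 1 = male), cohort}
#'     \item{truth}{planted truth: per-CpG `class` labels, trajectory
#'       `params`, noiseless `beta_clean`, and `phase_boundaries`}
#'   }
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_cohort = 20, n_cohorts = 2,
#'   n_cpgs = c(linear = 5, null = 5), seed = 7))
#' dim(sim$beta)
simulate_cohort <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  n_samples <- config$n_per_cohort * config$n_cohorts
  n_probes <- sum(config$n_cpgs)
  if (n_samples == 0L) stop("cannot simulate zero samples", call. = FALSE)
  if (n_probes == 0L) stop("cannot simulate zero CpGs", call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  eff <- config$effects
  ages <- stats::runif(n_samples, config$age_range[1], config$age_range[2])
  sexes <- as.integer(stats::runif(n_samples) < config$sex_ratio)
  cohort <- rep(paste0("cohort", seq_len(config$n_cohorts)),
                each = config$n_per_cohort)
  meta <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    age = ages, sex = sexes, cohort = cohort,
    stringsAsFactors = FALSE
  )

  class_vec <- rep(names(config$n_cpgs), times = config$n_cpgs)
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  mid_age <- mean(config$age_range)

  params <- vector("list", n_probes)
  phase_cycle <- 0L
  for (j in seq_len(n_probes)) {
    cl <- class_vec[j]
    p <- list(class = cl,
              baseline = stats::rnorm(1, 0, eff$baseline_sd))
    if (cl == "linear") {
      p$slope <- sample(c(-1, 1), 1) * stats::runif(1, eff$linear_slope[1], eff$linear_slope[2])
      p$center <- mid_age
    } else if (cl == "logistic") {
      span <- diff(config$age_range)
      p$amplitude <- sample(c(-1, 1), 1) * eff$logistic_amplitude
      p$steepness <- eff$logistic_steepness
      p$midpoint <- stats::runif(1, config$age_range[1] + 0.2 * span,
                                 config$age_range[2] - 0.2 * span)
    } else if (cl == "piecewise_phase") {
      .assert(length(config$phase_boundaries) > 0L,
              "piecewise_phase CpGs need at least one phase boundary")
      phase_cycle <- phase_cycle %% length(config$phase_boundaries) + 1L
      p$boundary <- config$phase_boundaries[phase_cycle]
      p$width <- eff$piecewise_width
      p$amplitude <- sample(c(-1, 1), 1) * eff$piecewise_amplitude
    } else if (cl == "sex_modulated") {
      s <- sample(c(-1, 1), 1) * stats::runif(1, eff$linear_slope[1], eff$linear_slope[2])
      p$slope_female <- s
      p$slope_male <- s * eff$sex_slope_ratio
      p$sex_offset <- eff$sex_offset
      p$center <- mid_age
    }
    params[[j]] <- p
  }
  names(params) <- probe_ids

  clean_logit <- matrix(0, n_probes, n_samples,
                        dimnames = list(probe_ids, meta$sample_id))
  for (j in seq_len(n_probes)) {
    clean_logit[j, ] <- .trajectory_logit(params[[j]], ages, sexes)
  }
  offset_by_sample <- config$cohort_offsets[rep(seq_len(config$n_cohorts),
                                                each = config$n_per_cohort)]
  noisy_logit <- sweep(clean_logit, 2L, offset_by_sample, "+") +
    matrix(stats::rnorm(n_probes * n_samples, 0, config$noise_sd),
           n_probes, n_samples)

  truth <- list(class = stats::setNames(class_vec, probe_ids),
                params = params,
                beta_clean = inv_logit(clean_logit),
                phase_boundaries = config$phase_boundaries)
  list(beta = inv_logit(noisy_logit), meta = meta, truth = truth)
}

#' Map age bins to planted phases
#'
#' Each bin is assigned the phase interval containing its midpoint; a bin
#' straddling a boundary therefore goes with the side holding its midpoint.
#' Open-ended bins use the midpoint of their last/first covered 5-year span
#' (e.g. "<20" has midpoint 17.5, "85+" has 87.5).
#'
#' @param truth planted truth from [simulate_cohort()] (or any list with a
#'   `phase_boundaries` component)
#' @param bins a bin scheme from [age_bin_scheme()]
#' @return integer phase label per bin, named by bin label
#' @export
truth_phase_partition <- function(truth, bins) {
  .assert(!is.null(truth$phase_boundaries), "truth lacks phase_boundaries")
  .assert(is.data.frame(bins) && all(c("label", "lo", "hi") %in% names(bins)),
          "bins must come from age_bin_scheme()")
  .assert(!is.unsorted(bins$lo, strictly = TRUE), "bins must be ordered")
  width <- 5
  mids <- ifelse(is.finite(bins$lo) & is.finite(bins$hi),
                 (bins$lo + bins$hi) / 2,
                 ifelse(is.finite(bins$hi), bins$hi - width / 2, bins$lo + width / 2))
  phase <- findInterval(mids, truth$phase_boundaries) + 1L
  stats::setNames(as.integer(phase), bins$label)
}
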