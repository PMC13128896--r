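#' Define an age/sex stratification scheme
#'
#' Age bins are half-open `[lo, hi)`; the last bin is closed at the top so
#' the oldest sample is not dropped. Defaults are the four broad bins used
#' for feature selection (10-40, 40-50, 50-70, 70-100 years) crossed with
#' sex, giving 8 strata; set `by_sex = FALSE` for the 4-stratum
#' sexes-pooled reading.
#'
#' @param age_edges strictly increasing bin edges in years
#' @param by_sex stratify by sex within each age bin (default TRUE)
#' @return object of class `stratum_scheme`
#' @export
stratum_scheme <- function(age_edges = c(10, 40, 50, 70, 100), by_sex = TRUE) {
  .assert(length(age_edges) >= 2L && !is.unsorted(age_edges, strictly = TRUE),
          "age_edges must be strictly increasing with >= 2 values")
  structure(list(age_edges = as.numeric(age_edges), by_sex = isTRUE(by_sex)),
            class = "stratum_scheme")
}

#' Assign every sample to one (age-bin, sex) stratum
#'
#' @param meta sample sheet (sample_id, age, sex, cohort)
#' @param scheme a [stratum_scheme()]
#' @return character stratum label per sample, e.g. `"[40,50)/F"`; levels
#'   are ordered by age bin then sex
#' @export
assign_strata <- function(meta, scheme) {
  .assert(inherits(scheme, "stratum_scheme"), "scheme must be a stratum_scheme")
  edges <- scheme$age_edges
  out_of_range <- meta$age < edges[1] | meta$age > edges[length(edges)]
  if (any(out_of_range))
    stop("samples with age outside [", edges[1], ", ", edges[length(edges)],
         "]: ", paste(meta$sample_id[out_of_range][1:min(5, sum(out_of_range))],
                      collapse = ", "), call. = FALSE)
  bin <- findInterval(meta$age, edges, rightmost.closed = TRUE)
  bin_lab <- sprintf("[%g,%g)", edges[bin], edges[bin + 1L])
  bin_levels <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1L])
  if (!scheme$by_sex) {
    return(factor(bin_lab, levels = bin_levels))
  }
  if (anyNA(meta$sex))
    stop("unknown sex for samples ",
         paste(meta$sample_id[is.na(meta$sex)][1:min(5, sum(is.na(meta$sex)))],
               collapse = ", "),
         " with sex stratification enabled", call. = FALSE)
  sex_lab <- ifelse(meta$sex == 1L, "M", "F")
  factor(paste0(bin_lab, "/", sex_lab),
         levels = as.vector(t(outer(bin_levels, c("F", "M"), paste, sep = "/"))))
}

# Spearman rho of every matrix row against y (average ranks for ties),
# with asymptotic t-test p-values. Constant rows give NA.
.row_spearman <- function(m, y) {
  n <- length(y)
  .assert(ncol(m) == n, "matrix columns must align with y")
  if (n < 3L) {
    return(list(rho = stats::setNames(rep(NA_real_, nrow(m)), rownames(m)),
                p = stats::setNames(rep(NA_real_, nrow(m)), rownames(m)), n = n))
  }
  ry <- rank(y)
  rm <- t(apply(m, 1L, rank))
  .row_pearson(rm, ry)
}

# Pearson r of every matrix row against y, with t-approximation p-values.
.row_pearson <- function(m, y) {
  n <- length(y)
  yc <- y - mean(y)
  mc <- m - rowMeans(m)
  denom <- sqrt(rowSums(mc^2) * sum(yc^2))
  r <- as.vector(mc %*% yc) / denom
  r[!is.finite(r)] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(rho = stats::setNames(r, rownames(m)),
       p = stats::setNames(p, rownames(m)), n = n)
}

#' Spearman correlation of every CpG with age
#'
#' Rank-based, so invariant under any strictly monotone transform of beta.
#' CpGs that are constant (or when age is constant) get NA and are excluded
#' from downstream selection.
#'
#' @param m probes x samples beta matrix
#' @param ages numeric vector aligned with columns of `m`
#' @return named numeric vector of rho
#' @export
spearman_age_correlation <- function(m, ages) {
  .assert(length(ages) >= 3L, "need at least 3 samples")
  .row_spearman(m, ages)$rho
}

#' Per-stratum Spearman correlation table
#'
#' Computes, within each (age-bin, sex) stratum, the Spearman correlation of
#' every CpG with chronological age. Strata with fewer than `min_n` samples
#' are skipped with a message.
#'
#' @param m probes x samples beta matrix
#' @param meta sample sheet aligned with columns of `m`
#' @param scheme a [stratum_scheme()]
#' @param min_n minimum samples per stratum (default 3)
#' @return data.frame with columns cpg, stratum, rho, n, p
#' @export
stratified_correlations <- function(m, meta, scheme, min_n = 3L) {
  .assert(ncol(m) == nrow(meta), "matrix columns must align with meta rows")
  strata <- assign_strata(meta, scheme)
  out <- list()
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < min_n) {
      message("skipping stratum ", s, ": only ", length(idx), " samples")
      next
    }
    sp <- .row_spearman(m[, idx, drop = FALSE], meta$age[idx])
    out[[s]] <- data.frame(cpg = rownames(m), stratum = s, rho = sp$rho,
                           n = sp$n, p = sp$p, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  .assert(length(out) > 0L, "no stratum had enough samples")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Number of features kept by a top-fraction rule
#'
#' `floor(fraction * n_features)`, with a minimum of one feature whenever
#' any are available (689,541 shared probes at 1 percent gives 6895).
#'
#' @param n_features total feature count (> 0)
#' @param fraction fraction in (0, 1]
#' @return integer count
#' @export
#' @examples
#' top_fraction_count(689541, 0.01)
top_fraction_count <- function(n_features, fraction) {
  .assert(n_features >= 1L, "n_features must be >= 1")
  .assert(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  max(1L, as.integer(floor(fraction * n_features)))
}

#' Select the per-stratum top fraction of age-correlated CpGs
#'
#' Within each stratum the top-K CpGs by absolute Spearman rho are taken
#' (K = floor(fraction x number of rankable CpGs), ties broken by probe ID),
#' the per-stratum lists are merged into a non-redundant union with
#' provenance, and the union is optionally intersected with a platform
#' probe list.
#'
#' @param tables correlation table from [stratified_correlations()]
#' @param fraction top fraction per stratum (default 0.01)
#' @param platform_probes optional character vector; final set is
#'   restricted to these probes
#' @return object of class `feature_set`: list with `features` (CpG IDs
#'   ordered by best absolute rho), `table` (cpg, stratum, rho at
#'   selection) and `k_per_stratum`
#' @export
select_features <- function(tables, fraction = 0.01, platform_probes = NULL) {
  .assert(fraction > 0, "fraction must be > 0 (an empty selection is not a feature set)")
  .assert(all(c("cpg", "stratum", "rho") %in% names(tables)),
          "tables must have columns cpg, stratum, rho")
  picks <- list()
  ks <- c()
  for (s in unique(tables$stratum)) {
    sub <- tables[tables$stratum == s & !is.na(tables$rho), , drop = FALSE]
    if (!nrow(sub)) next
    k <- top_fraction_count(nrow(sub), fraction)
    ord <- order(-abs(sub$rho), sub$cpg)
    picks[[s]] <- sub[ord[seq_len(min(k, nrow(sub)))], c("cpg", "stratum", "rho")]
    ks[s] <- k
  }
  .assert(length(picks) > 0L, "no stratum yielded selectable CpGs")
  tab <- do.call(rbind, c(picks, list(make.row.names = FALSE)))
  if (!is.null(platform_probes)) tab <- tab[tab$cpg %in% platform_probes, , drop = FALSE]
  .assert(nrow(tab) > 0L, "platform intersection removed every selected CpG")
  best <- tapply(abs(tab$rho), tab$cpg, max)
  feats <- names(best)[order(-best, names(best))]
  structure(list(features = feats, table = tab, k_per_stratum = ks),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", length(x$features), "CpGs from",
      length(unique(x$table$stratum)), "strata\n")
  invisible(x)
}

#' Classify CpGs by stratified vs pooled detectability
#'
#' Compares stratified Spearman significance (any stratum with p < alpha)
#' against pooled Pearson significance on the full cohort. CpGs significant
#' only after stratification expose monotone within-stratum trends diluted
#' in the pooled linear analysis.
#'
#' @param m probes x samples beta matrix
#' @param meta sample sheet aligned with `m`
#' @param scheme a [stratum_scheme()]
#' @param alpha significance level in (0, 1), default 0.05 (unadjusted)
#' @param adjust multiplicity handling for the any-stratum Spearman test:
#'   `"none"` (default) or `"bonferroni"` across strata. With 8 unadjusted
#'   strata the family-wise false-positive rate of "any stratum significant"
#'   is about 1 - 0.95^8 = 34 percent, so a pure-noise CpG lands in
#'   `neither` only ~63 percent of the time; the Bonferroni option restores
#'   ~95 percent.
#' @return factor per CpG with levels stratified_spearman_only, both,
#'   pooled_pearson_only, neither; degenerate CpGs are NA with a warning
#' @export
classify_detectability <- function(m, meta, scheme, alpha = 0.05,
                                   adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  tab <- stratified_correlations(m, meta, scheme)
  alpha_strat <- if (adjust == "bonferroni")
    alpha / length(unique(tab$stratum)) else alpha
  strat_sig <- tapply(tab$p < alpha_strat, tab$cpg, any, na.rm = TRUE)
  strat_sig <- strat_sig[rownames(m)]
  pooled <- .row_pearson(m, meta$age)
  pooled_sig <- !is.na(pooled$p) & pooled$p < alpha
  degenerate <- is.na(pooled$rho) & (is.na(strat_sig) | !strat_sig)
  if (any(degenerate))
    warning(sum(degenerate), " degenerate CpG(s) excluded from classification")
  cls <- ifelse(strat_sig & pooled_sig, "both",
         ifelse(strat_sig & !pooled_sig, "stratified_spearman_only",
         ifelse(!strat_sig & pooled_sig, "pooled_pearson_only", "neither")))
  cls[degenerate] <- NA
  factor(stats::setNames(cls, rownames(m)),
         levels = c("stratified_spearman_only", "both", "pooled_pearson_only", "neither"))
}

#' Write / read a feature list (one CpG ID per line)
#'
#' The one-ID-per-line text file is the model's input feature contract.
#'
#' @param features character vector or `feature_set`
#' @param path file path
#' @export
write_feature_list <- function(features, path) {
  if (inherits(features, "feature_set")) features <- features$features
  writeLines(features, path)
  invisible(path)
}

#' @rdname write_feature_list
#' @export
read_feature_list <- function(path) readLines(path)
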