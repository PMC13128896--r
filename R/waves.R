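# Hierarchical clustering of age-bin attribution profiles with
# multiscale-bootstrap edge support and fixed-height phase cutting.

# extract the matrix clustered from either an age_bin_profile or a matrix
.profile_matrix <- function(x, which = "signed") {
  if (inherits(x, "age_bin_profile")) x[[which]] else as.matrix(x)
}

#' Ward.D2 clustering of age-bin profiles
#'
#' Euclidean distance between per-bin attribution profiles, agglomerated
#' with Ward.D2 linkage (squared-increment form).
#'
#' @param profile an `age_bin_profile` (its signed mean matrix is used) or a
#'   bins x features numeric matrix
#' @return an object of class `hclust`
#' @export
ward_cluster <- function(profile) {
  m <- .profile_matrix(profile)
  .assert(nrow(m) >= 2L, "need at least 2 bins to cluster")
  .assert(!anyNA(m), "profile contains missing values")
  stats::hclust(stats::dist(m), method = "ward.D2")
}

# canonical signature of every internal node's member set.
# Returns a character vector of length n-1 (one per merge).
.node_signatures <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    mem <- integer(0)
    for (kk in kids) {
      mem <- c(mem, if (kk < 0) -kk else sets[[kk]])
    }
    sets[[i]] <- sort(mem)
  }
  vapply(sets, function(s) paste(hc$labels[s], collapse = "|"), character(1))
}

#' Multiscale bootstrap support for age-bin clusters
#'
#' Resamples the feature (CpG) axis at scales `r` with resample size
#' `round(r * F)`, reclusters the bins, and records for every edge of the
#' observed dendrogram the fraction of resamples containing the identical
#' member set (`BP_r`). `BP` is `BP_r` at `r = 1`. The approximately
#' unbiased support is obtained from the fit
#' \deqn{\Phi^{-1}(1 - BP_r) \approx v \sqrt{r} + c / \sqrt{r}}
#' over scales with `BP_r` strictly inside (0, 1), by weighted least squares
#' (binomial delta-method weights \eqn{B \phi(\psi_r)^2 / (BP_r (1-BP_r))}),
#' and `AU = 1 - Phi(v - c)`. Edges with fewer than two usable scales fall
#' back to `AU = BP` and are flagged.
#'
#' @param profile an `age_bin_profile` or bins x features matrix
#' @param scales bootstrap scale grid (default 0.5 to 1.4 by 0.1)
#' @param B bootstrap replicates per scale (default 1000, >= 10)
#' @param seed RNG seed
#' @param weighted use delta-method WLS weights (default TRUE)
#' @return object of class `supported_dendrogram`: list with `hclust`, an
#'   `edges` data.frame (node, members, au, bp, v, c, n_scales_used,
#'   au_fallback), per-edge `bp_by_scale`, and the bootstrap `settings`
#' @export
multiscale_bootstrap <- function(profile, scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000L, seed = 1L, weighted = TRUE) {
  m <- .profile_matrix(profile)
  .assert(B >= 10L, "B must be >= 10")
  .assert(all(scales > 0), "scales must be positive")
  F_ <- ncol(m)
  .assert(F_ >= 2L, "need at least 2 features to resample")
  hc <- ward_cluster(m)
  sig <- .node_signatures(hc)
  n_edges <- length(sig)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  counts <- matrix(0L, n_edges, length(scales))
  for (si in seq_along(scales)) {
    size <- max(2L, round(scales[si] * F_))
    for (b in seq_len(B)) {
      cols <- sample.int(F_, size, replace = TRUE)
      hb <- stats::hclust(stats::dist(m[, cols, drop = FALSE]), method = "ward.D2")
      hits <- sig %in% .node_signatures(hb)
      counts[, si] <- counts[, si] + hits
    }
  }
  bp_by_scale <- counts / B
  colnames(bp_by_scale) <- sprintf("r=%g", scales)
  rownames(bp_by_scale) <- sig

  r1 <- which.min(abs(scales - 1))
  edges <- data.frame(node = seq_len(n_edges), members = sig,
                      bp = bp_by_scale[, r1], au = NA_real_,
                      v = NA_real_, c = NA_real_,
                      n_scales_used = 0L, au_fallback = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE)
  for (e in seq_len(n_edges)) {
    fit <- .fit_au(bp_by_scale[e, ], scales, B, weighted, bp = edges$bp[e])
    edges$au[e] <- fit$au; edges$v[e] <- fit$v; edges$c[e] <- fit$c
    edges$n_scales_used[e] <- fit$n_used
    edges$au_fallback[e] <- fit$fallback
  }
  structure(list(hclust = hc, edges = edges, bp_by_scale = bp_by_scale,
                 settings = list(scales = scales, B = B, seed = seed,
                                 weighted = weighted)),
            class = "supported_dendrogram")
}

# AU from per-scale bootstrap probabilities via the psi(r) = v*sqrt(r) +
# c/sqrt(r) fit. Scales with degenerate BP (0 or 1) are excluded; with fewer
# than two usable scales AU falls back to BP (flagged).
.fit_au <- function(p, scales, B, weighted = TRUE, bp = NULL) {
  if (is.null(bp)) bp <- p[which.min(abs(scales - 1))]
  usable <- p > 0 & p < 1
  if (sum(usable) < 2L) {
    return(list(au = unname(bp), v = NA_real_, c = NA_real_, n_used = 0L,
                fallback = TRUE))
  }
  r <- scales[usable]
  psi <- stats::qnorm(1 - p[usable])
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- if (weighted) B * stats::dnorm(psi)^2 / (p[usable] * (1 - p[usable]))
       else rep(1, length(r))
  vc <- stats::lm.wfit(X, psi, w)$coefficients
  list(au = unname(1 - stats::pnorm(vc[1] - vc[2])),
       v = unname(vc[1]), c = unname(vc[2]),
       n_used = sum(usable), fallback = FALSE)
}

#' @export
print.supported_dendrogram <- function(x, ...) {
  cat("supported_dendrogram over", length(x$hclust$labels), "bins;",
      sum(x$edges$au >= 0.95), "of", nrow(x$edges), "edges with AU >= 0.95",
      "(B =", x$settings$B, ")\n")
  invisible(x)
}

#' Cut a dendrogram into aging phases
#'
#' Cutting at height `h` keeps all merges with height <= `h`; in `k` mode
#' the minimal height producing `k` clusters is computed and recorded, so a
#' cut derived on one cohort can be reused verbatim on another. Phase labels
#' are integers in leaf (age) order: phase 1 holds the youngest bin.
#'
#' @param d a `supported_dendrogram` or plain `hclust`
#' @param height cut height (>= 0); exactly one of `height`/`k` given
#' @param k target number of phases (1 <= k <= number of bins)
#' @param au_threshold AU support threshold for phase support summaries
#' @return object of class `phase_assignment`: list with `phases` (named
#'   integer per bin), `cut_height`, `k`, and per-phase `support` (AU of the
#'   edge defining each multi-bin phase; singleton phases are trivially
#'   supported with AU 1)
#' @export
cut_phases <- function(d, height = NULL, k = NULL, au_threshold = 0.95) {
  hc <- if (inherits(d, "supported_dendrogram")) d$hclust else d
  .assert(inherits(hc, "hclust"), "d must be a dendrogram")
  .assert(xor(is.null(height), is.null(k)), "give exactly one of height or k")
  n <- length(hc$labels)
  if (!is.null(k)) {
    .assert(k >= 1L && k <= n, sprintf("k must be in [1, %d]", n))
    height <- if (k == 1L) hc$height[n - 1L] else if (k == n) 0 else hc$height[n - k]
    cl <- stats::cutree(hc, k = k)
  } else {
    .assert(height >= 0, "height must be >= 0")
    cl <- stats::cutree(hc, h = height)
  }
  k_out <- max(cl)
  support <- rep(NA_real_, k_out)
  if (inherits(d, "supported_dendrogram")) {
    for (ph in seq_len(k_out)) {
      members <- sort(which(cl == ph))
      if (length(members) == 1L) { support[ph] <- 1; next }
      sig <- paste(hc$labels[members], collapse = "|")
      hit <- match(sig, d$edges$members)
      if (!is.na(hit)) support[ph] <- d$edges$au[hit]
    }
  }
  structure(list(phases = cl, cut_height = height, k = k_out,
                 support = support, au_threshold = au_threshold,
                 supported = !is.na(support) & support >= au_threshold),
            class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat("phase_assignment:", x$k, "phases at cut height",
      signif(x$cut_height, 5), "(", sum(x$supported), "supported )\n")
  invisible(x)
}

#' Sex-stratified phase comparison at a shared cut height
#'
#' Builds a supported dendrogram per group, applies one absolute cut height
#' to every group (mirroring a conserved dashed line across panels), and
#' counts supported phases (AU >= `au_threshold`; singleton phases count as
#' trivially supported).
#'
#' @param profiles named list of `age_bin_profile`s (e.g. female/male); all
#'   must share an identical bin set
#' @param cut_height shared absolute cut height
#' @param scales,B,seed,weighted bootstrap settings (see
#'   [multiscale_bootstrap()])
#' @param au_threshold AU support threshold (default 0.95)
#' @return named list per group: `dendrogram`, `phases`
#'   (a `phase_assignment`), `n_supported`
#' @export
compare_sex_phases <- function(profiles, cut_height,
                               scales = seq(0.5, 1.4, by = 0.1), B = 1000L,
                               seed = 1L, weighted = TRUE,
                               au_threshold = 0.95) {
  .assert(is.list(profiles) && length(profiles) >= 2L,
          "profiles must be a named list with >= 2 groups")
  bin_sets <- lapply(profiles, function(p) rownames(.profile_matrix(p)))
  if (!all(vapply(bin_sets, identical, logical(1), bin_sets[[1]])))
    stop("groups have mismatched bin sets; rebuild profiles on a shared scheme",
         call. = FALSE)
  out <- list()
  for (g in names(profiles)) {
    sd <- multiscale_bootstrap(profiles[[g]], scales = scales, B = B,
                               seed = derive_seed(seed, paste0("sexphase_", g)),
                               weighted = weighted)
    pa <- cut_phases(sd, height = cut_height, au_threshold = au_threshold)
    out[[g]] <- list(dendrogram = sd, phases = pa,
                     n_supported = sum(pa$supported))
  }
  out
}

#' Bin-averaged beta profiles and raw-beta clustering
#'
#' `beta_bin_profile` averages beta values within age bins (bins x CpGs);
#' `cluster_raw_beta` feeds that matrix through the identical
#' clustering/bootstrap path used for attribution profiles.
#'
#' @param m probes x samples beta matrix
#' @param meta sample sheet aligned with columns of `m`
#' @param bins bin scheme from [age_bin_scheme()]
#' @return bins x probes matrix (empty bins dropped)
#' @export
beta_bin_profile <- function(m, meta, bins = age_bin_scheme()) {
  idx <- .bin_index(meta$age, bins)
  .assert(!anyNA(idx), "some ages fall outside the bin scheme")
  counts <- tabulate(idx, nbins = nrow(bins))
  keep <- which(counts > 0L)
  f <- factor(idx, levels = keep)
  prof <- rowsum(t(m), f) / counts[keep]
  rownames(prof) <- bins$label[keep]
  prof
}

#' @rdname beta_bin_profile
#' @param ... passed to [multiscale_bootstrap()]
#' @export
cluster_raw_beta <- function(m, meta, bins = age_bin_scheme(), ...) {
  multiscale_bootstrap(beta_bin_profile(m, meta, bins), ...)
}

# recursive nested-list representation of the merge tree
.dendro_tree <- function(hc, edges) {
  build <- function(node) {
    if (node < 0) return(list(leaf = hc$labels[-node]))
    kids <- hc$merge[node, ]
    list(height = hc$height[node],
         au = edges$au[node], bp = edges$bp[node],
         children = list(build(kids[1]), build(kids[2])))
  }
  build(nrow(hc$merge))
}

#' Serialize a supported dendrogram
#'
#' JSON holds the nested merge tree with heights and AU/BP per edge plus the
#' bootstrap settings; Newick annotates internal nodes as `au:bp`.
#'
#' @param d a `supported_dendrogram`
#' @param path output path
#' @export
write_dendrogram_json <- function(d, path) {
  jsonlite::write_json(list(tree = .dendro_tree(d$hclust, d$edges),
                            settings = d$settings,
                            edges = d$edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dendrogram_json
#' @export
write_dendrogram_newick <- function(d, path) {
  hc <- d$hclust; edges <- d$edges
  build <- function(node, parent_h) {
    if (node < 0) {
      return(sprintf("%s:%g", hc$labels[-node], parent_h))
    }
    h <- hc$height[node]
    kids <- hc$merge[node, ]
    sprintf("(%s,%s)%.3f:%g", build(kids[1], h), build(kids[2], h),
            edges$au[node], parent_h - h)
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  kids <- hc$merge[root, ]
  nwk <- sprintf("(%s,%s)%.3f;", build(kids[1], h), build(kids[2], h),
                 edges$au[root])
  writeLines(nwk, path)
  invisible(path)
}

#' Write a phase table as CSV (bin, phase, cut_height)
#'
#' @param pa a `phase_assignment`
#' @param path output CSV
#' @export
write_phase_table <- function(pa, path) {
  data.table::fwrite(data.table::data.table(
    bin = names(pa$phases), phase = as.integer(pa$phases),
    cut_height = pa$cut_height), path, quote = FALSE)
  invisible(path)
}
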