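#' Five-year age-bin scheme
#'
#' Default bins: an open-ended "<20" bin, five-year bins `[20,25)` through
#' `[80,85)`, and an open-ended "85+" bin. Bins with no samples are dropped
#' downstream (and logged), so the number of populated bins is data-driven.
#'
#' @param low upper edge of the open bottom bin (default 20)
#' @param high lower edge of the open top bin (default 85)
#' @param width bin width in years (default 5)
#' @return data.frame with columns label, lo, hi (half-open `[lo, hi)`)
#' @export
age_bin_scheme <- function(low = 20, high = 85, width = 5) {
  .assert(low < high && width > 0, "need low < high and width > 0")
  starts <- seq(low, high - width, by = width)
  data.frame(
    label = c(sprintf("<%g", low),
              sprintf("%g-%g", starts, starts + width - 1),
              sprintf("%g+", high)),
    lo = c(-Inf, starts, high),
    hi = c(low, starts + width, Inf),
    stringsAsFactors = FALSE)
}

# bin index per age (NA if none matches; cannot happen with open-ended bins)
.bin_index <- function(ages, bins) {
  idx <- rep(NA_integer_, length(ages))
  for (b in seq_len(nrow(bins))) {
    idx[ages >= bins$lo[b] & ages < bins$hi[b]] <- b
  }
  idx
}

#' Expected-gradients (gradient SHAP) attribution
#'
#' Estimates Shapley-style attributions
#' \deqn{\phi_i = E_{x' \sim bg,\ \alpha \sim U(0,1)}
#'   [(x_i - x'_i)\, \partial f/\partial x_i(x' + \alpha (x - x'))].}
#' The estimator enumerates the background set in full (each background
#' sample is used equally often, so the linear-model closed form
#' \eqn{\phi_i = w_i (x_i - \bar{x}'_i)} holds exactly) and stratifies the
#' \eqn{\alpha} grid across background samples, giving a fine effective
#' integration grid for the path integral. `n_steps` is the total number of
#' (background, alpha) pairs per explained sample; it is rounded up to a
#' multiple of the background size.
#'
#' @param model an `mlp_model` (or `loco_ensemble`, attributed per submodel
#'   and averaged — matching the ensemble-mean prediction rule)
#' @param design samples x features matrix to explain (must match the
#'   model's feature contract)
#' @param background background matrix (default: `design` itself); if larger
#'   than `n_background` rows, a seeded subsample is taken
#' @param n_steps total path evaluations per sample (default 200)
#' @param n_background maximum background rows used (default 100)
#' @param seed seed for the background subsample
#' @return object of class `attribution_matrix`: list with `phi`
#'   (samples x features), `baseline` (E[f] over the background),
#'   `background_ids`, `n_steps`, `seed`
#' @export
explain <- function(model, design, background = NULL, n_steps = 200L,
                    n_background = 100L, seed = 1L) {
  if (inherits(model, "loco_ensemble")) {
    parts <- lapply(model$models, explain, design = design,
                    background = background, n_steps = n_steps,
                    n_background = n_background, seed = seed)
    phi <- Reduce(`+`, lapply(parts, `[[`, "phi")) / length(parts)
    out <- parts[[1]]
    out$phi <- phi
    out$baseline <- mean(vapply(parts, `[[`, numeric(1), "baseline"))
    return(out)
  }
  .assert(inherits(model, "mlp_model"), "model must be an mlp_model or loco_ensemble")
  .check_contract(model$features, colnames(design))
  if (is.null(background)) background <- design
  .assert(nrow(background) >= 1L, "background set must be non-empty")
  .check_contract(model$features, colnames(background))

  if (nrow(background) > n_background) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    keep <- sort(sample(nrow(background), n_background))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    background <- background[keep, , drop = FALSE]
  }
  X <- as.matrix(design); BG <- as.matrix(background)
  n <- nrow(X); n_bg <- nrow(BG)
  n_alpha <- max(1L, ceiling(n_steps / n_bg))

  phi <- matrix(0, n, ncol(X), dimnames = dimnames(X))
  for (j in seq_len(n_bg)) {
    diffj <- sweep(X, 2L, BG[j, ])           # x - x'_j
    for (a in seq_len(n_alpha)) {
      alpha <- (a - 1 + (j - 0.5) / n_bg) / n_alpha
      pts <- sweep(diffj * alpha, 2L, BG[j, ], "+")
      g <- .mlp_input_gradient(model, pts)
      phi <- phi + diffj * g
    }
  }
  phi <- phi / (n_bg * n_alpha)
  structure(list(phi = phi,
                 baseline = mean(.mlp_eval(model, BG)),
                 background_ids = rownames(BG),
                 n_steps = as.integer(n_bg * n_alpha), seed = seed),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat("attribution_matrix:", nrow(x$phi), "samples x", ncol(x$phi),
      "features; baseline", signif(x$baseline, 5), "\n")
  invisible(x)
}

#' Aggregate attributions into age-bin profiles
#'
#' Averages per-CpG attributions within age bins, producing both the signed
#' mean (the default clustering input) and the mean magnitude (used for
#' top/bottom CpG selection). Bins without samples are dropped with a
#' message.
#'
#' @param attr an `attribution_matrix` from [explain()]
#' @param meta sample sheet aligned with rows of the attribution matrix
#' @param bins bin scheme from [age_bin_scheme()]
#' @return object of class `age_bin_profile`: list with `signed` and
#'   `magnitude` (bins x features matrices), `counts`, `bins`
#' @export
bin_profiles <- function(attr, meta, bins = age_bin_scheme()) {
  phi <- if (inherits(attr, "attribution_matrix")) attr$phi else as.matrix(attr)
  # profiles are defined over CpG features: a design-aligned attribution
  # matrix carries the sex indicator as its last column; it is not a CpG
  # and its per-bin mean tracks bin sex composition, so it is excluded.
  phi <- phi[, colnames(phi) != "sex", drop = FALSE]
  .assert(nrow(phi) == nrow(meta), "attributions and meta must align")
  .assert(nrow(phi) > 0L, "no samples to profile")
  idx <- .bin_index(meta$age, bins)
  .assert(!anyNA(idx), "some ages fall outside the bin scheme")
  counts <- tabulate(idx, nbins = nrow(bins))
  empty <- which(counts == 0L)
  if (length(empty))
    message("dropping empty age bin(s): ",
            paste(bins$label[empty], collapse = ", "))
  keep <- which(counts > 0L)
  f <- factor(idx, levels = keep)
  signed <- rowsum(phi, f) / counts[keep]
  magnitude <- rowsum(abs(phi), f) / counts[keep]
  rownames(signed) <- rownames(magnitude) <- bins$label[keep]
  structure(list(signed = signed, magnitude = magnitude,
                 counts = stats::setNames(counts[keep], bins$label[keep]),
                 bins = bins[keep, , drop = FALSE]),
            class = "age_bin_profile")
}

#' @export
print.age_bin_profile <- function(x, ...) {
  cat("age_bin_profile:", nrow(x$signed), "populated bins x",
      ncol(x$signed), "CpGs\n")
  invisible(x)
}

#' Select the top and bottom K CpGs by mean attribution magnitude
#'
#' Ranks CpGs by their overall mean absolute attribution (bin means weighted
#' by bin sample counts when a profile is supplied). Ties break by probe ID;
#' if `k` is at least the feature count, both lists contain every feature.
#'
#' @param x an `age_bin_profile`, or a named numeric vector of mean
#'   magnitudes
#' @param k number of CpGs per list (>= 1)
#' @return list with `top` and `bottom` character vectors
#' @export
select_extreme_cpgs <- function(x, k = 1000L) {
  .assert(k >= 1L, "k must be >= 1")
  if (inherits(x, "age_bin_profile")) {
    w <- x$counts / sum(x$counts)
    mag <- as.vector(w %*% x$magnitude)
    names(mag) <- colnames(x$magnitude)
  } else {
    mag <- x
    .assert(!is.null(names(mag)), "magnitude vector must be named by CpG")
  }
  k <- min(k, length(mag))
  ord_desc <- order(-mag, names(mag))
  ord_asc <- order(mag, names(mag))
  list(top = names(mag)[ord_desc[seq_len(k)]],
       bottom = names(mag)[ord_asc[seq_len(k)]])
}

#' Serialize an attribution matrix / bin profile
#'
#' The attribution matrix is written as TSV plus a JSON sidecar recording
#' the background sample IDs, seed and step count; bin profiles are TSV
#' (bins x CpGs).
#'
#' @param attr an `attribution_matrix`
#' @param path TSV path; the sidecar is written next to it as `<path>.json`
#' @export
write_attributions <- function(attr, path) {
  dt <- data.table::data.table(sample_id = rownames(attr$phi))
  for (j in seq_len(ncol(attr$phi)))
    data.table::set(dt, j = colnames(attr$phi)[j], value = attr$phi[, j])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(background_ids = attr$background_ids,
                            baseline = attr$baseline,
                            n_steps = attr$n_steps, seed = attr$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_attributions
#' @param profile an `age_bin_profile`
#' @param which `"signed"` or `"magnitude"`
#' @export
write_bin_profile <- function(profile, path, which = c("signed", "magnitude")) {
  which <- match.arg(which)
  m <- profile[[which]]
  dt <- data.table::data.table(bin = rownames(m))
  for (j in seq_len(ncol(m))) data.table::set(dt, j = colnames(m)[j], value = m[, j])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
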