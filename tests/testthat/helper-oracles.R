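# Independent oracles and shared fixtures. Everything here is deliberately
# naive (enumeration / textbook formulas) and never calls the package code
# paths it is used to check.

# Naive O(n^3) agglomerative Ward.D2 via the Lance-Williams update:
# d(k, i+j)^2 = ((n_i + n_k) d_ki^2 + (n_j + n_k) d_kj^2 - n_k d_ij^2) /
#               (n_i + n_j + n_k)
# Returns merge heights (sorted) and the set of member-set signatures.
oracle_ward_d2 <- function(m) {
  n <- nrow(m)
  labels <- rownames(m)
  d2 <- as.matrix(stats::dist(m))^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  heights <- numeric(0)
  sigs <- character(0)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); best_d2 <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b && d2[active[a], active[b]] < best_d2) {
        best <- c(active[a], active[b]); best_d2 <- d2[active[a], active[b]]
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_d2))
    new_members <- sort(c(members[[i]], members[[j]]))
    sigs <- c(sigs, paste(labels[new_members], collapse = "|"))
    for (k in active) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((sizes[i] + sizes[k]) * d2[k, i] + (sizes[j] + sizes[k]) * d2[k, j] -
           sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  list(heights = heights, signatures = sigs)
}

# member-set signatures of an hclust tree (mirrors definition, independent code)
hclust_signatures <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  out <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    mem <- integer(0)
    for (kk in hc$merge[i, ]) mem <- c(mem, if (kk < 0) -kk else sets[[kk]])
    sets[[i]] <- sort(mem)
    out[i] <- paste(hc$labels[sets[[i]]], collapse = "|")
  }
  out
}

# hand-built linear "network": one always-active ReLU hidden layer so that
# f(x) = sum(w * x) + b exactly on [0, 1]^d inputs. Gives a model object for
# which expected-gradients attribution has a closed form.
linear_mlp <- function(w, b = 0, features = paste0("f", seq_along(w))) {
  d <- length(w)
  shift <- 10
  structure(list(
    W = list(diag(d), matrix(w, d, 1)),
    b = list(rep(shift, d), b - shift * sum(w)),
    config = model_config(n_hidden = 1L, width = d, dropout = 0,
                          epochs = 1L, lr = 1e-3),
    features = features, center = NULL, scale = NULL,
    loss_trace = NA_real_), class = "mlp_model")
}

# constant-output "network" (used for ensemble-mean and zero-attribution checks)
constant_mlp <- function(value, features) {
  d <- length(features)
  structure(list(
    W = list(matrix(0, d, 1), matrix(0, 1, 1)),
    b = list(0, value),
    config = model_config(n_hidden = 1L, width = 1L, dropout = 0,
                          epochs = 1L, lr = 1e-3),
    features = features, center = NULL, scale = NULL,
    loss_trace = NA_real_), class = "mlp_model")
}

# the acceptance-world simulation: boundary transitions are the dominant
# age-informative class (see the methods vignette for rationale)
acceptance_sim_config <- function(seed) {
  sim_config(n_cpgs = c(linear = 150, logistic = 75, piecewise_phase = 600,
                        sex_modulated = 75, null = 600),
             seed = seed)
}

# one full select -> LOCO-train -> explain pass at desk scale; memoised per
# seed so several test files can share the heavy fixture
.fixture_cache <- new.env(parent = emptyenv())
trained_fixture <- function(seed = 1L) {
  key <- as.character(seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sim <- simulate_cohort(acceptance_sim_config(derive_seed(seed, "simulate")))
  tab <- stratified_correlations(sim$beta, sim$meta, stratum_scheme())
  fs <- select_features(tab, 0.01)
  design <- make_design(sim$beta, sim$meta, fs)
  ens <- loco_train(design, sim$meta$age, sim$meta$cohort,
                    small_model_config(epochs = 600,
                                       seed = derive_seed(seed, "train")))
  attr <- explain(ens, design, n_steps = 150, n_background = 75,
                  seed = derive_seed(seed, "explain"))
  out <- list(sim = sim, features = fs, design = design, ensemble = ens,
              attr = attr)
  .fixture_cache[[key]] <- out
  out
}
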