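# deterministic two-group bin profile: `gap` separates the groups, `jitter`
# spreads bins within groups over many features
planted_profile <- function(n1 = 3, n2 = 3, F_ = 40, gap = 10,
                            jitter = 0.2, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  m <- matrix(rnorm(n * F_, 0, jitter), n, F_)
  m[(n1 + 1):n, 1:(F_ / 2)] <- m[(n1 + 1):n, 1:(F_ / 2)] + gap / sqrt(F_ / 2)
  rownames(m) <- sprintf("bin%02d", seq_len(n))
  colnames(m) <- sprintf("cg%03d", seq_len(F_))
  m
}

test_that("Ward clustering handles trivial geometries", {
  m <- rbind(A = c(1, 1), B = c(1, 1), C = c(9, 9))
  hc <- ward_cluster(m)
  expect_equal(hc$height[1], 0)                       # identical profiles
  expect_identical(sort(hclust_signatures(hc))[1], "A|B")
  m2 <- rbind(A = 0, B = 1, C = 100)
  expect_identical(hclust_signatures(ward_cluster(m2))[1], "A|B")
  expect_error(ward_cluster(m[1, , drop = FALSE]), "at least 2 bins")
  expect_error(ward_cluster(rbind(A = c(1, NA), B = c(0, 1))), "missing")
})

test_that("Ward.D2 merge order and heights match the Lance-Williams oracle", {
  set.seed(99)
  for (i in 1:10) {
    m <- matrix(rnorm(6 * 20), 6, 20,
                dimnames = list(paste0("b", 1:6), NULL))
    hc <- ward_cluster(m)
    oracle <- oracle_ward_d2(m)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-8)
    expect_setequal(hclust_signatures(hc), oracle$signatures)
  }
})

test_that("feature permutation leaves the dendrogram unchanged", {
  m <- planted_profile(seed = 3)
  hc1 <- ward_cluster(m)
  hc2 <- ward_cluster(m[, sample(ncol(m))])
  expect_equal(hc1$merge, hc2$merge)
  expect_equal(hc1$height, hc2$height)
})

test_that("AU fit reproduces closed-form and fallback cases", {
  scales <- seq(0.5, 1.4, 0.1)
  # flat BP_r = 0.5 -> psi = 0 everywhere -> v = c = 0 -> AU = 0.5
  flat <- methylwave:::.fit_au(rep(0.5, 10), scales, B = 1000)
  expect_equal(flat$au, 0.5, tolerance = 1e-12)
  expect_equal(flat$v, 0, tolerance = 1e-12)
  expect_equal(flat$c, 0, tolerance = 1e-12)
  # single usable scale -> AU = BP, flagged
  one <- methylwave:::.fit_au(c(0.8), scales = 1, B = 1000)
  expect_true(one$fallback)
  expect_equal(one$au, 0.8)
  # degenerate scales (0/1) are excluded from the fit
  mixed <- methylwave:::.fit_au(c(1, 1, 1, 1, 1, 1, 1, 1, 0.9, 0.85),
                                scales, B = 1000)
  expect_identical(mixed$n_used, 2L)
})

test_that("a strongly planted split earns AU and BP near 1", {
  m <- planted_profile(gap = 12, jitter = 0.3, seed = 7)
  sd_ <- multiscale_bootstrap(m, B = 200, seed = 1)
  split_sig <- paste(sort(rownames(m)[1:3]), collapse = "|")
  other_sig <- paste(sort(rownames(m)[4:6]), collapse = "|")
  hit <- sd_$edges[sd_$edges$members %in% c(split_sig, other_sig), ]
  expect_gte(nrow(hit), 1)
  expect_true(all(hit$au >= 0.95))
  expect_true(all(hit$bp >= 0.9))
  # BP behaves like a binomial proportion across seeds
  sd2 <- multiscale_bootstrap(m, B = 200, seed = 2)
  bp1 <- sd_$edges$bp[match(split_sig, sd_$edges$members)]
  bp2 <- sd2$edges$bp[match(split_sig, sd2$edges$members)]
  if (!is.na(bp1) && !is.na(bp2)) {
    tol <- 3 * sqrt(max(bp1 * (1 - bp1), 0.25 / 200) / 200) + 1e-9
    expect_lte(abs(bp1 - bp2), max(tol, 0.05))
  }
})

test_that("phase cutting honors height and k semantics", {
  m <- planted_profile(gap = 12, jitter = 0.2, seed = 5)
  hc <- ward_cluster(m)
  root <- max(hc$height)
  expect_identical(cut_phases(hc, height = root + 1)$k, 1L)
  expect_identical(cut_phases(hc, height = 0)$k, nrow(m))
  expect_error(cut_phases(hc, k = 99), "k must be")
  expect_error(cut_phases(hc), "exactly one")
  pa <- cut_phases(hc, k = 2)
  expect_identical(pa$k, 2L)
  # k-mode records the minimal height producing k clusters
  expect_identical(max(stats::cutree(hc, h = pa$cut_height)), 2L)
  expect_identical(unname(pa$phases[1:3]), rep(1L, 3))
  expect_identical(unname(pa$phases[4:6]), rep(2L, 3))
})

test_that("supported-phase counting uses the AU threshold", {
  m <- planted_profile(gap = 12, jitter = 0.3, seed = 7)
  sd_ <- multiscale_bootstrap(m, B = 100, seed = 1)
  pa <- cut_phases(sd_, k = 2)
  expect_identical(sum(pa$supported), 2L)
  pa_impossible <- cut_phases(sd_, k = 2, au_threshold = 1.01)
  expect_identical(sum(pa_impossible$supported), 0L)
})

test_that("sex-stratified comparison reuses one absolute cut height", {
  prof <- planted_profile(gap = 12, jitter = 0.2, seed = 9)
  same <- list(female = prof, male = prof)
  res <- compare_sex_phases(same, cut_height = max(ward_cluster(prof)$height) - 1e-6,
                            B = 50, seed = 3)
  expect_identical(res$female$phases$phases, res$male$phases$phases)
  expect_identical(res$female$n_supported, res$male$n_supported)
  # mismatched bin sets are rejected
  other <- prof; rownames(other)[1] <- "binXX"
  expect_error(compare_sex_phases(list(f = prof, m = other), cut_height = 1),
               "mismatched bin sets")
})

test_that("planted 1- vs 2-boundary groups give 2 vs 3 supported phases", {
  set.seed(31)
  F_ <- 60
  bins <- sprintf("bin%02d", 1:9)
  step <- function(breaks) {
    m <- matrix(rnorm(9 * F_, 0, 0.25), 9, F_,
                dimnames = list(bins, sprintf("cg%03d", 1:F_)))
    for (i in seq_along(breaks)) {
      block <- ((i - 1) * 20 + 1):(i * 20)
      m[(breaks[i] + 1):9, block] <- m[(breaks[i] + 1):9, block] + 8 / sqrt(20)
    }
    m
  }
  male <- step(5)                    # one planted boundary
  female <- step(c(3, 6))            # two planted boundaries
  # shared cut height: above every within-group (noise) merge of both trees,
  # below the female tree's two structural merges
  fh <- sort(ward_cluster(female)$height)
  mh <- sort(ward_cluster(male)$height)
  cut_h <- (max(fh[6], mh[7]) + fh[7]) / 2
  res <- compare_sex_phases(list(female = female, male = male),
                            cut_height = cut_h, B = 100, seed = 5)
  # shared height cuts male into its 2 supported and female into 3
  expect_identical(res$male$phases$k, 2L)
  expect_identical(res$female$phases$k, 3L)
  expect_identical(res$male$n_supported, 2L)
  expect_identical(res$female$n_supported, 3L)
})

test_that("raw-beta clustering shares the attribution code path", {
  sim <- simulate_cohort(sim_config(n_per_cohort = 60, n_cohorts = 1,
    n_cpgs = c(piecewise_phase = 60, null = 30), seed = 41))
  prof <- beta_bin_profile(sim$beta, sim$meta)
  d1 <- cluster_raw_beta(sim$beta, sim$meta, B = 20, seed = 2)
  d2 <- multiscale_bootstrap(prof, B = 20, seed = 2)
  expect_identical(d1$edges, d2$edges)
  expect_equal(d1$hclust$height, d2$hclust$height)
  # constant profiles merge at height zero
  const <- matrix(0.4, 4, 10, dimnames = list(paste0("b", 1:4), NULL))
  expect_true(all(ward_cluster(const)$height == 0))
})

test_that("dendrograms serialize to JSON and Newick with supports", {
  m <- planted_profile(seed = 13)
  sd_ <- multiscale_bootstrap(m, B = 50, seed = 1)
  jpath <- withr::local_tempfile(fileext = ".json")
  npath <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_json(sd_, jpath)
  write_dendrogram_newick(sd_, npath)
  j <- jsonlite::read_json(jpath)
  expect_identical(length(j$edges), nrow(sd_$edges))
  expect_identical(j$settings$B, 50L)
  nwk <- readLines(npath)
  expect_match(nwk, "^\\(.*\\)[0-9.]+;$")
  expect_true(all(vapply(rownames(m), grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})
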