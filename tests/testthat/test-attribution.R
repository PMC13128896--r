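test_that("expected gradients are exact for linear models", {
  set.seed(4)
  w <- c(2.5, -1.2, 0.4)
  mod <- linear_mlp(w, b = 10)
  X <- matrix(runif(30), 10, 3, dimnames = list(paste0("s", 1:10),
                                                mod$features))
  bg <- matrix(runif(15), 5, 3, dimnames = list(paste0("b", 1:5),
                                                mod$features))
  # sanity: the constructed network really is linear
  expect_equal(predict(mod, X), as.vector(X %*% w) + 10, tolerance = 1e-10)
  a <- explain(mod, X, background = bg, n_steps = 20)
  want <- sweep(X, 2, colMeans(bg)) %*% diag(w)
  dimnames(want) <- dimnames(a$phi)
  expect_equal(a$phi, want, tolerance = 1e-10)
  # completeness holds exactly for linear f
  expect_equal(unname(rowSums(a$phi)),
               predict(mod, X) - mean(predict(mod, bg)),
               tolerance = 1e-10)
})

test_that("constant models and ignored features get zero attribution", {
  feats <- c("f1", "f2")
  X <- matrix(runif(8), 4, 2, dimnames = list(NULL, feats))
  a <- explain(constant_mlp(7, feats), X, n_steps = 10)
  expect_true(all(a$phi == 0))
  # dummy axiom: zero-weight input path
  mod <- linear_mlp(c(3, 0), b = 1)
  X2 <- matrix(runif(12), 6, 2, dimnames = list(NULL, mod$features))
  a2 <- explain(mod, X2, n_steps = 10)
  expect_true(all(a2$phi[, 2] == 0))
})

test_that("duplicated identical features share attribution symmetrically", {
  # symmetric network in features 1 and 2 (equal first-layer rows), explained
  # at inputs where x1 == x2
  d <- 3
  W1 <- matrix(rnorm(d * 4), d, 4)
  W1[2, ] <- W1[1, ]
  mod <- structure(list(
    W = list(W1, matrix(rnorm(4), 4, 1)),
    b = list(rep(0.5, 4), 0),
    config = model_config(n_hidden = 1, width = 4, dropout = 0,
                          epochs = 1, lr = 1e-3),
    features = c("dupA", "dupB", "other"), center = NULL, scale = NULL,
    loss_trace = NA_real_), class = "mlp_model")
  x <- runif(6)
  X <- cbind(dupA = x, dupB = x, other = runif(6))
  bg <- cbind(dupA = rep(0.5, 4), dupB = rep(0.5, 4), other = runif(4))
  a <- explain(mod, X, background = bg, n_steps = 40)
  expect_equal(a$phi[, "dupA"], a$phi[, "dupB"], tolerance = 1e-10)
})

test_that("the estimator is seeded and background subsampling reproducible", {
  fix <- trained_fixture(1)
  X <- fix$design[1:20, ]
  mod <- fix$ensemble$models[[1]]
  a1 <- explain(mod, X, background = fix$design, n_steps = 30,
                n_background = 10, seed = 42)
  a2 <- explain(mod, X, background = fix$design, n_steps = 30,
                n_background = 10, seed = 42)
  expect_identical(a1$phi, a2$phi)
  expect_identical(a1$background_ids, a2$background_ids)
  expect_error(explain(mod, X, background = X[0, , drop = FALSE]),
               "non-empty")
})

test_that("age-bin profiles average signed values and magnitudes", {
  bins <- age_bin_scheme()
  phi <- rbind(c(1, -1), c(3, 1))
  colnames(phi) <- c("cg1", "cg2")
  meta <- data.frame(sample_id = c("a", "b"), age = c(22, 23),
                     sex = c(0L, 1L), cohort = "c")
  suppressMessages(prof <- bin_profiles(phi, meta, bins))
  expect_identical(rownames(prof$signed), "20-24")      # one populated bin
  expect_equal(unname(prof$signed[1, ]), c(2, 0))
  expect_equal(unname(prof$magnitude[1, ]), c(2, 1))
  # single sample in a bin reproduces that sample's row
  meta2 <- data.frame(sample_id = c("a", "b"), age = c(22, 47),
                      sex = c(0L, 1L), cohort = "c")
  suppressMessages(prof2 <- bin_profiles(phi, meta2, bins))
  expect_equal(unname(prof2$signed["45-49", ]), unname(phi[2, ]))
})

test_that("the sex indicator column is excluded from profiles", {
  phi <- cbind(cg1 = c(1, 2), sex = c(5, 5))
  meta <- data.frame(sample_id = c("a", "b"), age = c(30, 31),
                     sex = c(0L, 1L), cohort = "c")
  suppressMessages(prof <- bin_profiles(phi, meta))
  expect_identical(colnames(prof$signed), "cg1")
})

test_that("extreme-CpG selection ranks by magnitude with ID tie-break", {
  mag <- c(cgB = 0.5, cgA = 0.5, cgC = 2, cgD = 0.1)
  sel <- select_extreme_cpgs(mag, k = 1)
  expect_identical(sel$top, "cgC")
  expect_identical(sel$bottom, "cgD")
  sel2 <- select_extreme_cpgs(mag, k = 2)
  expect_identical(sel2$top, c("cgC", "cgA"))           # tie -> lexicographic
  all_of_them <- select_extreme_cpgs(mag, k = 10)
  expect_setequal(all_of_them$top, names(mag))
  expect_setequal(all_of_them$bottom, names(mag))
  expect_error(select_extreme_cpgs(mag, k = 0), "k must be")
})

test_that("boundary-step CpGs express their step in the bin profiles", {
  fix <- trained_fixture(1)
  prof <- bin_profiles(fix$attr, fix$sim$meta)
  cls <- fix$sim$truth$class[colnames(prof$signed)]
  pw <- colnames(prof$signed)[!is.na(cls) & cls == "piecewise_phase"]
  boundaries <- vapply(fix$sim$truth$params[pw], `[[`, numeric(1), "boundary")
  # attribution jump across a CpG's own boundary vs a far within-phase pair
  jump_at <- function(cg, from, to)
    abs(prof$signed[to, cg] - prof$signed[from, cg])
  pairs <- list(`35` = c("30-34", "35-39", "20-24", "25-29"),
                `45` = c("40-44", "45-49", "55-59", "60-64"),
                `65` = c("60-64", "65-69", "50-54", "55-59"))
  ratios <- vapply(pw, function(cg) {
    p <- pairs[[as.character(boundaries[cg])]]
    (jump_at(cg, p[1], p[2]) + 1e-9) / (jump_at(cg, p[3], p[4]) + 1e-9)
  }, numeric(1))
  # on average the planted step dominates within-phase drift
  expect_gt(stats::median(ratios), 2)
  # and step CpGs' boundary jumps exceed null CpGs' jumps at the same bins
  nulls <- colnames(prof$signed)[!is.na(cls) & cls == "null"]
  if (length(nulls)) {
    null_jump <- mean(vapply(nulls, jump_at, numeric(1),
                             from = "60-64", to = "65-69"))
    pw65 <- pw[boundaries == 65]
    step_jump <- mean(vapply(pw65, jump_at, numeric(1),
                             from = "60-64", to = "65-69"))
    expect_gt(step_jump, null_jump)
  }
})

test_that("attribution artifacts serialize with their sidecar", {
  fix <- trained_fixture(1)
  sub <- methylwave:::.subset_attr(fix$attr, 1:5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_attributions(sub, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- data.table::fread(path, data.table = FALSE)
  expect_equal(as.matrix(back[, -1]), unname(sub$phi), ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$n_steps, sub$n_steps)
})
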