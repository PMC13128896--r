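toy_world <- function(n = 60, seed = 5) {
  set.seed(seed)
  m <- matrix(runif(3 * n), 3, n,
              dimnames = list(c("cgA", "cgB", "cgC"), paste0("s", 1:n)))
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     age = runif(n, 20, 80),
                     sex = rep_len(c(0L, 1L), n),
                     cohort = rep_len(c("c1", "c2", "c3"), n))
  list(m = m, meta = meta)
}

test_that("make_design enforces the feature + sex contract", {
  w <- toy_world()
  X <- make_design(w$m, w$meta, c("cgB", "cgA", "cgC"))
  expect_identical(colnames(X), c("cgB", "cgA", "cgC", "sex"))
  expect_identical(rownames(X), w$meta$sample_id)
  # rows follow meta order even when shuffled
  shuf <- w$meta[rev(seq_len(nrow(w$meta))), ]
  Xs <- make_design(w$m, shuf, c("cgB", "cgA", "cgC"))
  expect_identical(rownames(Xs), shuf$sample_id)
  expect_equal(Xs[w$meta$sample_id, ], X[w$meta$sample_id, ])
  expect_error(make_design(w$m, w$meta, c("cgA", "cgZ")), "cgZ")
  w$meta$sex[3] <- NA
  expect_error(make_design(w$m, w$meta, "cgA"), "missing sex")
})

test_that("the MLP fits an exactly representable target to < 0.5 years", {
  set.seed(1)
  n <- 150
  beta1 <- runif(n)
  design <- cbind(cg1 = beta1, sex = rep_len(c(0, 1), n))
  ages <- 100 * beta1
  mod <- train_mlp(design, ages,
                   small_model_config(width = 32, epochs = 2500, l2 = 0))
  expect_lt(mean(abs(predict(mod, design) - ages)), 0.5)
})

test_that("training is seed-deterministic and epoch-monotone on hard targets", {
  set.seed(2)
  n <- 80
  design <- cbind(cg1 = runif(n), cg2 = runif(n), sex = rep_len(c(0, 1), n))
  ages <- 40 + 30 * design[, "cg1"] - 20 * design[, "cg2"] + rnorm(n, 0, 1)
  m1 <- train_mlp(design, ages, small_model_config(epochs = 150, seed = 9))
  m2 <- train_mlp(design, ages, small_model_config(epochs = 150, seed = 9))
  expect_identical(predict(m1, design), predict(m2, design))
  short <- train_mlp(design, ages, small_model_config(epochs = 10, seed = 9))
  long <- train_mlp(design, ages, small_model_config(epochs = 2000, seed = 9))
  expect_gt(mean(abs(predict(short, design) - ages)),
            mean(abs(predict(long, design) - ages)))
})

test_that("non-finite loss is reported as an error", {
  design <- cbind(cg1 = c(0.1, 0.9, 0.5, 0.2), sex = c(0, 1, 0, 1))
  expect_error(
    train_mlp(design, c(30, 60, 45, 35),
              model_config(n_hidden = 2, width = 8, dropout = 0,
                           l2 = 0, lr = 1e200, epochs = 5)),
    "non-finite")
})

test_that("LOCO builds one leakage-free submodel per held-out cohort", {
  w <- toy_world(n = 90, seed = 8)
  X <- make_design(w$m, w$meta, rownames(w$m))
  cfg <- small_model_config(epochs = 30)
  ens <- loco_train(X, w$meta$age, w$meta$cohort, cfg)
  expect_s3_class(ens, "loco_ensemble")
  expect_identical(sort(names(ens$models)), c("c1", "c2", "c3"))
  expect_identical(nrow(ens$folds), 3L)
  # two cohorts -> two submodels; one cohort -> error
  two <- w$meta$cohort %in% c("c1", "c2")
  ens2 <- loco_train(X[two, ], w$meta$age[two], w$meta$cohort[two], cfg)
  expect_identical(length(ens2$models), 2L)
  expect_error(loco_train(X, w$meta$age, rep("only", nrow(X)), cfg),
               "at least 2 cohorts")
  # always-train cohort is never held out
  ens3 <- loco_train(X, w$meta$age, w$meta$cohort, cfg, always_train = "c1")
  expect_identical(sort(ens3$excluded), c("c2", "c3"))
})

test_that("LOCO training is isolated from its held-out cohort", {
  w <- toy_world(n = 90, seed = 12)
  X <- make_design(w$m, w$meta, rownames(w$m))
  cfg <- small_model_config(epochs = 40)
  ens <- loco_train(X, w$meta$age, w$meta$cohort, cfg)
  ages_bad <- w$meta$age
  ages_bad[w$meta$cohort == "c2"] <- 999   # corrupt held-out labels
  ens_bad <- loco_train(X, ages_bad, w$meta$cohort, cfg)
  expect_identical(ens$models[["c2"]]$W, ens_bad$models[["c2"]]$W)
  expect_identical(ens$models[["c2"]]$b, ens_bad$models[["c2"]]$b)
})

test_that("predict_age averages submodels and enforces the contract", {
  feats <- c("cgA", "cgB", "sex")
  fake <- structure(list(
    models = list(a = constant_mlp(40, feats), b = constant_mlp(50, feats),
                  c = constant_mlp(60, feats)),
    excluded = c("a", "b", "c"), folds = NULL, features = feats,
    config = small_model_config()), class = "loco_ensemble")
  X <- matrix(runif(6), 2, 3, dimnames = list(c("s1", "s2"), feats))
  expect_equal(unname(predict_age(fake, X)), c(50, 50))
  one <- fake; one$models <- one$models["b"]
  expect_equal(unname(predict_age(one, X)), c(50, 50))
  Xp <- X[, c(2, 1, 3)]
  expect_error(predict_age(fake, Xp), "contract")
})

test_that("random-search tuning returns the argmin trial, reproducibly", {
  w <- toy_world(n = 60, seed = 3)
  X <- make_design(w$m, w$meta, rownames(w$m))
  space <- list(n_hidden = c(1L, 2L), width = c(8L, 16L),
                dropout = c(0.15, 0.3), l2 = c(1e-6, 1e-2),
                lr = c(1e-3, 1e-2), epochs = c(10L, 30L))
  t1 <- tune_hyperparameters(X, w$meta$age, w$meta$cohort, space,
                             n_trials = 3, seed = 4)
  t2 <- tune_hyperparameters(X, w$meta$age, w$meta$cohort, space,
                             n_trials = 3, seed = 4)
  expect_identical(t1$trials, t2$trials)               # seeded trial sequence
  expect_equal(t1$best_mae, min(t1$trials$mean_loco_mae))
  best_row <- t1$trials[which.min(t1$trials$mean_loco_mae), ]
  expect_identical(t1$best_config$width, best_row$width)
  expect_identical(t1$best_config$epochs, best_row$epochs)
  single <- tune_hyperparameters(X, w$meta$age, w$meta$cohort, space,
                                 n_trials = 1, seed = 4)
  expect_identical(single$best_config$width, single$trials$width[1])
})

test_that("ensembles stay within 2x the best submodel on unseen cohorts", {
  sim <- simulate_cohort(sim_config(n_per_cohort = 80, n_cohorts = 3,
    n_cpgs = c(linear = 40, null = 40), seed = 23))
  holdout <- sim$meta$cohort == "cohort3"
  tab <- stratified_correlations(sim$beta[, !holdout], sim$meta[!holdout, ],
                                 stratum_scheme())
  fs <- select_features(tab, 0.1)
  X <- make_design(sim$beta, sim$meta, fs)
  ens <- loco_train(X[!holdout, ], sim$meta$age[!holdout],
                    sim$meta$cohort[!holdout], small_model_config(epochs = 200))
  truth <- sim$meta$age[holdout]
  ens_mae <- mean(abs(predict_age(ens, X[holdout, ]) - truth))
  sub_mae <- vapply(ens$models, function(mod)
    mean(abs(predict(mod, X[holdout, ]) - truth)), numeric(1))
  expect_true(is.finite(ens_mae))
  expect_lte(ens_mae, 2 * min(sub_mae))
})

test_that("model bundles survive a save/load round trip", {
  w <- toy_world(n = 40, seed = 6)
  X <- make_design(w$m, w$meta, rownames(w$m))
  ens <- loco_train(X, w$meta$age, w$meta$cohort, small_model_config(epochs = 20))
  dir <- withr::local_tempdir()
  save_model(ens, dir)
  expect_true(file.exists(file.path(dir, "features.txt")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- load_model(dir)
  expect_identical(predict_age(back, X), predict_age(ens, X))
})
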