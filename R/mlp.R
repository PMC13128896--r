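#' Configure the feed-forward age regressor
#'
#' The production default mirrors the tuned configuration used at full
#' cohort scale: two hidden layers of 1024 units, dropout 0.25, L2
#' 1.71e-5, learning rate 3.06e-5, 5000 epochs. That network is far too
#' large for test-sized cohorts; [small_model_config()] gives the
#' desk-scale default (2 x 64 units, 300 epochs).
#'
#' @param n_hidden number of hidden layers
#' @param width hidden layer width (search space uses 128/256/512/1024)
#' @param dropout hidden-unit dropout rate in [0, 1)
#' @param l2 L2 weight-decay strength
#' @param lr Adam learning rate
#' @param epochs full-batch training epochs
#' @param seed RNG seed for init, dropout and shuffling
#' @param standardize z-score inputs before training (default FALSE; beta is
#'   already bounded in [0, 1])
#' @param lr_schedule `"constant"`, or `"cosine"` decay of the learning rate
#'   to 1 percent of `lr` over the run (the desk-scale default: at the
#'   larger desk learning rate a constant-step Adam leaves the weights
#'   oscillating, and the converged fit gives crisper attributions)
#' @return object of class `model_config`
#' @export
model_config <- function(n_hidden = 2L, width = 1024L, dropout = 0.25,
                         l2 = 1.71e-5, lr = 3.06e-5, epochs = 5000L,
                         seed = 1L, standardize = FALSE,
                         lr_schedule = c("constant", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  .assert(n_hidden >= 1L, "need at least one hidden layer")
  .assert(width >= 1L, "width must be >= 1")
  .assert(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  .assert(l2 >= 0 && lr > 0 && epochs >= 1L, "invalid l2/lr/epochs")
  structure(list(n_hidden = as.integer(n_hidden), width = as.integer(width),
                 dropout = dropout, l2 = l2, lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 standardize = isTRUE(standardize),
                 lr_schedule = lr_schedule),
            class = "model_config")
}

#' @rdname model_config
#' @param ... overrides passed to [model_config()]
#' @export
small_model_config <- function(...) {
  defaults <- list(n_hidden = 2L, width = 64L, dropout = 0, l2 = 0.01,
                   lr = 0.01, epochs = 300L, seed = 1L,
                   lr_schedule = "cosine")
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# He-initialized parameter list for a given layer-size vector
.mlp_init <- function(sizes) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                  sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass; returns activations and pre-activations for backprop.
# drop_masks: list of inverted-dropout masks (NULL = evaluation mode)
.mlp_forward <- function(par, X, drop_masks = NULL) {
  L <- length(par$W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], "+")
    if (l < L) {
      h <- pmax(Z[[l]], 0)
      if (!is.null(drop_masks)) h <- h * drop_masks[[l]]
      A[[l + 1L]] <- h
    } else {
      A[[l + 1L]] <- Z[[l]]
    }
  }
  list(A = A, Z = Z)
}

#' Train the multilayer perceptron age regressor
#'
#' Full-batch training with the Adam optimizer on a squared-error loss plus
#' L2 weight decay, ReLU hidden activations and a linear scalar output.
#' With a fixed `config$seed` the fit is bit-reproducible on the same
#' platform.
#'
#' @param design samples x features numeric matrix (see [make_design()])
#' @param ages numeric response, decimal years
#' @param config a [model_config()]
#' @return object of class `mlp_model`
#' @export
train_mlp <- function(design, ages, config = small_model_config()) {
  .assert(inherits(config, "model_config"), "config must be a model_config")
  design <- as.matrix(design)
  .assert(nrow(design) >= 2L, "need at least 2 samples")
  .assert(nrow(design) == length(ages) && all(is.finite(ages)),
          "ages must be finite and aligned with the design")
  .assert(all(is.finite(design)), "design contains non-finite values (impute first)")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  center <- NULL; scale <- NULL
  X <- design
  if (config$standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  }
  n <- nrow(X); d <- ncol(X)
  sizes <- c(d, rep(config$width, config$n_hidden), 1L)
  par <- .mlp_init(sizes)
  L <- length(par$W)

  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  y <- matrix(ages, ncol = 1L)
  loss_trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    masks <- NULL
    if (config$dropout > 0) {
      masks <- lapply(seq_len(L - 1L), function(l)
        matrix(stats::rbinom(n * sizes[l + 1L], 1L, 1 - config$dropout),
               n, sizes[l + 1L]) / (1 - config$dropout))
    }
    fwd <- .mlp_forward(par, X, masks)
    resid <- fwd$A[[L + 1L]] - y
    loss <- mean(resid^2)
    if (!is.finite(loss))
      stop(sprintf("non-finite training loss at epoch %d (lr %g may be too large)",
                   epoch, config$lr), call. = FALSE)
    loss_trace[epoch] <- loss

    delta <- 2 * resid / n                      # dL/dz at output
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- crossprod(fwd$A[[l]], delta) + config$l2 * par$W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(par$W[[l]])) * (fwd$Z[[l - 1L]] > 0)
        if (!is.null(masks)) delta <- delta * masks[[l - 1L]]
      }
    }
    lr_t <- if (identical(config$lr_schedule, "cosine"))
      config$lr * (0.01 + 0.99 * (1 + cos(pi * (epoch - 1) / config$epochs)) / 2)
    else config$lr
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      corr1 <- 1 - beta1^epoch; corr2 <- 1 - beta2^epoch
      par$W[[l]] <- par$W[[l]] - lr_t * (mW[[l]] / corr1) /
        (sqrt(vW[[l]] / corr2) + eps)
      par$b[[l]] <- par$b[[l]] - lr_t * (mb[[l]] / corr1) /
        (sqrt(vb[[l]] / corr2) + eps)
    }
  }
  structure(list(W = par$W, b = par$b, config = config,
                 features = colnames(design), center = center, scale = scale,
                 loss_trace = loss_trace),
            class = "mlp_model")
}

# evaluation-mode forward pass on raw (unstandardized) input
.mlp_eval <- function(model, design) {
  X <- as.matrix(design)
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  fwd <- .mlp_forward(list(W = model$W, b = model$b), X)
  as.vector(fwd$A[[length(fwd$A)]])
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  .check_contract(object$features, colnames(newdata))
  .mlp_eval(object, newdata)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("mlp_model:", length(x$features), "inputs,",
      x$config$n_hidden, "x", x$config$width, "hidden units,",
      x$config$epochs, "epochs (final loss",
      signif(utils::tail(x$loss_trace, 1), 4), ")\n")
  invisible(x)
}

# gradient of the scalar output w.r.t. each input, per sample (n x d).
# Used by expected-gradients attribution; evaluation mode (no dropout).
.mlp_input_gradient <- function(model, design) {
  X <- as.matrix(design)
  if (!is.null(model$center))
    X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  par <- list(W = model$W, b = model$b)
  fwd <- .mlp_forward(par, X)
  L <- length(par$W)
  delta <- matrix(1, nrow(X), 1L)
  for (l in L:2) {
    delta <- (delta %*% t(par$W[[l]])) * (fwd$Z[[l - 1L]] > 0)
  }
  g <- delta %*% t(par$W[[1L]])
  if (!is.null(model$scale)) g <- sweep(g, 2L, model$scale, "/")
  g
}

.check_contract <- function(expected, got) {
  if (is.null(got) || length(got) != length(expected) || !all(got == expected)) {
    stop("design columns do not match the model's feature contract ",
         "(same features in the same order are required)", call. = FALSE)
  }
  invisible(TRUE)
}
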