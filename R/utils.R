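#' Logit and inverse-logit
#'
#' Methylation beta-values are modelled on the logit scale throughout the
#' package (M-value scale up to a factor of log2); the inverse transform
#' guarantees simulated beta stays inside (0, 1) without clipping.
#'
#' @param p proportions in (0, 1)
#' @param x real values
#' @return numeric vector
#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Derive a per-stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds so that every stage is
#' independently reproducible. The derivation is a fixed polynomial hash of
#' the stage name folded into the global seed, kept below 2^31 - 1.
#'
#' @param seed integer global seed
#' @param stage character scalar, e.g. `"simulate"`, `"train"`
#' @return integer seed
#' @export
#' @examples
#' derive_seed(1L, "train")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

# shared assertion helper: stop with caller's message when cond fails
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted phase partitions. Standard
#' Hubert-Arabie form; 1 for identical partitions (up to label
#' permutation), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length
#' @return numeric scalar
#' @export
adjusted_rand_index <- function(a, b) {
  .assert(length(a) == length(b), "labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
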