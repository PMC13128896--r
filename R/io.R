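#' Read a beta-value matrix from delimited text
#'
#' Expects a header row and a first column of probe IDs (series-matrix style,
#' probes as rows); set `samples_as_rows = TRUE` for the transposed layout.
#' Empty fields and the literal "NA" are read as missing values, never as 0.
#'
#' @param path TSV/CSV file path (delimiter auto-detected by data.table)
#' @param samples_as_rows logical; input has samples as rows
#' @return numeric matrix, probes x samples, values in [0, 1] or NA
#' @export
read_beta_matrix <- function(path, samples_as_rows = FALSE) {
  dt <- data.table::fread(path, header = TRUE, na.strings = c("", "NA"),
                          data.table = FALSE)
  .assert(ncol(dt) >= 2L, "beta matrix file needs an ID column plus data")
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (samples_as_rows) m <- t(m)
  .validate_beta(m)
  m
}

.validate_beta <- function(m) {
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))])[1:5], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))])[1:5], collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value out of [0,1]: probe %s, sample %s (value %g)",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  invisible(m)
}

#' Write a beta matrix as TSV (probes as rows)
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces the matrix bit-exactly.
#'
#' @param m probes x samples matrix
#' @param path output path
#' @export
write_beta_matrix <- function(m, path) {
  txt <- matrix(ifelse(is.na(m), NA_character_, sprintf("%.17g", m)),
                nrow(m), ncol(m))
  dt <- data.table::data.table(probe_id = rownames(m))
  for (j in seq_len(ncol(m))) data.table::set(dt, j = colnames(m)[j], value = txt[, j])
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' CSV with columns sample_id, age (decimal years), sex (0 = female,
#' 1 = male, NA = unknown), cohort. One row per unique individual.
#'
#' @param path CSV path
#' @return data.frame
#' @export
read_sample_meta <- function(path) {
  df <- data.table::fread(path, header = TRUE, na.strings = c("", "NA", "unknown"),
                          data.table = FALSE)
  need <- c("sample_id", "age", "sex", "cohort")
  .assert(all(need %in% names(df)),
          paste("sample sheet must have columns:", paste(need, collapse = ", ")))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  df$cohort <- as.character(df$cohort)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  .assert(all(is.finite(df$age)), "ages must be finite")
  .assert(all(is.na(df$sex) | df$sex %in% c(0L, 1L)),
          "sex must be 0 (female), 1 (male) or NA")
  df
}

#' @rdname read_sample_meta
#' @param meta data.frame with the four sample-sheet columns
#' @export
write_sample_meta <- function(meta, path) {
  data.table::fwrite(meta[, c("sample_id", "age", "sex", "cohort")], path,
                     na = "NA", quote = FALSE)
  invisible(path)
}

#' Collapse EPIC v2 replicate addresses to canonical probe IDs
#'
#' EPIC v2 names replicate addresses as `cgXXXXXXXX_<suffix>`. The canonical
#' ID is the text before the first underscore; replicate rows are averaged
#' over their non-missing values. Unsuffixed probes pass through unchanged,
#' so the operation is idempotent.
#'
#' @param m probes x samples beta matrix
#' @return beta matrix with unique canonical probe IDs
#' @export
collapse_epicv2 <- function(m) {
  canonical <- sub("_.*$", "", rownames(m))
  if (!anyDuplicated(canonical)) {
    rownames(m) <- canonical
    return(m)
  }
  grp <- factor(canonical, levels = unique(canonical))
  present <- !is.na(m)
  vals <- m
  vals[!present] <- 0
  sums <- rowsum(vals, grp)
  counts <- rowsum(present + 0, grp)
  out <- sums / counts          # 0/0 -> NaN for all-missing groups
  out[counts == 0] <- NA
  rownames(out) <- levels(grp)
  out
}

#' Restrict matrices to their shared probe set
#'
#' Mirrors cross-platform harmonization: only CpGs present in every input
#' are kept, in the first matrix's order, so all outputs have identical row
#' spaces.
#'
#' @param matrices list of >= 2 beta matrices
#' @return list with `matrices` (restricted, same row order) and `shared`
#'   (the common probe IDs)
#' @export
harmonize <- function(matrices) {
  .assert(is.list(matrices) && length(matrices) >= 2L,
          "harmonize needs a list of at least two matrices")
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(shared)) stop("no probes shared across matrices", call. = FALSE)
  list(matrices = lapply(matrices, function(m) m[shared, , drop = FALSE]),
       shared = shared)
}

#' Fill missing beta values
#'
#' `probe_mean` fills each probe's gaps with the mean of its observed values.
#' `reference_then_probe_mean` first fills from a named vector of whole-blood
#' reference means and falls back to probe means for residual gaps. Observed
#' entries are never altered.
#'
#' @param m probes x samples beta matrix
#' @param strategy `"probe_mean"` or `"reference_then_probe_mean"`
#' @param reference_means named numeric vector of per-probe reference means
#' @return matrix with no missing values
#' @export
impute_missing <- function(m, strategy = c("probe_mean", "reference_then_probe_mean"),
                           reference_means = NULL) {
  strategy <- match.arg(strategy)
  if (!anyNA(m)) return(m)
  if (strategy == "reference_then_probe_mean") {
    .assert(!is.null(reference_means), "strategy needs reference_means")
    hit <- rownames(m)[rownames(m) %in% names(reference_means)]
    for (p in hit) {
      nas <- is.na(m[p, ])
      if (any(nas)) m[p, nas] <- reference_means[[p]]
    }
  }
  miss_rows <- which(rowSums(is.na(m)) > 0L)
  if (length(miss_rows)) {
    means <- rowMeans(m[miss_rows, , drop = FALSE], na.rm = TRUE)
    dead <- miss_rows[!is.finite(means)]
    if (length(dead))
      stop("probe(s) with all values missing and no reference mean: ",
           paste(rownames(m)[dead][1:min(5, length(dead))], collapse = ", "),
           call. = FALSE)
    for (k in seq_along(miss_rows)) {
      i <- miss_rows[k]
      nas <- is.na(m[i, ])
      m[i, nas] <- means[k]
    }
  }
  m
}
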