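#' Age acceleration (delta-age)
#'
#' Biological (predicted) age minus chronological age, elementwise.
#'
#' @param predicted,chronological aligned numeric vectors
#' @return numeric vector
#' @export
delta_age <- function(predicted, chronological) {
  .assert(length(predicted) == length(chronological),
          "predicted and chronological must align")
  predicted - chronological
}

#' Calibration panel for a clock's predictions
#'
#' Computes the standard benchmarking panel: N, MAE, median AE, RMSE, bias
#' (mean of predicted - chronological), Pearson r, Spearman rho, R-squared
#' (defined as squared Pearson r — the only definition consistent with the
#' reported benchmark rows), slope and intercept of the least-squares fit of
#' predicted on chronological age, and Age_Accel_SD (sample SD of
#' delta-age, n - 1 denominator). Full precision is kept internally;
#' rounding happens only in [format_calibration()].
#'
#' @param predicted,chronological aligned numeric vectors, n >= 3, finite
#' @return object of class `calibration_report` (a named list)
#' @export
calibration_metrics <- function(predicted, chronological) {
  .assert(length(predicted) == length(chronological), "vectors must align")
  n <- length(predicted)
  .assert(n >= 3L, "need at least 3 samples")
  .assert(all(is.finite(predicted)) && all(is.finite(chronological)),
          "values must be finite")
  if (stats::sd(chronological) == 0)
    stop("chronological age is constant; slope undefined", call. = FALSE)
  d <- delta_age(predicted, chronological)
  r <- stats::cor(predicted, chronological)
  fit <- stats::lm.fit(cbind(1, chronological), predicted)
  structure(list(
    n = n,
    mae = mean(abs(d)),
    medae = stats::median(abs(d)),
    rmse = sqrt(mean(d^2)),
    bias = mean(d),
    pearson_r = r,
    spearman_rho = stats::cor(predicted, chronological, method = "spearman"),
    r2 = r^2,
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    age_accel_sd = stats::sd(d)
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration: n=%d MAE=%.2f RMSE=%.2f bias=%.2f r=%.3f slope=%.3f\n",
              x$n, x$mae, x$rmse, x$bias, x$pearson_r, x$slope))
  invisible(x)
}

#' Format calibration reports like a benchmark table row
#'
#' @param x a `calibration_report`
#' @return one-row data.frame with conventional 2-3 decimal rounding
#' @export
format_calibration <- function(x) {
  data.frame(N = x$n, MAE = round(x$mae, 2), MedAE = round(x$medae, 2),
             RMSE = round(x$rmse, 2), Bias = round(x$bias, 2),
             Pearson_r = round(x$pearson_r, 3),
             Spearman_rho = round(x$spearman_rho, 3),
             R2 = round(x$r2, 3), Slope = round(x$slope, 3),
             Intercept = round(x$intercept, 2),
             Age_Accel_SD = round(x$age_accel_sd, 2))
}

#' Rank clocks by MAE
#'
#' @param reports named list of `calibration_report`s (names = clock names)
#' @return data.frame ordered by ascending MAE (ties broken by clock name),
#'   with a Rank column
#' @export
rank_clocks <- function(reports) {
  .assert(length(reports) >= 1L, "need at least one report")
  .assert(!is.null(names(reports)) && all(nzchar(names(reports))),
          "reports must be named by clock")
  rows <- do.call(rbind, lapply(reports, format_calibration))
  rows <- cbind(Clock = names(reports), rows)
  ord <- order(vapply(reports, `[[`, numeric(1), "mae"), names(reports))
  rows <- rows[ord, , drop = FALSE]
  cbind(Rank = seq_len(nrow(rows)), rows, row.names = NULL)
}

#' Cell-composition sensitivity analysis
#'
#' Regresses a clock's predictions on leukocyte fractions (least squares
#' with intercept; rank-deficient fraction matrices are handled by the
#' pivoting QR with a warning), reports the variance explained
#' (`r2_cells`), the raw and cell-adjusted correlations of the clock with
#' age (adjusted = Pearson correlation of the residualized clock with age;
#' age itself is not residualized), their difference `delta_r`, and
#' per-fraction Pearson correlations with the clock.
#'
#' @param clock numeric clock predictions
#' @param fractions samples x fractions numeric matrix (conventionally the
#'   12 deconvolved leukocyte fractions), no missing values
#' @param ages chronological ages aligned with `clock`
#' @return object of class `cell_adjustment_report`
#' @export
cell_adjustment <- function(clock, fractions, ages) {
  fractions <- as.matrix(fractions)
  .assert(length(clock) == nrow(fractions) && length(ages) == length(clock),
          "clock, fractions and ages must align")
  .assert(!anyNA(clock) && !anyNA(fractions) && !anyNA(ages),
          "missing values are not allowed")
  X <- cbind(`(Intercept)` = 1, fractions)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    warning("fraction matrix is rank-deficient; fit uses the pivoting QR ",
            "(coefficients of aliased fractions are dropped)")
  coefs <- qr.coef(qr_x, clock)
  fitted <- as.vector(X[, !is.na(coefs), drop = FALSE] %*% coefs[!is.na(coefs)])
  resid <- clock - fitted
  ss_tot <- sum((clock - mean(clock))^2)
  r2_cells <- if (ss_tot == 0) 0 else 1 - sum(resid^2) / ss_tot
  raw_r <- stats::cor(clock, ages)
  degenerate <- stats::sd(resid) < .Machine$double.eps^0.5 * max(1, stats::sd(clock))
  adjusted_r <- if (degenerate) 0 else stats::cor(resid, ages)
  per_fraction <- apply(fractions, 2L, function(f)
    if (stats::sd(f) == 0) NA_real_ else stats::cor(clock, f))
  structure(list(r2_cells = r2_cells, raw_r = raw_r,
                 adjusted_r = adjusted_r, delta_r = adjusted_r - raw_r,
                 per_fraction_r = per_fraction,
                 degenerate_residuals = degenerate),
            class = "cell_adjustment_report")
}

#' @export
print.cell_adjustment_report <- function(x, ...) {
  cat(sprintf("cell adjustment: R2_cells=%.3f raw r=%.3f adjusted r=%.3f (delta %.3f)%s\n",
              x$r2_cells, x$raw_r, x$adjusted_r, x$delta_r,
              if (x$degenerate_residuals) " [degenerate residuals]" else ""))
  invisible(x)
}

#' Read an external clock prediction table
#'
#' CSV with columns sample_id, clock_name, predicted_age (long format, one
#' row per sample per clock).
#'
#' @param path CSV path
#' @return data.frame
#' @export
read_prediction_table <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("sample_id", "clock_name", "predicted_age")
  .assert(all(need %in% names(df)),
          paste("prediction table needs columns:", paste(need, collapse = ", ")))
  df[, need]
}
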