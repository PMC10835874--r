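#' Library-size normalization and log transform
#'
#' Scales every sample to a common library size (the median of the observed
#' per-sample totals by default) and applies \code{log2(x + 1)}. This is the
#' variance-stabilizing step applied before gene filtering and z-scoring;
#' because all downstream scoring operates on gene-wise z-scores, results are
#' insensitive to the exact choice of stabilizer, and this simple transform
#' keeps the chain fully reproducible from plain count tables.
#'
#' @param x an \code{expression_matrix} at stage \code{"counts"}.
#' @param target_size library size every sample is scaled to; defaults to
#'   the median per-sample total.
#' @return An \code{expression_matrix} at stage \code{"normalized"}.
#' @export
normalize_log <- function(x, target_size = NULL) {
  assert_stage(x, "counts")
  v <- x$values
  if (anyNA(v) || any(v < 0))
    abort("counts must be non-negative and complete", "invalid_input")
  totals <- colSums(v)
  zero <- totals == 0
  if (any(zero))
    abort(sprintf("all-zero sample(s): %s",
                  paste(colnames(v)[zero], collapse = ", ")),
          "degenerate_sample")
  if (is.null(target_size)) target_size <- stats::median(totals)
  scaled <- sweep(v, 2, target_size / totals, `*`)
  expression_matrix(log2(scaled + 1), "normalized")
}

#' Remove low-variability genes by the interquartile-range filter
#'
#' Computes the IQR of every gene across samples and removes genes whose IQR
#' is strictly smaller than the \code{cutoff}-quantile of all gene IQRs
#' (linear-interpolation quantile, the R default, type 7). With the default
#' \code{cutoff = 0.25} this drops genes below the 25th percentile of the
#' IQR distribution. Gene order is preserved; ties at the threshold are kept.
#'
#' @param x an \code{expression_matrix} at stage \code{"normalized"}.
#' @param cutoff quantile of the gene-IQR distribution used as threshold,
#'   in \code{[0, 1)}.
#' @return The filtered \code{expression_matrix}, same stage.
#' @export
iqr_filter <- function(x, cutoff = 0.25) {
  assert_stage(x, "normalized")
  if (!is_prob(cutoff) || cutoff >= 1)
    abort("cutoff must be in [0, 1)", "invalid_parameter")
  if (ncol(x$values) < 2)
    abort("iqr_filter needs at least 2 samples", "invalid_input")
  iqrs <- apply(x$values, 1, stats::IQR, type = 7)
  thr <- stats::quantile(iqrs, cutoff, type = 7, names = FALSE)
  keep <- !(iqrs < thr)   # strict "<": genes at the threshold survive
  expression_matrix(x$values[keep, , drop = FALSE], x$stage)
}

#' Gene-wise z-scores
#'
#' Standardizes every gene to mean 0 and sample SD 1 (denominator n - 1)
#' across samples of one cohort. Cohorts are standardized independently;
#' no cross-cohort batch correction is performed by design.
#'
#' @param x an \code{expression_matrix} at stage \code{"normalized"} (an
#'   already standardized matrix is accepted and re-standardized, which is
#'   an exact no-op).
#' @return An \code{expression_matrix} at stage \code{"standardized"}.
#' @export
standardize_genes <- function(x) {
  assert_stage(x, c("normalized", "standardized"))
  v <- x$values
  if (ncol(v) < 2)
    abort("standardization needs at least 2 samples", "invalid_input")
  s <- row_sds(v)
  bad <- s == 0 | !is.finite(s)
  if (any(bad))
    abort(sprintf("zero-variance gene(s): %s",
                  paste(rownames(v)[bad], collapse = ", ")),
          "zero_variance")
  z <- (v - rowMeans(v)) / s
  expression_matrix(z, "standardized")
}
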