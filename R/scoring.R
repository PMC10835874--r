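#' Transcriptomic risk score (TRS)
#'
#' The TRS of a sample is the median over the weighted standardized
#' expression values of the signature genes present in the matrix:
#' \deqn{TRS_k = median_g ( w_g z_{gk} )}
#' where \eqn{w_g} is the gene's log hazard ratio weight and \eqn{z_{gk}}
#' its z-scored expression. Genes of the signature absent from the matrix
#' are silently dropped; a warning is raised when fewer than half of the
#' signature genes are available, and an error when none are. The median of
#' an even number of values is the mean of the two central values.
#'
#' @param z an \code{expression_matrix} at stage \code{"standardized"}.
#' @param sig a \code{signature}.
#' @return A \code{score_vector}: data.frame with columns \code{sample_id}
#'   and \code{score}, plus attributes \code{n_genes_used} and
#'   \code{signature_name}.
#' @export
compute_trs <- function(z, sig) {
  assert_stage(z, "standardized")
  used <- intersect(sig$gene_id, gene_ids(z))
  check_overlap(used, sig)
  w <- sig$weight[match(used, sig$gene_id)]
  scores <- apply(w * z$values[used, , drop = FALSE], 2, stats::median)
  score_vector(sample_ids(z), scores, length(used), signature_name(sig))
}

#' Simplified (direction-only) risk score
#'
#' Cross-signature benchmarking cannot rely on published weights, which are
#' unknown or platform-specific for most panels. The simplified score keeps
#' only the direction of each gene's effect:
#' \deqn{S_k = median(z_{gk}: w_g > 0) - median(z_{gk}: w_g < 0)}
#' A side with no genes available contributes 0 (with a warning); when both
#' sides are empty the score is undefined and an error is raised. For a
#' signature whose weights are all +1/-1 this equals the full TRS.
#'
#' @inheritParams compute_trs
#' @export
compute_simplified_score <- function(z, sig) {
  assert_stage(z, "standardized")
  used <- intersect(sig$gene_id, gene_ids(z))
  check_overlap(used, sig)
  dir <- sig$direction[match(used, sig$gene_id)]
  hi <- used[dir > 0]
  lo <- used[dir < 0]
  if (length(hi) == 0L || length(lo) == 0L)
    warn(sprintf("signature '%s': one risk direction absent from matrix, side scored 0",
                 signature_name(sig)), "one_sided_signature")
  side <- function(g) {
    if (length(g) == 0L) return(rep(0, ncol(z$values)))
    apply(z$values[g, , drop = FALSE], 2, stats::median)
  }
  score_vector(sample_ids(z), side(hi) - side(lo), length(used),
               signature_name(sig))
}

#' Per-cell risk score
#'
#' Single-cell data have high dropout and low per-gene depth, which makes
#' logHR weights inapplicable; the per-cell score therefore uses unweighted
#' means: mean expression over risk genes (weight > 0) minus mean over
#' protective genes (weight < 0), computed on the genes available in the
#' cell table. Expression should be normalized and study-wise standardized
#' upstream.
#'
#' @param cells a \code{cell_table} (see \code{\link{simulate_cell_table}}).
#' @param sig a \code{signature}.
#' @return A \code{score_vector} with one score per cell.
#' @export
compute_cell_trs <- function(cells, sig) {
  stopifnot(inherits(cells, "cell_table"))
  used <- intersect(sig$gene_id, cells$gene_ids)
  check_overlap(used, sig)
  dir <- sig$direction[match(used, sig$gene_id)]
  hi <- used[dir > 0]
  lo <- used[dir < 0]
  side <- function(g) {
    if (length(g) == 0L) return(rep(0, nrow(cells$values)))
    Matrix::rowMeans(cells$values[, g, drop = FALSE])
  }
  score_vector(cells$cells$cell_id, as.numeric(side(hi)) - as.numeric(side(lo)),
               length(used), signature_name(sig))
}

check_overlap <- function(used, sig) {
  if (length(used) == 0L)
    abort(sprintf("no overlap between signature '%s' and expression genes",
                  signature_name(sig)), "no_overlap")
  if (length(used) < 0.5 * nrow(sig))
    warn(sprintf("signature '%s': only %d of %d genes available",
                 signature_name(sig), length(used), nrow(sig)),
         "low_overlap")
  invisible(used)
}

score_vector <- function(sample_id, score, n_genes_used, signature_name) {
  if (any(!is.finite(score))) abort("non-finite score", "invalid_input")
  out <- data.frame(sample_id = as.character(sample_id), score = score,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_genes_used") <- n_genes_used
  attr(out, "signature_name") <- signature_name
  class(out) <- c("score_vector", "data.frame")
  out
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> '%s': %d samples, %d genes used\n",
              attr(x, "signature_name"), nrow(x), attr(x, "n_genes_used")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# accept a score_vector or a plain numeric vector
score_values <- function(scores) {
  if (inherits(scores, "score_vector")) {
    stats::setNames(scores$score, scores$sample_id)
  } else if (is.numeric(scores)) {
    scores
  } else abort("scores must be a score_vector or numeric", "invalid_input")
}

#' Dichotomize risk scores at zero
#'
#' Samples with score strictly greater than 0 are labeled
#' \code{"increased"} risk, all others (including exactly 0)
#' \code{"reduced"} - the boundary belongs to the reduced-risk group.
#'
#' @param scores a \code{score_vector} or numeric vector.
#' @return factor with levels \code{"reduced"}, \code{"increased"}.
#' @export
dichotomize <- function(scores) {
  s <- score_values(scores)
  if (any(!is.finite(s))) abort("scores must be finite", "invalid_input")
  factor(ifelse(s > 0, "increased", "reduced"),
         levels = c("reduced", "increased"))
}

#' Write scores (and optional risk groups) as CSV
#' @param scores a \code{score_vector}.
#' @param path file path.
#' @export
write_scores_csv <- function(scores, path) {
  df <- data.frame(sample_id = scores$sample_id, score = scores$score,
                   group = dichotomize(scores))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
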