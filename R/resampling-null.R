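#' Build the matched gene pool for random-set nulls
#'
#' Random competitor gene sets must be drawn from genes that were
#' themselves candidates: genes analyzed in the training meta-analysis but
#' not part of the final signature, restricted to genes that passed the
#' cohort's expression filter. Pool genes without a training logHR cannot
#' be weighted as the null requires and are excluded at build time.
#'
#' @param all_meta_genes gene ids that entered the training meta-analysis.
#' @param sig the \code{signature} being tested.
#' @param expression_filter_pass gene ids that passed the expression
#'   filter in the cohort at hand.
#' @param weights_lookup named numeric vector gene -> training logHR; pool
#'   genes absent from it are dropped.
#' @return Character vector of pool gene ids (deterministic order).
#' @export
build_gene_pool <- function(all_meta_genes, sig, expression_filter_pass,
                            weights_lookup = NULL) {
  if (length(all_meta_genes) == 0 || length(expression_filter_pass) == 0)
    abort("empty inputs to build_gene_pool", "invalid_input")
  pool <- intersect(setdiff(all_meta_genes, sig$gene_id),
                    expression_filter_pass)
  if (!is.null(weights_lookup))
    pool <- pool[pool %in% names(weights_lookup)]
  if (length(pool) == 0)
    abort("gene pool is empty after exclusions", "empty_pool")
  pool
}

#' Random-gene-set null distribution of a signature's prognostic p-value
#'
#' Draws \code{B} random gene sets of the same size as the signature's
#' overlap with the cohort, assigns each pool gene its training logHR as
#' weight, scores every random set with the weighted-median TRS, and
#' records the univariate Cox Wald p-value of the continuous score. The
#' observed signature is processed identically, and its empirical p-value
#' uses the add-one correction
#' \code{(1 + #\{null p <= observed p\}) / (B + 1)}, which is never zero.
#' Sets are sampled without replacement within a set and independently
#' across sets.
#'
#' @param z standardized \code{expression_matrix} of the cohort.
#' @param clinical the cohort's clinical table.
#' @param sig the \code{signature} under test.
#' @param pool pool gene ids from \code{\link{build_gene_pool}}.
#' @param weights_lookup named numeric vector gene -> training logHR;
#'   must cover the pool.
#' @param B number of random sets (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @return A \code{null_distribution}: list with \code{B},
#'   \code{null_pvalues}, \code{observed_p}, \code{empirical_p},
#'   \code{pool_size}, \code{set_size}, \code{seed}.
#' @export
null_distribution <- function(z, clinical, sig, pool, weights_lookup,
                              B = 1000, seed) {
  assert_stage(z, "standardized")
  check_clinical(clinical)
  if (!is_count(B) || B < 1)
    abort("B must be a positive integer", "invalid_parameter")
  if (missing(seed) || !is_count(seed))
    abort("an integer seed is required", "invalid_parameter")
  if (anyNA(match(pool, names(weights_lookup))))
    abort("weights_lookup must cover every pool gene", "invalid_input")
  set_size <- length(intersect(sig$gene_id, gene_ids(z)))
  if (set_size == 0)
    abort("signature has no overlap with the cohort", "no_overlap")
  pool <- intersect(pool, gene_ids(z))
  if (length(pool) < set_size)
    abort(sprintf("pool (%d) smaller than set size (%d)",
                  length(pool), set_size),
          "insufficient_pool")

  cox_p <- function(s) {
    fit <- suppressWarnings(fit_cox(s, clinical))
    fit$p[1]
  }
  observed_p <- cox_p(suppressWarnings(compute_trs(z, sig)))

  set.seed(derive_seed(seed, 0L))
  null_pvalues <- vapply(seq_len(B), function(b) {
    g <- sample(pool, set_size, replace = FALSE)
    rs <- signature_def(g, weights_lookup[g], name = sprintf("null_%d", b))
    cox_p(suppressWarnings(compute_trs(z, rs)))
  }, numeric(1))

  structure(list(
    B = as.integer(B), null_pvalues = null_pvalues,
    observed_p = observed_p,
    empirical_p = (1 + sum(null_pvalues <= observed_p)) / (B + 1),
    pool_size = length(pool), set_size = set_size, seed = as.integer(seed)
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> B = %d, set size %d from pool %d\n  observed p = %.3g, empirical p = %.3g\n",
    x$B, x$set_size, x$pool_size, x$observed_p, x$empirical_p))
  invisible(x)
}
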