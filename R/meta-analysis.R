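#' Random-effects combination of per-cohort effect estimates
#'
#' Inverse-variance pooling with between-cohort heterogeneity:
#' weights \eqn{1/(SE_i^2 + \tau^2)}. \eqn{\tau^2} is estimated by
#' restricted maximum likelihood (the default, via
#' \code{\link[metafor]{rma}}) or by the DerSimonian-Laird closed form
#' \eqn{\tau^2 = max(0, (Q - (k-1)) / C)} with
#' \eqn{Q = \sum w_i (y_i - \bar y_w)^2}, \eqn{C = \sum w_i - \sum w_i^2 /
#' \sum w_i}, \eqn{w_i = 1/SE_i^2}. DL doubles as the closed-form fallback
#' when REML does not converge. With a single estimate the input is
#' returned unchanged with \eqn{\tau^2 = 0}. The p-value is the Wald test
#' of the combined effect.
#'
#' @param effects numeric vector of per-cohort effects (logHR or logOR).
#' @param ses matching positive standard errors.
#' @param method \code{"REML"} (default) or \code{"DL"}.
#' @return List with \code{combined}, \code{se}, \code{tau2}, \code{p},
#'   \code{ci_lo}, \code{ci_hi}, \code{k}.
#' @export
random_effects_combine <- function(effects, ses, method = c("REML", "DL")) {
  method <- match.arg(method)
  if (length(effects) != length(ses) || length(effects) == 0)
    abort("effects and ses must be non-empty and matched", "invalid_input")
  if (any(!is.finite(effects)) || any(!is.finite(ses)) || any(ses <= 0))
    abort("ses must be finite and > 0", "invalid_input")
  k <- length(effects)
  if (k == 1) {
    return(list(combined = effects, se = ses, tau2 = 0,
                p = 2 * stats::pnorm(-abs(effects / ses)),
                ci_lo = effects - 1.96 * ses, ci_hi = effects + 1.96 * ses,
                k = 1L))
  }
  if (method == "DL") {
    res <- dl_combine(effects, ses)
  } else {
    res <- tryCatch({
      fit <- metafor::rma(yi = effects, sei = ses, method = "REML",
                          control = list(maxiter = 100, threshold = 1e-8))
      list(combined = as.numeric(fit$beta), se = fit$se,
           tau2 = fit$tau2, p = fit$pval)
    }, error = function(e) dl_combine(effects, ses))
  }
  res$ci_lo <- res$combined - 1.96 * res$se
  res$ci_hi <- res$combined + 1.96 * res$se
  res$k <- as.integer(k)
  res
}

# DerSimonian-Laird closed form
dl_combine <- function(effects, ses) {
  w <- 1 / ses^2
  ybar <- sum(w * effects) / sum(w)
  q <- sum(w * (effects - ybar)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (length(effects) - 1)) / cc)
  wstar <- 1 / (ses^2 + tau2)
  combined <- sum(wstar * effects) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  list(combined = combined, se = se, tau2 = tau2,
       p = 2 * stats::pnorm(-abs(combined / se)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at 1
#' (delegates to \code{\link[stats]{p.adjust}} after validating the
#' inputs).
#'
#' @param pvals numeric p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    abort("p-values must lie in [0, 1]", "invalid_input")
  stats::p.adjust(pvals, method = "BH")
}

# per-gene univariate effect + SE in one cohort for a given endpoint
cohort_gene_effects <- function(study, endpoint, weights = NULL) {
  z <- if (study$expression$stage == "standardized") study$expression
       else standardize_genes(study$expression)
  cl <- study$clinical
  genes <- gene_ids(z)
  eff <- se <- rep(NA_real_, length(genes))
  if (endpoint == "survival") {
    if (sum(cl$event) == 0) return(NULL)
    for (i in seq_along(genes)) {
      fit <- tryCatch(
        suppressWarnings(fit_cox(z$values[genes[i], ], cl, weights = weights)),
        trscore_error = function(e) NULL)
      if (!is.null(fit) && attr(fit, "converged")) {
        eff[i] <- fit$logHR[1]; se[i] <- fit$se[1]
      }
    }
  } else {  # gs_gt7: logistic log odds ratio for Gleason score > 7
    if (!"gs" %in% names(cl) || anyNA(cl$gs)) return(NULL)
    y <- as.integer(cl$gs > 7)
    if (length(unique(y)) < 2) return(NULL)
    for (i in seq_along(genes)) {
      fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ x,
                                    data = data.frame(y = y, x = z$values[genes[i], ]),
                                    family = stats::binomial(),
                                    weights = weights)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      sm <- summary(fit)$coefficients
      if (!"x" %in% rownames(sm)) next
      if (abs(sm["x", 1]) > 10) next   # separation: omit this cohort/gene
      eff[i] <- sm["x", 1]; se[i] <- sm["x", 2]
    }
  }
  ok <- is.finite(eff) & is.finite(se) & se > 0
  data.frame(gene_id = genes[ok], effect = eff[ok], se = se[ok],
             stringsAsFactors = FALSE)
}

#' Gene-wise random-effects meta-analysis across cohorts
#'
#' For every gene and cohort, a univariate (optionally weighted) Cox
#' regression of the outcome on the gene's standardized expression
#' (endpoint \code{"survival"}), or a logistic regression predicting
#' Gleason score > 7 (endpoint \code{"gs_gt7"}). Per-gene effects from
#' cohorts in which the gene is present are combined with
#' \code{\link{random_effects_combine}}; genes present in fewer than 2
#' cohorts are excluded. P-values are BH-FDR adjusted across genes.
#' Cohorts with zero events (survival) or a single Gleason class are
#' skipped with a warning; non-convergent per-gene fits omit that cohort
#' for that gene.
#'
#' @param cohorts list of \code{cohort_study} objects.
#' @param endpoint \code{"survival"} or \code{"gs_gt7"}.
#' @param duplicate_weights optional list (one element per cohort, or
#'   \code{NULL}s) of per-sample case weights, e.g. 1/N for patients
#'   represented N times across cohorts.
#' @param method tau^2 estimator passed on to
#'   \code{\link{random_effects_combine}}.
#' @return A \code{meta_gene_result} data.frame: \code{gene_id}, \code{k},
#'   \code{effect}, \code{se}, \code{ci_lo}, \code{ci_hi}, \code{tau2},
#'   \code{p}, \code{fdr}, \code{n_consistent}, plus the per-cohort
#'   effects in \code{attr(, "per_cohort")}.
#' @export
genewise_meta <- function(cohorts, endpoint = c("survival", "gs_gt7"),
                          duplicate_weights = NULL,
                          method = c("REML", "DL")) {
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  if (length(cohorts) < 2)
    abort("meta-analysis needs at least 2 cohorts", "invalid_input")

  per <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    w <- if (!is.null(duplicate_weights)) duplicate_weights[[i]] else NULL
    tab <- cohort_gene_effects(cohorts[[i]], endpoint, weights = w)
    if (is.null(tab)) {
      warn(sprintf("cohort %d unusable for endpoint '%s'; skipped",
                   i, endpoint), "cohort_skipped")
      next
    }
    tab$cohort <- cohorts[[i]]$cohort_id %||% sprintf("c%d", i)
    per[[i]] <- tab
  }
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0)
    abort("no usable cohorts", "invalid_input")

  counts <- table(per$gene_id)
  keep <- names(counts)[counts >= 2]   # inclusion rule: >= 2 cohorts
  keep <- keep[order(match(keep, per$gene_id))]
  rows <- lapply(keep, function(g) {
    sub <- per[per$gene_id == g, ]
    cmb <- random_effects_combine(sub$effect, sub$se, method = method)
    data.frame(gene_id = g, k = cmb$k, effect = cmb$combined, se = cmb$se,
               ci_lo = cmb$ci_lo, ci_hi = cmb$ci_hi, tau2 = cmb$tau2,
               p = cmb$p,
               n_consistent = sum(sign(sub$effect) == sign(cmb$combined)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[, c("gene_id", "k", "effect", "se", "ci_lo", "ci_hi",
                 "tau2", "p", "fdr", "n_consistent")]
  attr(out, "per_cohort") <- per
  attr(out, "endpoint") <- endpoint
  class(out) <- c("meta_gene_result", "data.frame")
  out
}

#' Spearman correlation of combined effects between two meta-analyses
#'
#' @param meta_a,meta_b \code{meta_gene_result} tables (e.g. survival vs
#'   Gleason endpoints).
#' @return Spearman rho on the gene intersection.
#' @export
effect_size_correlation <- function(meta_a, meta_b) {
  shared <- intersect(meta_a$gene_id, meta_b$gene_id)
  if (length(shared) < 3)
    abort("need at least 3 shared genes", "insufficient_overlap")
  stats::cor(meta_a$effect[match(shared, meta_a$gene_id)],
             meta_b$effect[match(shared, meta_b$gene_id)],
             method = "spearman")
}

#' Direction concordance between two meta-analyses
#'
#' Fraction of overlapping genes (optionally restricted to a signature)
#' whose combined effects agree in sign.
#'
#' @param train_meta,valid_meta \code{meta_gene_result} tables.
#' @param sig optional \code{signature} restricting the gene set.
#' @return Fraction in [0, 1].
#' @export
direction_concordance <- function(train_meta, valid_meta, sig = NULL) {
  shared <- intersect(train_meta$gene_id, valid_meta$gene_id)
  if (!is.null(sig)) shared <- intersect(shared, sig$gene_id)
  if (length(shared) == 0)
    abort("no overlapping genes", "insufficient_overlap")
  a <- sign(train_meta$effect[match(shared, train_meta$gene_id)])
  b <- sign(valid_meta$effect[match(shared, valid_meta$gene_id)])
  mean(a == b)
}

#' Write a meta-analysis table as TSV
#' @param meta a \code{meta_gene_result}.
#' @param path file path.
#' @export
write_meta_tsv <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
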