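#' Specimen-age association filter
#'
#' FFPE conservation degrades RNA over time, so genes whose measured
#' expression drifts with specimen age carry storage-time information that
#' can distort their prognostic contribution. For every gene a simple
#' linear regression of expression on specimen age is fit; the gene is
#' flagged when the two-sided slope t-test has p < \code{alpha}. The
#' regression is fit on normalized (pre-z-scoring) expression for
#' interpretable slopes; z-scoring rescales slope and SE equally and leaves
#' the p-value unchanged.
#'
#' @param x an \code{expression_matrix} (normalized or standardized).
#' @param specimen_age numeric vector of per-sample specimen ages (years),
#'   same order as the matrix samples.
#' @param alpha flagging threshold for the slope p-value (default 0.1,
#'   deliberately liberal: false removals cost little, retained degraded
#'   genes cost a lot).
#' @return data.frame with one row per gene: \code{gene_id}, \code{slope},
#'   \code{p}, \code{flagged}.
#' @export
age_association_filter <- function(x, specimen_age, alpha = 0.1) {
  assert_stage(x, c("normalized", "standardized"))
  v <- x$values
  n <- ncol(v)
  if (length(specimen_age) != n || anyNA(specimen_age))
    abort("specimen_age must be known for every sample", "invalid_input")
  if (n < 3)
    abort("age regression needs at least 3 samples", "invalid_input")
  if (stats::var(specimen_age) == 0)
    abort("specimen_age is constant; slope not identifiable",
          "degenerate_regressor")
  if (!is_prob(alpha) || alpha <= 0)
    abort("alpha must be in (0, 1]", "invalid_parameter")

  # vectorized per-gene simple regression: slope = Sxy/Sxx, t on n-2 df
  a <- specimen_age - mean(specimen_age)
  sxx <- sum(a^2)
  yc <- v - rowMeans(v)
  slope <- as.numeric(yc %*% a) / sxx
  rss <- rowSums(yc^2) - slope^2 * sxx
  rss <- pmax(rss, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(gene_id = rownames(v), slope = slope, p = p,
             flagged = p < alpha, stringsAsFactors = FALSE)
}

#' External-cohort consistency filter
#'
#' For each signature gene, a univariate Cox regression of the external
#' cohort's outcome on the gene's standardized expression. The gene is kept
#' only when the external effect is nominally significant
#' (p < \code{alpha}) \emph{and} its sign agrees with the signature weight.
#' Genes absent from the external cohort, or whose external fit does not
#' converge, cannot be validated and are not kept (a policy, not an error).
#'
#' @param sig a \code{signature}.
#' @param external a \code{cohort_study} whose expression will be
#'   standardized if it is not already.
#' @param alpha significance threshold (default 0.1).
#' @return data.frame per signature gene: \code{gene_id}, \code{weight},
#'   \code{ext_logHR}, \code{ext_p}, \code{present}, \code{kept}.
#' @export
external_consistency_filter <- function(sig, external, alpha = 0.1) {
  stopifnot(inherits(external, "cohort_study"))
  if (!is_prob(alpha) || alpha <= 0)
    abort("alpha must be in (0, 1]", "invalid_parameter")
  z <- if (external$expression$stage == "standardized") external$expression
       else standardize_genes(external$expression)
  check_clinical(external$clinical)
  if (sum(external$clinical$event) == 0)
    abort("external cohort has no events", "no_events")

  out <- data.frame(gene_id = sig$gene_id, weight = sig$weight,
                    ext_logHR = NA_real_, ext_p = NA_real_,
                    present = sig$gene_id %in% gene_ids(z),
                    kept = FALSE, stringsAsFactors = FALSE)
  for (i in which(out$present)) {
    fit <- tryCatch(
      suppressWarnings(fit_cox(z$values[out$gene_id[i], ],
                               external$clinical)),
      trscore_error = function(e) NULL)
    if (is.null(fit) || !attr(fit, "converged")) next
    out$ext_logHR[i] <- fit$logHR[1]
    out$ext_p[i] <- fit$p[1]
    out$kept[i] <- fit$p[1] < alpha &&
      sign(fit$logHR[1]) == sign(out$weight[i])
  }
  out
}

#' Two-stage FFPE signature refinement
#'
#' Restricts a signature to genes that (1) show no association between
#' expression and FFPE specimen age in the FFPE cohort and (2) have a
#' nominally significant, direction-consistent prognostic effect in an
#' independent external cohort. Weights of surviving genes are preserved
#' unchanged. Crucially, neither filter looks at the FFPE cohort's own
#' survival endpoint, so refinement cannot overfit the cohort it is meant
#' to rescue.
#'
#' @param sig a \code{signature}.
#' @param ffpe a \code{cohort_study} with \code{specimen_age} in its
#'   clinical table (normalized expression).
#' @param external a \code{cohort_study} with survival outcomes.
#' @param alpha_age,alpha_ext filter thresholds (defaults 0.1).
#' @return List with \code{signature} (the refined \code{signature}) and
#'   \code{report}: per input gene \code{age_slope}, \code{age_p},
#'   \code{ext_logHR}, \code{ext_p}, \code{retained},
#'   \code{removal_reason} in \{none, age_associated, missing_in_external,
#'   ext_inconsistent, ext_nonsignificant\}.
#' @export
refine_signature <- function(sig, ffpe, external,
                             alpha_age = 0.1, alpha_ext = 0.1) {
  stopifnot(inherits(sig, "signature"), inherits(ffpe, "cohort_study"))
  if (!"specimen_age" %in% names(ffpe$clinical) ||
      anyNA(ffpe$clinical$specimen_age))
    abort("FFPE cohort needs complete specimen_age", "invalid_input")

  in_ffpe <- intersect(sig$gene_id, gene_ids(ffpe$expression))
  age <- age_association_filter(
    expression_matrix(ffpe$expression$values[in_ffpe, , drop = FALSE],
                      ffpe$expression$stage),
    ffpe$clinical$specimen_age, alpha = alpha_age)
  ext <- external_consistency_filter(sig, external, alpha = alpha_ext)

  rep <- data.frame(gene_id = sig$gene_id, weight = sig$weight,
                    stringsAsFactors = FALSE)
  ai <- match(rep$gene_id, age$gene_id)
  rep$age_slope <- age$slope[ai]
  rep$age_p <- age$p[ai]
  age_flag <- !is.na(ai) & age$flagged[ai]
  ei <- match(rep$gene_id, ext$gene_id)
  rep$ext_logHR <- ext$ext_logHR[ei]
  rep$ext_p <- ext$ext_p[ei]

  reason <- rep("none", nrow(rep))
  reason[!ext$kept[ei] & ext$present[ei] & !is.na(rep$ext_p) &
           rep$ext_p < alpha_ext] <- "ext_inconsistent"
  reason[!ext$kept[ei] & ext$present[ei] &
           (is.na(rep$ext_p) | rep$ext_p >= alpha_ext)] <- "ext_nonsignificant"
  reason[!ext$present[ei]] <- "missing_in_external"
  reason[age_flag] <- "age_associated"   # age filter takes precedence
  rep$retained <- reason == "none"
  rep$removal_reason <- reason

  if (!any(rep$retained))
    abort("refinement removed every gene", "empty_signature")
  refined <- signature_def(rep$gene_id[rep$retained],
                           rep$weight[rep$retained],
                           name = paste0(signature_name(sig), "_refined"))
  list(signature = refined, report = rep)
}
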