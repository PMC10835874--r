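#' Benchmark direction-annotated signatures across cohorts
#'
#' Every signature is applied to every cohort with the simplified
#' (direction-only) score - weights beyond their sign are ignored for all
#' signatures alike, since published panels rarely report comparable
#' weights. Per (signature, cohort) cell: univariate Cox p-value and logHR
#' of the continuous score, and the log-rank p-value of the score
#' dichotomized at 0. Within each cohort, signatures are ranked by
#' ascending p-value per test (ties broken by signature name, so ranks are
#' deterministic); a signature's overall standing is its average rank
#' across the cohorts where it was evaluable. Signatures without gene
#' overlap in a cohort get NA cells and are excluded from that cohort's
#' ranking.
#'
#' @param cohorts list of \code{cohort_study} objects (expression is
#'   standardized on the fly if needed).
#' @param signatures list of \code{signature} objects with unique names.
#' @return A \code{benchmark_table}: list with \code{detail} (per
#'   signature x cohort: cox_p, cox_logHR, logrank_p, rank_cox,
#'   rank_logrank) and \code{summary} (per signature: avg_rank_cox,
#'   avg_rank_logrank, n_cohorts).
#' @export
benchmark_signatures <- function(cohorts, signatures) {
  if (length(signatures) < 2)
    abort("benchmark needs at least 2 signatures", "invalid_input")
  if (length(cohorts) < 1)
    abort("benchmark needs at least 1 cohort", "invalid_input")
  sig_names <- vapply(signatures, signature_name, character(1))
  if (anyDuplicated(sig_names))
    abort("signature names must be unique", "invalid_input")

  rows <- list()
  for (ci in seq_along(cohorts)) {
    study <- cohorts[[ci]]
    cid <- study$cohort_id %||% sprintf("c%d", ci)
    z <- if (study$expression$stage == "standardized") study$expression
         else standardize_genes(study$expression)
    for (si in seq_along(signatures)) {
      sig <- signatures[[si]]
      cell <- data.frame(signature = sig_names[si], cohort = cid,
                         cox_p = NA_real_, cox_logHR = NA_real_,
                         logrank_p = NA_real_, stringsAsFactors = FALSE)
      sc <- tryCatch(suppressWarnings(compute_simplified_score(z, sig)),
                     trscore_error = function(e) NULL)
      if (is.null(sc)) {
        warn(sprintf("signature '%s' has no overlap in cohort '%s'",
                     sig_names[si], cid), "benchmark_no_overlap")
      } else {
        fit <- tryCatch(suppressWarnings(fit_cox(sc, study$clinical)),
                        trscore_error = function(e) NULL)
        if (!is.null(fit)) {
          cell$cox_p <- fit$p[1]
          cell$cox_logHR <- fit$logHR[1]
        }
        lr <- tryCatch(
          logrank_test(study$clinical, dichotomize(sc)),
          trscore_error = function(e) NULL)
        if (!is.null(lr)) cell$logrank_p <- lr$p
      }
      rows[[length(rows) + 1L]] <- cell
    }
  }
  detail <- do.call(rbind, rows)

  # deterministic within-cohort ranks: ascending p, ties by signature name
  rank_col <- function(p, sig) {
    r <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    r[ok] <- order(order(p[ok], sig[ok]))
    r
  }
  detail$rank_cox <- stats::ave(seq_len(nrow(detail)), detail$cohort,
    FUN = function(i) rank_col(detail$cox_p[i], detail$signature[i]))
  detail$rank_logrank <- stats::ave(seq_len(nrow(detail)), detail$cohort,
    FUN = function(i) rank_col(detail$logrank_p[i], detail$signature[i]))

  summary <- do.call(rbind, lapply(sort(sig_names), function(s) {
    d <- detail[detail$signature == s, ]
    data.frame(signature = s,
               avg_rank_cox = mean(d$rank_cox, na.rm = TRUE),
               avg_rank_logrank = mean(d$rank_logrank, na.rm = TRUE),
               n_cohorts = sum(!is.na(d$cox_p)),
               stringsAsFactors = FALSE)
  }))
  structure(list(detail = detail, summary = summary),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("<benchmark_table> %d signatures x %d cohorts\n",
              nrow(x$summary), length(unique(x$detail$cohort))))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
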