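check_clinical <- function(clinical) {
  need <- c("sample_id", "time", "event")
  if (!is.data.frame(clinical) || !all(need %in% names(clinical)))
    abort("clinical table needs columns sample_id, time, event",
          "invalid_input")
  if (anyDuplicated(clinical$sample_id))
    abort("duplicate sample ids in clinical table", "invalid_input")
  if (any(!is.finite(clinical$time)) || any(clinical$time < 0))
    abort("times must be finite and >= 0", "invalid_input")
  if (!all(clinical$event %in% c(0, 1)))
    abort("event must be 0/1", "invalid_input")
  invisible(clinical)
}

# align a score_vector (or named/plain numeric) to the clinical sample order
align_scores <- function(scores, clinical) {
  s <- score_values(scores)
  if (!is.null(names(s))) {
    miss <- setdiff(clinical$sample_id, names(s))
    if (length(miss))
      abort(sprintf("scores missing for samples: %s",
                    paste(utils::head(miss, 5), collapse = ", ")),
            "invalid_input")
    s <- s[clinical$sample_id]
  } else if (length(s) != nrow(clinical)) {
    abort("unnamed scores must match clinical length", "invalid_input")
  }
  unname(s)
}

#' Cox proportional-hazards regression
#'
#' Fits a (optionally weighted, multivariable) Cox model by maximizing the
#' partial likelihood with Efron tie handling, via
#' \code{\link[survival]{coxph}}. Degenerate inputs are rejected up front:
#' zero events, missing covariate values, constant covariates. Monotone
#' partial likelihoods (perfect separation) are flagged - the result
#' carries an honest \code{converged = FALSE} and a warning rather than a
#' silent huge estimate.
#'
#' @param covariates numeric matrix or data.frame, samples x terms, rows in
#'   clinical order (or a single numeric vector / \code{score_vector}).
#' @param clinical data.frame with \code{sample_id}, \code{time},
#'   \code{event}.
#' @param weights optional positive per-sample case weights (e.g. 1/N for a
#'   patient represented by N samples).
#' @param ties tie-handling method: \code{"efron"} (default, more accurate
#'   with tied event times) or \code{"breslow"} (under which case-weight
#'   identities, such as duplicating samples at half weight, hold exactly).
#' @return A \code{cox_result}: data.frame with one row per term
#'   (\code{term}, \code{logHR}, \code{se}, \code{hr}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}) and attributes \code{n}, \code{n_events},
#'   \code{converged}.
#' @export
fit_cox <- function(covariates, clinical, weights = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_clinical(clinical)
  if (inherits(covariates, "score_vector"))
    covariates <- align_scores(covariates, clinical)
  x <- as.matrix(covariates)
  if (is.null(colnames(x)))
    colnames(x) <- if (ncol(x) == 1) "x" else paste0("x", seq_len(ncol(x)))
  if (nrow(x) != nrow(clinical))
    abort("covariate rows must match clinical samples", "invalid_input")
  if (anyNA(x))
    abort("missing covariate values", "missing_covariate")
  if (sum(clinical$event) == 0)
    abort("no events in clinical table", "no_events")
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    abort(sprintf("constant covariate(s): %s",
                  paste(colnames(x)[const], collapse = ", ")),
          "degenerate_covariate")
  if (!is.null(weights) && any(weights <= 0))
    abort("weights must be > 0", "invalid_input")

  df <- data.frame(.time = clinical$time, .event = clinical$event, x,
                   check.names = FALSE)
  df$.w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  fml <- stats::reformulate(sprintf("`%s`", colnames(x)),
                            response = "survival::Surv(.time, .event)")
  infinite_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, weights = .w, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        infinite_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- fit$coefficients
  se <- sqrt(diag(fit$var))
  converged <- !infinite_warn && all(is.finite(co)) && all(abs(co) <= 10)
  if (!converged)
    warn("monotone likelihood or non-convergence; estimates unreliable",
         "cox_nonconvergence")
  out <- data.frame(term = colnames(x), logHR = unname(co), se = unname(se),
                    hr = exp(unname(co)),
                    ci_lo = exp(unname(co) - 1.96 * unname(se)),
                    ci_hi = exp(unname(co) + 1.96 * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(co) / unname(se))),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(clinical)
  attr(out, "n_events") <- sum(clinical$event)
  attr(out, "converged") <- converged
  class(out) <- c("cox_result", "data.frame")
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, converged = %s\n",
              attr(x, "n"), attr(x, "n_events"), attr(x, "converged")))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Multivariable Cox model: risk score adjusted for Gleason grade
#'
#' Two-term Cox fit of the continuous risk score together with a
#' high-grade indicator. Gleason Grade Group is encoded as the binary
#' indicator GGG > 2, which splits the large Gleason-7 group (GGG 2 = 3+4
#' vs GGG 3 = 4+3); a continuous Gleason-score adjustment is available as
#' an alternative.
#'
#' @param scores a \code{score_vector} (continuous TRS).
#' @param clinical clinical table with \code{ggg} (or \code{gs}).
#' @param adjust \code{"ggg_gt2"} (default) or \code{"gs"}.
#' @return A \code{cox_result} with terms \code{trs} and the adjuster.
#' @export
multivariable_trs_ggg <- function(scores, clinical, adjust = c("ggg_gt2", "gs")) {
  adjust <- match.arg(adjust)
  check_clinical(clinical)
  s <- align_scores(scores, clinical)
  col <- if (adjust == "ggg_gt2") "ggg" else "gs"
  if (!col %in% names(clinical))
    abort(sprintf("clinical table lacks column '%s'", col),
          "missing_covariate")
  miss <- clinical$sample_id[is.na(clinical[[col]])]
  if (length(miss))
    abort(sprintf("missing %s for samples: %s", col,
                  paste(utils::head(miss, 5), collapse = ", ")),
          "missing_covariate")
  adj <- if (adjust == "ggg_gt2") as.numeric(clinical$ggg > 2) else clinical$gs
  x <- cbind(trs = s, adj)
  colnames(x)[2] <- adjust
  fit_cox(x, clinical)
}

#' Kaplan-Meier estimate per risk group
#'
#' Product-limit estimator per group with Greenwood variance and log-log
#' 95\% confidence intervals. Estimation itself is never truncated; the
#' conventional rendering rule (truncate curves once fewer than 10 patients
#' remain at risk in every group) is reported as \code{truncation_time} for
#' plotting layers to apply.
#'
#' @param clinical clinical table.
#' @param groups per-sample group labels (factor or character), e.g. from
#'   \code{\link{dichotomize}}.
#' @return A \code{km_result}: list with \code{curves} (one data.frame per
#'   group: time, surv, lo, hi, at_risk, n_event), \code{survival_at(t,
#'   group)}, and \code{truncation_time}.
#' @export
km_estimate <- function(clinical, groups) {
  check_clinical(clinical)
  groups <- as.factor(groups)   # declared factor levels are kept
  if (length(groups) != nrow(clinical))
    abort("groups must match clinical samples", "invalid_input")
  if (nlevels(groups) == 0 || any(table(groups) == 0))
    abort("every group must be non-empty", "empty_group")
  fit <- survival::survfit(
    survival::Surv(clinical$time, clinical$event) ~ groups,
    conf.type = "log-log", conf.int = 0.95)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time))
            else sub("^groups=", "", as.character(sm$strata))
  curves <- lapply(levels(groups), function(g) {
    i <- strata == g
    data.frame(time = sm$time[i], surv = sm$surv[i],
               lo = ifelse(is.na(sm$lower[i]), 0, sm$lower[i]),
               hi = ifelse(is.na(sm$upper[i]), 1, sm$upper[i]),
               at_risk = sm$n.risk[i], n_event = sm$n.event[i])
  })
  names(curves) <- levels(groups)

  survival_at <- function(t, group = levels(groups)[1]) {
    cv <- curves[[group]]
    if (is.null(cv)) abort(sprintf("unknown group '%s'", group), "empty_group")
    ev <- cv[cv$n_event > 0, ]
    vapply(t, function(tt) {
      if (nrow(ev) == 0 || tt < min(ev$time)) 1
      else ev$surv[max(which(ev$time <= tt))]
    }, numeric(1))
  }

  # time at which < 10 remain at risk in every group
  last_ok <- vapply(curves, function(cv) {
    ok <- cv$time[cv$at_risk >= 10]
    if (length(ok)) max(ok) else 0
  }, numeric(1))
  structure(list(curves = curves, survival_at = survival_at,
                 truncation_time = max(last_ok)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> groups: %s; truncation_time = %.3g\n",
              paste(names(x$curves), collapse = ", "), x$truncation_time))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Mantel-Haenszel observed-minus-expected statistic with a 1-df chi-square
#' p-value, via \code{\link[survival]{survdiff}}.
#'
#' @param clinical clinical table.
#' @param groups per-sample labels; exactly two non-empty groups required.
#' @return List with \code{chi2} and \code{p}.
#' @export
logrank_test <- function(clinical, groups) {
  check_clinical(clinical)
  groups <- droplevels(as.factor(as.character(groups)))
  if (nlevels(groups) != 2)
    abort("log-rank comparison requires exactly 2 non-empty groups",
          "degenerate_grouping")
  sd <- survival::survdiff(
    survival::Surv(clinical$time, clinical$event) ~ groups)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Fraction of comparable sample pairs in which the higher risk score has
#' the shorter time to event; score ties count 1/2. Computed with
#' \code{\link[survival]{concordance}} (\code{reverse = TRUE} so that a
#' higher score means higher risk).
#'
#' @param scores a \code{score_vector} or numeric vector.
#' @param clinical clinical table.
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(scores, clinical) {
  check_clinical(clinical)
  s <- align_scores(scores, clinical)
  cc <- survival::concordance(
    survival::Surv(clinical$time, clinical$event) ~ s, reverse = TRUE)
  npairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (npairs == 0)
    abort("no comparable pairs (all censored?)", "no_pairs")
  unname(cc$concordance)
}
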