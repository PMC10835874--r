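#' Configuration for the synthetic-cohort generator
#'
#' Bundles and validates all simulation parameters. The generator emulates
#' the structure of multi-cohort prostate-cancer expression studies: a
#' minority of truly prognostic genes with known log hazard ratios, survival
#' times from a proportional-hazards model with independent censoring,
#' per-gene expression drift correlated with FFPE specimen age, optional
#' Gleason-grade contribution to the hazard, per-cohort gene-wise offsets
#' and partial gene-panel overlap.
#'
#' @param n_samples,n_genes cohort dimensions (positive integers).
#' @param n_prognostic number of genes with a non-zero true logHR.
#' @param effect_size_range range of |true logHR| per 1 SD of expression;
#'   signs are drawn at random.
#' @param baseline_hazard exponential baseline event rate (events per unit
#'   time), > 0.
#' @param censor_rate target fraction of censored samples, in [0, 1];
#'   achieved within about 0.02 by tuning an independent exponential
#'   censoring rate by bisection.
#' @param n_age_affected number of genes receiving an additive
#'   specimen-age drift.
#' @param age_slope_range range of |drift slope| (expression units per
#'   year); signs drawn at random.
#' @param specimen_age_range range (years) of the uniform specimen-age
#'   distribution.
#' @param cohort_offsets SD of per-gene per-cohort mean shifts (0 = none).
#' @param panel_overlap fraction of genes exposed by each cohort's panel,
#'   in (0, 1].
#' @param ggg_effect additive log-hazard contribution of Gleason Grade
#'   Group > 2 (0 = grade carries no independent signal).
#' @param ggg_link strength of the latent link between the gene-driven
#'   linear predictor and Gleason grade: with \code{ggg_link > 0}, grades
#'   are assigned by quantile-cutting \code{ggg_link * eta + noise}, so
#'   the same genes drive both survival and the Gleason endpoint; 0
#'   (default) draws grades independently.
#' @param allow_overlap if \code{FALSE} (default) the prognostic and
#'   age-affected gene sets are drawn disjoint, so recovery experiments
#'   have unambiguous truth.
#' @param counts_mode if \code{TRUE}, Poisson counts are emitted (stage
#'   \code{"counts"}) instead of continuous log-scale values.
#' @param seed master seed; all sub-streams derive from it by fixed offsets.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples, n_genes, n_prognostic = 0,
                              effect_size_range = c(0.3, 0.6),
                              baseline_hazard = 0.1, censor_rate = 0.3,
                              n_age_affected = 0,
                              age_slope_range = c(0.05, 0.15),
                              specimen_age_range = c(1, 18),
                              cohort_offsets = 0, panel_overlap = 1,
                              ggg_effect = 0, ggg_link = 0,
                              allow_overlap = FALSE,
                              counts_mode = FALSE, seed = 1) {
  if (!is_count(n_samples) || n_samples <= 0 ||
      !is_count(n_genes) || n_genes <= 0)
    abort("n_samples and n_genes must be positive integers", "invalid_config")
  if (!is_count(n_prognostic) || n_prognostic < 0 || n_prognostic > n_genes)
    abort("n_prognostic must be in [0, n_genes]", "invalid_config")
  if (!is_count(n_age_affected) || n_age_affected < 0)
    abort("n_age_affected must be a non-negative integer", "invalid_config")
  if (!allow_overlap && n_prognostic + n_age_affected > n_genes)
    abort("n_prognostic + n_age_affected exceeds n_genes (disjoint sets)",
          "invalid_config")
  if (!is_prob(censor_rate))
    abort("censor_rate must be in [0, 1]", "invalid_config")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    abort("baseline_hazard must be > 0", "invalid_config")
  if (!is.numeric(panel_overlap) || panel_overlap <= 0 || panel_overlap > 1)
    abort("panel_overlap must be in (0, 1]", "invalid_config")
  if (!is.numeric(cohort_offsets) || cohort_offsets < 0)
    abort("cohort_offsets must be >= 0", "invalid_config")
  rng <- function(r, what) {
    if (length(r) != 2 || !is.numeric(r) || r[1] > r[2])
      abort(sprintf("%s must be an ordered numeric pair", what),
            "invalid_config")
    as.numeric(r)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_prognostic = as.integer(n_prognostic),
    effect_size_range = rng(effect_size_range, "effect_size_range"),
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    n_age_affected = as.integer(n_age_affected),
    age_slope_range = rng(age_slope_range, "age_slope_range"),
    specimen_age_range = rng(specimen_age_range, "specimen_age_range"),
    cohort_offsets = cohort_offsets, panel_overlap = panel_overlap,
    ggg_effect = ggg_effect, ggg_link = ggg_link,
    allow_overlap = isTRUE(allow_overlap),
    counts_mode = isTRUE(counts_mode), seed = as.integer(seed)
  ), class = "simulation_config")
}

# gene-level ground truth shared across cohorts of one study; consumes the
# master-seed RNG stream
draw_truth <- function(config) {
  set.seed(derive_seed(config$seed, 0L))
  ng <- config$n_genes
  gene_id <- sprintf("g%04d", seq_len(ng))
  mu <- stats::runif(ng, 2, 10)         # log2-scale baseline means
  sd <- stats::runif(ng, 0.5, 1.5)
  idx_prog <- if (config$n_prognostic > 0) seq_len(config$n_prognostic) else integer(0)
  pool_age <- if (config$allow_overlap) seq_len(ng) else setdiff(seq_len(ng), idx_prog)
  idx_age <- if (config$n_age_affected > 0)
    pool_age[seq_len(config$n_age_affected)] else integer(0)
  beta <- numeric(ng)
  if (length(idx_prog)) {
    mag <- stats::runif(length(idx_prog), config$effect_size_range[1],
                        config$effect_size_range[2])
    beta[idx_prog] <- mag * sample(c(-1, 1), length(idx_prog), replace = TRUE)
  }
  slope <- numeric(ng)
  if (length(idx_age)) {
    mag <- stats::runif(length(idx_age), config$age_slope_range[1],
                        config$age_slope_range[2])
    slope[idx_age] <- mag * sample(c(-1, 1), length(idx_age), replace = TRUE)
  }
  data.frame(gene_id = gene_id, mu = mu, sd = sd, true_logHR = beta,
             age_slope = slope, is_prognostic = beta != 0,
             is_age_affected = slope != 0, stringsAsFactors = FALSE)
}

# solve for the exponential censoring rate rc such that the expected
# censored fraction E[rc / (rc + lambda_k)] matches the target
tune_censor_rate <- function(lambda, target, tol = 1e-6) {
  f <- function(rc) mean(rc / (rc + lambda)) - target
  lo <- 1e-10; hi <- 1e10
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi / lo < 1 + tol) break
  }
  sqrt(lo * hi)
}

# one cohort from shared truth; all randomness under cohort_seed
sim_cohort_core <- function(truth, config, cohort_seed, cohort_id) {
  set.seed(cohort_seed)
  n <- config$n_samples
  ng <- nrow(truth)

  offsets <- numeric(ng)
  if (config$cohort_offsets > 0)
    offsets <- stats::rnorm(ng, 0, config$cohort_offsets)
  panel <- seq_len(ng)
  if (config$panel_overlap < 1)
    panel <- sort(sample.int(ng, max(1L, floor(config$panel_overlap * ng))))

  eps <- matrix(stats::rnorm(ng * n), nrow = ng)   # true standardized signal
  eta <- as.numeric(crossprod(eps, truth$true_logHR))

  ggg_probs <- c(0.25, 0.35, 0.2, 0.12, 0.08)
  if (config$ggg_link > 0) {
    # grade reflects the same latent tumor biology that drives survival
    eta_std <- if (stats::sd(eta) > 0) (eta - mean(eta)) / stats::sd(eta) else 0
    latent <- config$ggg_link * eta_std + stats::rnorm(n)
    ggg <- as.integer(cut(rank(latent, ties.method = "first") / n,
                          breaks = c(0, cumsum(ggg_probs)),
                          include.lowest = TRUE))
  } else {
    ggg <- sample(1:5, n, replace = TRUE, prob = ggg_probs)
  }
  if (config$ggg_effect != 0) eta <- eta + config$ggg_effect * (ggg > 2)

  lambda <- config$baseline_hazard * exp(eta)
  t_event <- stats::rexp(n, lambda)
  if (config$censor_rate > 0) {
    rc <- tune_censor_rate(lambda, config$censor_rate)
    t_cens <- stats::rexp(n, rc)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }

  age <- stats::runif(n, config$specimen_age_range[1],
                      config$specimen_age_range[2])
  tumor_content <- stats::runif(n, 10, 90)

  x <- truth$mu + truth$sd * eps + offsets
  drift <- truth$age_slope != 0
  if (any(drift))
    x[drift, ] <- x[drift, ] + outer(truth$age_slope[drift], age)

  sample_id <- sprintf("%s_s%04d", cohort_id, seq_len(n))
  dimnames(x) <- list(truth$gene_id, sample_id)
  x <- x[panel, , drop = FALSE]

  if (config$counts_mode) {
    counts <- matrix(stats::rpois(length(x), lambda = pmax(2^x - 1, 0)),
                     nrow = nrow(x), dimnames = dimnames(x))
    expr <- expression_matrix(counts, "counts")
  } else {
    expr <- expression_matrix(x, "normalized")
  }

  gs_map <- c(6L, 7L, 7L, 8L, 9L)
  clinical <- data.frame(
    sample_id = sample_id, time = time, event = event,
    patient_id = sample_id, ggg = ggg, gs = gs_map[ggg],
    specimen_age = age, tumor_content = tumor_content,
    stringsAsFactors = FALSE
  )

  structure(list(
    expression = expr, clinical = clinical,
    truth = truth[, c("gene_id", "true_logHR", "age_slope",
                      "is_prognostic", "is_age_affected")],
    cohort_id = cohort_id, config = config
  ), class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("<cohort_study> '%s': %d genes x %d samples, %d events\n",
              x$cohort_id, nrow(x$expression$values),
              ncol(x$expression$values), sum(x$clinical$event)))
  invisible(x)
}

#' Simulate a single bulk expression cohort with survival ground truth
#'
#' Expression is drawn gene-wise from a log-normal-like model (log-scale
#' values mu_g + sd_g * eps). The per-sample linear predictor is
#' \eqn{\eta_k = \sum_g \beta_g \epsilon_{gk}} over the prognostic genes,
#' and event times are exponential with hazard
#' \code{baseline_hazard * exp(eta)}. Censoring times are independent
#' exponentials whose rate is tuned by bisection so the expected censored
#' fraction matches \code{censor_rate}. Age-affected genes then receive an
#' additive \code{slope * specimen_age} drift, which corrupts the observed
#' expression without touching the outcome - emulating FFPE degradation as
#' a pure confounder. The truth table records every per-gene parameter.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param cohort_index integer stream index; cohorts simulated from the
#'   same config but different indices share ground truth while drawing
#'   independent samples (index i matches cohort i of
#'   \code{\link{simulate_multi_cohorts}}).
#' @return A \code{cohort_study}: list with \code{expression}
#'   (\code{expression_matrix}), \code{clinical} (data.frame) and
#'   \code{truth} (per-gene data.frame).
#' @export
simulate_bulk_cohort <- function(config, cohort_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_count(cohort_index) || cohort_index < 1)
    abort("cohort_index must be a positive integer", "invalid_config")
  truth <- draw_truth(config)
  sim_cohort_core(truth, config, derive_seed(config$seed, 1000L * cohort_index),
                  sprintf("c%d", cohort_index))
}

#' Simulate a collection of cohorts sharing the same gene-level truth
#'
#' All cohorts share the per-gene true logHRs and age slopes drawn from the
#' master seed; each cohort adds its own gene-wise mean offsets (SD
#' \code{cohort_offsets}), exposes a random gene-panel subset of fraction
#' \code{panel_overlap}, and draws samples under a seed derived as
#' \code{seed + 1000 * cohort_index}. With \code{n_cohorts = 1} and
#' \code{panel_overlap = 1} the result is identical to
#' \code{\link{simulate_bulk_cohort}}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param n_cohorts number of cohorts (>= 1).
#' @return List of \code{cohort_study} objects.
#' @export
simulate_multi_cohorts <- function(config, n_cohorts) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is_count(n_cohorts) || n_cohorts < 1)
    abort("n_cohorts must be a positive integer", "invalid_config")
  truth <- draw_truth(config)
  lapply(seq_len(n_cohorts), function(i) {
    sim_cohort_core(truth, config, derive_seed(config$seed, 1000L * i),
                    sprintf("c%d", i))
  })
}

#' Simulate a labeled single-cell expression table
#'
#' Cells are assigned a patient, a lineage (uniformly at random) and a
#' tumor/adjacent tissue source. Each lineage owns a block of marker genes
#' (\code{markers_per_lineage}) whose expression is up-shifted by
#' \code{marker_strength} in cells of that lineage. Values are non-negative
#' log-scale expression with Gaussian noise; dropout zeros are injected at
#' the given rate. Marker gene ids are \code{mk_<lineage>_<j>}.
#'
#' @param n_patients,cells_per_patient table dimensions.
#' @param lineages character vector of at least two lineage labels.
#' @param marker_strength additive expression shift of a lineage's markers
#'   in its own cells.
#' @param dropout zero-injection rate in [0, 1).
#' @param n_genes total genes (markers included).
#' @param markers_per_lineage marker genes per lineage.
#' @param tumor_fraction probability a cell is from tumor tissue.
#' @param seed RNG seed.
#' @return A \code{cell_table}: list with sparse \code{values}
#'   (cells x genes, \code{dgCMatrix}), \code{cells} metadata data.frame
#'   (cell_id, patient_id, lineage, cell_type, source) and \code{gene_ids}.
#' @export
simulate_cell_table <- function(n_patients, cells_per_patient, lineages,
                                marker_strength = 2, dropout = 0.3,
                                n_genes = 200, markers_per_lineage = 5,
                                tumor_fraction = 0.5, seed = 1) {
  if (length(lineages) < 2)
    abort("need at least 2 lineages (differential expression undefined)",
          "invalid_config")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    abort("dropout must be in [0, 1)", "invalid_config")
  if (!is_count(n_patients) || n_patients < 1 ||
      !is_count(cells_per_patient) || cells_per_patient < 1)
    abort("n_patients and cells_per_patient must be positive", "invalid_config")
  lineages <- as.character(lineages)
  nl <- length(lineages)
  if (n_genes < nl * markers_per_lineage)
    abort("n_genes too small for the marker blocks", "invalid_config")

  set.seed(derive_seed(seed, 0L))
  n_cells <- n_patients * cells_per_patient
  marker_ids <- unlist(lapply(lineages, function(l)
    sprintf("mk_%s_%d", l, seq_len(markers_per_lineage))))
  gene_ids <- c(marker_ids, sprintf("g%04d", seq_len(n_genes - length(marker_ids))))
  marker_lineage <- c(rep(lineages, each = markers_per_lineage),
                      rep(NA_character_, n_genes - length(marker_ids)))

  patient_id <- rep(sprintf("pat%02d", seq_len(n_patients)),
                    each = cells_per_patient)
  lineage <- sample(lineages, n_cells, replace = TRUE)
  source <- ifelse(stats::runif(n_cells) < tumor_fraction, "tumor", "adjacent")

  mu <- stats::runif(n_genes, 1, 5)
  x <- matrix(stats::rnorm(n_cells * n_genes, sd = 0.5), nrow = n_cells)
  x <- sweep(x, 2, mu, `+`)
  if (marker_strength != 0) {
    for (j in which(!is.na(marker_lineage)))
      x[lineage == marker_lineage[j], j] <-
        x[lineage == marker_lineage[j], j] + marker_strength
  }
  x <- pmax(x, 0)
  if (dropout > 0)
    x[matrix(stats::runif(length(x)) < dropout, nrow = n_cells)] <- 0

  cell_id <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(x) <- list(cell_id, gene_ids)
  cell_table(
    values = methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"),
    cells = data.frame(cell_id = cell_id, patient_id = patient_id,
                       lineage = lineage, cell_type = lineage,
                       source = source, stringsAsFactors = FALSE)
  )
}

#' Construct a cell table from a matrix and cell metadata
#'
#' @param values cells x genes matrix (dense or sparse; stored sparse).
#' @param cells data.frame with at least \code{cell_id}, \code{patient_id},
#'   \code{lineage}; optional \code{cell_type}, \code{source}.
#' @return A \code{cell_table}.
#' @export
cell_table <- function(values, cells) {
  values <- methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  need <- c("cell_id", "patient_id", "lineage")
  if (!all(need %in% names(cells)))
    abort(sprintf("cell metadata needs columns: %s", paste(need, collapse = ", ")),
          "invalid_input")
  if (nrow(cells) != nrow(values))
    abort("metadata rows must match matrix rows (cells)", "invalid_input")
  if (is.null(colnames(values)))
    abort("cell matrix needs gene colnames", "invalid_input")
  if (is.null(rownames(values))) rownames(values) <- cells$cell_id
  structure(list(values = values, cells = cells,
                 gene_ids = colnames(values)),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells x %d genes, %d patients, lineages: %s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$cells$patient_id)),
              paste(unique(x$cells$lineage), collapse = ", ")))
  invisible(x)
}

#' Write a cohort study to plain-text files
#'
#' Writes expression TSV (genes x samples), clinical CSV and truth TSV into
#' a directory.
#'
#' @param study a \code{cohort_study}.
#' @param dir output directory (created if missing).
#' @export
write_cohort_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(study$expression,
                       file.path(dir, paste0(study$cohort_id, "_expression.tsv")))
  utils::write.csv(study$clinical,
                   file.path(dir, paste0(study$cohort_id, "_clinical.csv")),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(study$truth,
                     file.path(dir, paste0(study$cohort_id, "_truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
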