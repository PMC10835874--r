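#' Default pipeline configuration
#'
#' Returns the default configuration list for \code{\link{run_validation}}:
#' a fully synthetic study with shared gene-level truth across training,
#' validation, FFPE-like and external cohorts. All analysis thresholds
#' (age filter 0.1, external filter 0.1, IQR cutoff 0.25, FDR 0.05, number
#' of random gene sets) are surfaced here.
#'
#' @param seed master seed.
#' @return Nested list understood by \code{\link{run_validation}}.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    simulation = list(
      n_genes = 300, n_prognostic = 30,
      effect_size_range = c(0.3, 0.6),
      baseline_hazard = 0.1, censor_rate = 0.3,
      n_training = 2, n_validation = 3,
      n_samples_training = 300, n_samples_validation = 150,
      n_samples_ffpe = 176, n_samples_external = 300,
      n_age_affected = 60, age_slope_range = c(0.15, 0.35),
      specimen_age_range = c(1, 18), ggg_link = 1.5
    ),
    thresholds = list(
      alpha_age = 0.1, alpha_ext = 0.1, iqr_cutoff = 0.25,
      fdr = 0.05, null_B = 200
    )
  )
}

#' Run the end-to-end synthetic validation pipeline
#'
#' Executes the full chain on simulated data with known ground truth:
#' simulate (training, validation, FFPE-like and external cohorts sharing
#' per-gene truth) -> preprocess (IQR filter, z-scores) -> train a
#' signature by gene-wise random-effects meta-analysis of the training
#' cohorts -> refine it with the specimen-age and external-consistency
#' filters -> score and validate (Cox, Kaplan-Meier, log-rank,
#' concordance, GGG-adjusted Cox) the full and refined signatures in every
#' validation cohort and the FFPE cohort -> random-gene-set null for the
#' refined signature -> validation meta-analysis with direction
#' concordance against training -> benchmark full vs refined vs a
#' size-matched noise signature. Reruns with the same config are
#' bit-identical; no stage reads the clock or the environment.
#'
#' @param config a config list (see \code{\link{default_pipeline_config}})
#'   or the path of a YAML file holding one; missing entries fall back to
#'   the defaults.
#' @param out_dir optional directory; when given, all tables and the JSON
#'   run report are written there.
#' @return A \code{run_report} list: config echo, per-stage status,
#'   per-cohort results for full and refined signatures, null-distribution
#'   summary, meta-analysis summaries, benchmark summary, seed and package
#'   version.
#' @export
run_validation <- function(config = default_pipeline_config(),
                           out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort(sprintf("config file not found: %s", config), "file_not_found")
    config <- yaml::read_yaml(config)
  }
  config <- utils::modifyList(default_pipeline_config(), config)
  sim <- config$simulation
  thr <- config$thresholds
  if (is.null(config$seed) || !is_count(config$seed))
    abort("config must carry an integer seed", "config_error")
  seed <- as.integer(config$seed)
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)
  report <- list(config = config, seed = seed,
                 version = as.character(utils::packageVersion("trscore")))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "stage_error")
    })
  }

  ## -- simulate ----------------------------------------------------------
  cohorts <- run_stage("simulate", {
    base <- function(n_samples, n_age)
      simulation_config(
        n_samples = n_samples, n_genes = sim$n_genes,
        n_prognostic = sim$n_prognostic,
        effect_size_range = sim$effect_size_range,
        baseline_hazard = sim$baseline_hazard,
        censor_rate = sim$censor_rate,
        n_age_affected = n_age, age_slope_range = sim$age_slope_range,
        specimen_age_range = sim$specimen_age_range,
        ggg_link = sim$ggg_link, seed = seed)
    # same seed + identical pre-drift draws => shared truth; the FFPE-like
    # cohort alone expresses the specimen-age drift
    idx <- 0L
    nxt <- function() { idx <<- idx + 1L; idx }
    training <- lapply(seq_len(sim$n_training), function(i)
      simulate_bulk_cohort(base(sim$n_samples_training, 0L), nxt()))
    validation <- lapply(seq_len(sim$n_validation), function(i)
      simulate_bulk_cohort(base(sim$n_samples_validation, 0L), nxt()))
    external <- simulate_bulk_cohort(base(sim$n_samples_external, 0L), nxt())
    ffpe <- simulate_bulk_cohort(
      base(sim$n_samples_ffpe, sim$n_age_affected), nxt())
    list(training = training, validation = validation,
         external = external, ffpe = ffpe)
  })
  done("simulate")

  ## -- preprocess --------------------------------------------------------
  prep <- run_stage("preprocess", {
    standardize_study <- function(study) {
      filt <- iqr_filter(study$expression, cutoff = thr$iqr_cutoff)
      study$expression_filtered <- filt
      study$z <- standardize_genes(filt)
      study
    }
    lapply(cohorts, function(x)
      if (inherits(x, "cohort_study")) standardize_study(x)
      else lapply(x, standardize_study))
  })
  done("preprocess")

  ## -- train signature ---------------------------------------------------
  train <- run_stage("train_signature", {
    zs <- lapply(prep$training, function(s) {
      s$expression <- s$z; s
    })
    meta <- genewise_meta(zs, endpoint = "survival")
    hits <- meta[meta$fdr < thr$fdr & meta$effect != 0, ]
    if (nrow(hits) == 0)
      abort("no significant training genes", "empty_signature")
    list(meta = meta,
         signature = signature_def(hits$gene_id, hits$effect,
                                   name = "trained"))
  })
  done("train_signature")

  ## -- refine ------------------------------------------------------------
  refined <- run_stage("refine", {
    ffpe <- prep$ffpe
    ffpe$expression <- ffpe$expression_filtered
    ext <- prep$external
    ext$expression <- ext$z
    refine_signature(train$signature, ffpe, ext,
                     alpha_age = thr$alpha_age, alpha_ext = thr$alpha_ext)
  })
  done("refine")

  ## -- score + validate --------------------------------------------------
  validate_one <- function(study, sig) {
    sc <- tryCatch(suppressWarnings(compute_trs(study$z, sig)),
                   trscore_error = function(e) NULL)
    if (is.null(sc))   # signature entirely outside this cohort's panel
      return(list(signature = signature_name(sig), n_genes_used = 0L,
                  cox_logHR = NA, cox_p = NA, logrank_p = NA,
                  c_index = NA, cox_p_ggg_adjusted = NA))
    fit <- suppressWarnings(fit_cox(sc, study$clinical))
    grp <- dichotomize(sc)
    lr <- tryCatch(logrank_test(study$clinical, grp),
                   trscore_error = function(e) list(chi2 = NA, p = NA))
    mv <- tryCatch(
      suppressWarnings(multivariable_trs_ggg(sc, study$clinical)),
      trscore_error = function(e) NULL)
    list(signature = signature_name(sig),
         n_genes_used = attr(sc, "n_genes_used"),
         cox_logHR = fit$logHR[1], cox_p = fit$p[1],
         logrank_p = lr$p,
         c_index = concordance_index(sc, study$clinical),
         cox_p_ggg_adjusted = if (is.null(mv)) NA else mv$p[mv$term == "trs"])
  }
  validation_results <- run_stage("validate", {
    eval_cohorts <- c(prep$validation, list(ffpe = prep$ffpe))
    lapply(eval_cohorts, function(study) {
      list(cohort = study$cohort_id,
           full = validate_one(study, train$signature),
           refined = validate_one(study, refined$signature))
    })
  })
  done("validate")

  ## -- random-gene-set null ---------------------------------------------
  null_res <- run_stage("null", {
    study <- prep$validation[[1]]
    wl <- stats::setNames(train$meta$effect, train$meta$gene_id)
    pool <- build_gene_pool(train$meta$gene_id, refined$signature,
                            gene_ids(study$z), weights_lookup = wl)
    null_distribution(study$z, study$clinical, refined$signature,
                      pool, wl, B = thr$null_B,
                      seed = derive_seed(seed, 77L))
  })
  done("null")

  ## -- validation meta ---------------------------------------------------
  meta_res <- run_stage("meta", {
    zs <- lapply(prep$validation, function(s) { s$expression <- s$z; s })
    vmeta <- genewise_meta(zs, endpoint = "survival")
    gmeta <- tryCatch(genewise_meta(zs, endpoint = "gs_gt7"),
                      trscore_error = function(e) NULL)
    # concordance and cross-endpoint correlation are reported over the
    # signature genes (the genes whose directions the score relies on)
    sig_meta <- vmeta[vmeta$gene_id %in% train$signature$gene_id, ]
    list(
      validation_meta = vmeta,
      gs_meta = gmeta,
      direction_concordance_signature =
        direction_concordance(train$meta, vmeta, train$signature),
      direction_concordance_refined =
        direction_concordance(train$meta, vmeta, refined$signature),
      effect_size_correlation =
        if (is.null(gmeta) || nrow(sig_meta) < 3) NA else
          effect_size_correlation(sig_meta, gmeta)
    )
  })
  done("meta")

  ## -- benchmark ---------------------------------------------------------
  bench <- run_stage("benchmark", {
    study_list <- lapply(prep$validation, function(s) {
      s$expression <- s$z; s
    })
    wl <- stats::setNames(train$meta$effect, train$meta$gene_id)
    pool <- build_gene_pool(train$meta$gene_id, refined$signature,
                            gene_ids(study_list[[1]]$expression),
                            weights_lookup = wl)
    set.seed(derive_seed(seed, 88L))
    noise_genes <- sample(pool, min(nrow(refined$signature), length(pool)))
    noise <- signature_def(noise_genes,
                           sample(c(-1, 1), length(noise_genes), TRUE),
                           name = "noise")
    benchmark_signatures(study_list,
                         list(train$signature, refined$signature, noise))
  })
  done("benchmark")

  report$stages <- stats::setNames(as.list(rep("ok", length(stages))), stages)
  report$signature <- list(
    n_genes_full = nrow(train$signature),
    n_genes_refined = nrow(refined$signature),
    removal_reasons = as.list(table(refined$report$removal_reason)))
  report$validation <- validation_results
  report$null <- list(B = null_res$B, observed_p = null_res$observed_p,
                      empirical_p = null_res$empirical_p,
                      pool_size = null_res$pool_size,
                      set_size = null_res$set_size)
  report$meta <- list(
    n_genes_meta = nrow(meta_res$validation_meta),
    n_significant = sum(meta_res$validation_meta$fdr < thr$fdr),
    direction_concordance_signature = meta_res$direction_concordance_signature,
    direction_concordance_refined = meta_res$direction_concordance_refined,
    effect_size_correlation = meta_res$effect_size_correlation)
  report$benchmark <- bench$summary
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signature_tsv(train$signature,
                        file.path(out_dir, "signature_full.tsv"))
    write_signature_tsv(refined$signature,
                        file.path(out_dir, "signature_refined.tsv"))
    utils::write.table(refined$report,
                       file.path(out_dir, "refinement_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_meta_tsv(train$meta, file.path(out_dir, "meta_training.tsv"))
    write_meta_tsv(meta_res$validation_meta,
                   file.path(out_dir, "meta_validation.tsv"))
    utils::write.table(bench$detail,
                       file.path(out_dir, "benchmark_detail.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(names(x$stages), collapse = " -> "), "\n")
  cat(sprintf("  signature: %d genes -> %d after refinement\n",
              x$signature$n_genes_full, x$signature$n_genes_refined))
  cat(sprintf("  null: empirical p = %.4g (B = %d)\n",
              x$null$empirical_p, x$null$B))
  cat(sprintf("  meta: %d genes, %d significant; signature direction concordance %.2f (refined %.2f)\n",
              x$meta$n_genes_meta, x$meta$n_significant,
              x$meta$direction_concordance_signature,
              x$meta$direction_concordance_refined))
  invisible(x)
}
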