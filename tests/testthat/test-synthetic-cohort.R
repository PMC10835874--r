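test_that("identical config and seed give bit-identical cohorts", {
  cfg <- simulation_config(n_samples = 50, n_genes = 40, n_prognostic = 5,
                           n_age_affected = 5, seed = 9)
  a <- simulate_bulk_cohort(cfg)
  b <- simulate_bulk_cohort(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # serialization is byte-stable too
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("config validation catches impossible settings", {
  expect_error(simulation_config(0, 10), class = "invalid_config")
  expect_error(simulation_config(10, 10, censor_rate = 1.2),
               class = "invalid_config")
  expect_error(simulation_config(10, 10, n_prognostic = 6, n_age_affected = 6),
               class = "invalid_config")
  expect_error(simulate_multi_cohorts(simulation_config(10, 10), 0),
               class = "invalid_config")
  # overlap flag lifts the disjointness constraint
  expect_s3_class(simulation_config(10, 10, n_prognostic = 6,
                                    n_age_affected = 6, allow_overlap = TRUE),
                  "simulation_config")
})

test_that("censoring control: zero censor rate forces all events, targets hit", {
  cfg0 <- simulation_config(n_samples = 80, n_genes = 20, censor_rate = 0,
                            seed = 2)
  st0 <- simulate_bulk_cohort(cfg0)
  expect_true(all(st0$clinical$event == 1))

  cfg3 <- simulation_config(n_samples = 2000, n_genes = 20, n_prognostic = 3,
                            censor_rate = 0.4, seed = 3)
  st3 <- simulate_bulk_cohort(cfg3)
  expect_lt(abs(mean(st3$clinical$event == 0) - 0.4), 0.05)
})

test_that("truth table covers every gene once and matches the config", {
  cfg <- simulation_config(n_samples = 30, n_genes = 50, n_prognostic = 7,
                           n_age_affected = 4, seed = 5)
  st <- simulate_bulk_cohort(cfg)
  expect_identical(st$truth$gene_id, gene_ids(st$expression))
  expect_identical(anyDuplicated(st$truth$gene_id), 0L)
  expect_equal(sum(st$truth$is_prognostic), 7)
  expect_equal(sum(st$truth$is_age_affected), 4)
  expect_false(any(st$truth$is_prognostic & st$truth$is_age_affected))
  expect_identical(st$clinical$sample_id, sample_ids(st$expression))
  b <- st$truth$true_logHR[st$truth$is_prognostic]
  expect_true(all(abs(b) >= 0.3 & abs(b) <= 0.6))
})

test_that("multi-cohort collections share truth, split panels, and reduce to the bulk case", {
  cfg <- simulation_config(n_samples = 40, n_genes = 200, n_prognostic = 10,
                           panel_overlap = 0.5, cohort_offsets = 0.3, seed = 6)
  cohorts <- simulate_multi_cohorts(cfg, 3)
  expect_length(cohorts, 3)
  for (co in cohorts) {
    expect_equal(nrow(co$expression$values), 100)  # half the panel
    expect_identical(co$truth$true_logHR, cohorts[[1]]$truth$true_logHR)
  }
  # degenerate case: one cohort, full panel == the single-cohort generator
  cfg1 <- simulation_config(n_samples = 40, n_genes = 200, n_prognostic = 10,
                            seed = 6)
  expect_identical(simulate_multi_cohorts(cfg1, 1)[[1]]$expression$values,
                   simulate_bulk_cohort(cfg1)$expression$values)
})

test_that("per-cohort random-effects combination recovers shared truth", {
  # weak effects keep the univariate fits in the collapsible regime
  cfg <- simulation_config(n_samples = 250, n_genes = 60, n_prognostic = 4,
                           effect_size_range = c(0.3, 0.5), seed = 20)
  cohorts <- simulate_multi_cohorts(cfg, 5)
  tr <- cohorts[[1]]$truth
  g <- tr$gene_id[tr$is_prognostic][1]
  eff <- se <- numeric(5)
  for (i in 1:5) {
    z <- standardize_genes(cohorts[[i]]$expression)
    f <- suppressWarnings(fit_cox(z$values[g, ], cohorts[[i]]$clinical))
    eff[i] <- f$logHR[1]; se[i] <- f$se[1]
  }
  # inverse-variance combination by hand
  w <- 1 / se^2
  combined <- sum(w * eff) / sum(w)
  se_c <- sqrt(1 / sum(w))
  expect_lt(abs(combined - tr$true_logHR[tr$gene_id == g]), 2 * se_c)
})

test_that("stronger configured effects shift estimated effect sizes upward", {
  est_mean <- function(lo, hi, seed) {
    cfg <- simulation_config(n_samples = 300, n_genes = 40, n_prognostic = 5,
                             effect_size_range = c(lo, hi), seed = seed)
    st <- simulate_bulk_cohort(cfg)
    z <- standardize_genes(st$expression)
    prog <- st$truth$gene_id[st$truth$is_prognostic]
    mean(vapply(prog, function(g)
      abs(suppressWarnings(fit_cox(z$values[g, ], st$clinical))$logHR[1]),
      numeric(1)))
  }
  weak <- vapply(1:3, function(i) est_mean(0.1, 0.2, 400 + i), numeric(1))
  strong <- vapply(1:3, function(i) est_mean(0.6, 0.9, 400 + i), numeric(1))
  expect_true(all(strong > weak))
})

test_that("cell table simulation is labeled, sized, and reproducible", {
  ct <- simulate_cell_table(10, 50, c("epithelial", "immune", "stromal"),
                            marker_strength = 2, dropout = 0.3, seed = 4)
  expect_equal(nrow(ct$values), 500)
  expect_identical(ct$cells$cell_id, rownames(ct$values))
  expect_true(all(ct$cells$lineage %in% c("epithelial", "immune", "stromal")))
  expect_true(all(ct$values@x >= 0))
  ct2 <- simulate_cell_table(10, 50, c("epithelial", "immune", "stromal"),
                             marker_strength = 2, dropout = 0.3, seed = 4)
  expect_identical(ct$values, ct2$values)

  expect_error(simulate_cell_table(5, 10, "only_one", seed = 1),
               class = "invalid_config")
  expect_error(simulate_cell_table(5, 10, c("a", "b"), dropout = 1, seed = 1),
               class = "invalid_config")
})

test_that("cohort studies round-trip through plain-text writers", {
  cfg <- simulation_config(n_samples = 12, n_genes = 15, n_prognostic = 2,
                           seed = 8)
  st <- simulate_bulk_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort_study(st, dir)
  expr <- read_expression_tsv(file.path(dir, "c1_expression.tsv"))
  expect_equal(expr$values, st$expression$values, tolerance = 1e-6)
  cl <- read.csv(file.path(dir, "c1_clinical.csv"))
  expect_equal(cl$time, st$clinical$time, tolerance = 1e-6)

  ct <- simulate_cell_table(4, 10, c("a", "b"), seed = 2)
  write_cell_table_mtx(ct, dir)
  back <- read_cell_table_mtx(dir)
  expect_equal(as.matrix(back$values), as.matrix(ct$values), tolerance = 1e-6)
  expect_identical(back$cells$lineage, ct$cells$lineage)
})
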