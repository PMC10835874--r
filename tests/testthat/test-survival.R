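test_that("fit_cox matches brute-force Efron partial-likelihood maximization", {
  set.seed(101)
  checked <- 0
  while (checked < 10) {
    n <- sample(5:10, 1)
    cl <- make_clinical(time = sample(1:4, n, replace = TRUE),
                        event = rbinom(n, 1, 0.7))
    x <- round(rnorm(n), 1)
    if (sum(cl$event) == 0 || length(unique(x)) < 2) next
    fit <- tryCatch(suppressWarnings(fit_cox(x, cl)),
                    trscore_error = function(e) NULL)
    if (is.null(fit) || !attr(fit, "converged") || abs(fit$logHR) > 5) next
    expect_equal(fit$logHR, oracle_cox_1d(cl$time, cl$event, x),
                 tolerance = 1e-4)
    checked <- checked + 1
  }
})

test_that("fit_cox rejects degenerate inputs and flags monotone likelihoods", {
  cl <- make_clinical(time = 1:6, event = rep(1L, 6))
  expect_error(fit_cox(rep(2, 6), cl), class = "degenerate_covariate")
  cl0 <- make_clinical(time = 1:6, event = rep(0L, 6))
  expect_error(fit_cox(rnorm(6), cl0), class = "no_events")
  # perfectly separating covariate: reverse-ordered with the event times
  expect_warning(fit <- fit_cox(6:1, cl), class = "cox_nonconvergence")
  expect_false(attr(fit, "converged"))
  # hazard-ratio arithmetic is consistent
  set.seed(7)
  cl2 <- make_clinical(time = rexp(40), event = rbinom(40, 1, 0.7))
  f <- fit_cox(rnorm(40), cl2)
  expect_equal(f$hr, exp(f$logHR))
  expect_equal(f$ci_lo, exp(f$logHR - 1.96 * f$se))
})

test_that("case-weight identity: duplication at half weight (Breslow exact)", {
  set.seed(8)
  n <- 30
  cl <- make_clinical(time = round(rexp(n), 3), event = rbinom(n, 1, 0.7))
  x <- rnorm(n)
  base <- fit_cox(x, cl, ties = "breslow")
  dup <- make_clinical(time = rep(cl$time, 2), event = rep(cl$event, 2))
  half <- fit_cox(rep(x, 2), dup, weights = rep(0.5, 2 * n),
                  ties = "breslow")
  expect_equal(half$logHR, base$logHR, tolerance = 1e-8)
  # under Efron the duplicated copies tie and the identity is approximate
  base_e <- fit_cox(x, cl)
  half_e <- fit_cox(rep(x, 2), dup, weights = rep(0.5, 2 * n))
  expect_equal(half_e$logHR, base_e$logHR, tolerance = 0.05)
})

test_that("multivariable model separates score and grade signal", {
  # outcome driven by expression only: grade term stays near zero
  cfg <- simulation_config(n_samples = 400, n_genes = 60, n_prognostic = 8,
                           effect_size_range = c(0.5, 0.8), seed = 31)
  st <- simulate_bulk_cohort(cfg)
  z <- standardize_genes(st$expression)
  sig <- signature_def(st$truth$gene_id[st$truth$is_prognostic],
                       st$truth$true_logHR[st$truth$is_prognostic])
  sc <- compute_trs(z, sig)
  mv <- multivariable_trs_ggg(sc, st$clinical)
  expect_lt(mv$p[mv$term == "trs"], 0.01)
  expect_gt(mv$p[mv$term == "ggg_gt2"], 0.05)

  # outcome driven by grade only: converse pattern
  cfg2 <- simulation_config(n_samples = 400, n_genes = 60, n_prognostic = 0,
                            ggg_effect = 1.2, seed = 32)
  st2 <- simulate_bulk_cohort(cfg2)
  z2 <- standardize_genes(st2$expression)
  sig2 <- signature_def(gene_ids(z2)[1:8], rep(c(0.5, -0.5), 4))
  mv2 <- multivariable_trs_ggg(compute_trs(z2, sig2), st2$clinical)
  expect_lt(mv2$p[mv2$term == "ggg_gt2"], 0.01)
  expect_gt(mv2$p[mv2$term == "trs"], 0.05)

  cl_low <- st$clinical
  cl_low$ggg <- 1L
  expect_error(multivariable_trs_ggg(sc, cl_low),
               class = "degenerate_covariate")
  cl_na <- st$clinical
  cl_na$ggg[3] <- NA
  expect_error(multivariable_trs_ggg(sc, cl_na),
               class = "missing_covariate")
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  cl <- make_clinical(time = c(1, 2, 3), event = c(1L, 1L, 1L))
  km <- km_estimate(cl, rep("all", 3))
  cv <- km$curves$all
  expect_equal(cv$surv[cv$n_event > 0], c(2/3, 1/3, 0), tolerance = 1e-12)

  # all censored: survival stays at 1
  cl_c <- make_clinical(time = c(1, 2, 3), event = c(0L, 0L, 0L))
  km_c <- km_estimate(cl_c, rep("all", 3))
  expect_true(all(km_c$curves$all$surv == 1))
  expect_equal(km_c$survival_at(2.5), 1)

  # mixed toy with censoring, checked against the naive product over risk sets
  cl_m <- make_clinical(time = c(2, 4, 4, 5, 7, 9), event = c(1, 0, 1, 1, 0, 1))
  km_m <- km_estimate(cl_m, rep("all", 6))
  hand <- oracle_km(cl_m$time, cl_m$event)
  got <- km_m$survival_at(hand$time)
  expect_equal(got, hand$surv, tolerance = 1e-12)
  expect_error(km_estimate(cl_m, factor(rep("a", 6), levels = c("a", "b"))),
               class = "empty_group")
})

test_that("log-rank statistic equals the manual O/E/V tabulation", {
  set.seed(9)
  cl <- make_clinical(time = c(rexp(15, 0.2), rexp(15, 0.6)),
                      event = rbinom(30, 1, 0.8))
  grp <- rep(c("a", "b"), each = 15)
  lr <- logrank_test(cl, grp)
  expect_equal(lr$chi2, oracle_logrank(cl$time, cl$event, grp),
               tolerance = 1e-10)
  # label swap leaves the statistic unchanged
  lr2 <- logrank_test(cl, ifelse(grp == "a", "b", "a"))
  expect_equal(lr2$chi2, lr$chi2)
  # identical data in both groups: no signal
  cl_same <- make_clinical(time = rep(c(1, 2, 3), 2), event = rep(1L, 6))
  lr0 <- logrank_test(cl_same, rep(c("a", "b"), each = 3))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(cl_same, rep("a", 6)),
               class = "degenerate_grouping")
})

test_that("concordance index matches exhaustive pair enumeration", {
  # perfect anti-ordering: higher score, shorter time to event
  cl <- make_clinical(time = c(5, 4, 3, 2, 1), event = rep(1L, 5))
  expect_equal(concordance_index(1:5, cl), 1.0)

  cl_m <- make_clinical(time = c(3, 1, 4, 2, 6, 5), event = c(1, 1, 0, 1, 1, 0))
  sc <- c(0.3, 1.2, -0.5, 0.8, -1, 0.1)
  expect_equal(concordance_index(sc, cl_m),
               oracle_cindex(sc, cl_m$time, cl_m$event), tolerance = 1e-12)

  cl_all_c <- make_clinical(time = 1:4, event = rep(0L, 4))
  expect_error(concordance_index(rnorm(4), cl_all_c), class = "no_pairs")

  # independent scores hover near 1/2
  set.seed(13)
  cs <- replicate(20, {
    cln <- make_clinical(time = rexp(60), event = rbinom(60, 1, 0.7))
    concordance_index(rnorm(60), cln)
  })
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("log-rank and Cox significance calls agree on most planted cohorts", {
  agree <- 0
  for (i in 1:10) {
    cfg <- simulation_config(n_samples = 120, n_genes = 40,
                             n_prognostic = ifelse(i %% 2 == 0, 6, 0),
                             effect_size_range = c(0.5, 0.8), seed = 300 + i)
    st <- simulate_bulk_cohort(cfg)
    z <- standardize_genes(st$expression)
    sig <- signature_def(gene_ids(z)[1:6],
                         ifelse(st$truth$true_logHR[1:6] != 0,
                                st$truth$true_logHR[1:6],
                                rep(c(0.5, -0.5), 3)))
    sc <- compute_trs(z, sig)
    cox_sig <- suppressWarnings(fit_cox(sc, st$clinical))$p[1] < 0.05
    lr <- tryCatch(logrank_test(st$clinical, dichotomize(sc)),
                   trscore_error = function(e) NULL)
    if (is.null(lr)) next
    agree <- agree + ((lr$p < 0.05) == cox_sig)
  }
  expect_gte(agree, 8)
})
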