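# shared small cohort used across the one-sample fits
fixture_cohort <- local({
  m <- generate_manifest(15, seed = 301)
  spec <- simulation_spec(n_cases = 1200, n_controls = 1200, n_snps = 15,
                          causal_logor_per_year = log(0.9),
                          bmi_on_exposure = 0, bmi_on_disease = 0,
                          n_studies = 3, seed = 302)
  ds <- generate_cohort(spec, m)
  g <- scale_grs(compute_grs(ds$dosages, ds$manifest), 0.57)
  list(ds = ds, g = g)
})

test_that("the one-sample fit is invariant to row permutation", {
  ds <- fixture_cohort$ds; g <- fixture_cohort$g
  e1 <- fit_grs_logistic(ds$cohort, g)
  perm <- withr::with_seed(1, sample(nrow(ds$cohort)))
  e2 <- fit_grs_logistic(ds$cohort[perm, ], g)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-10)
  expect_equal(e1$se, e2$se, tolerance = 1e-10)
})

test_that("estimates carry consistent OR/CI fields and sample sizes", {
  e <- fit_grs_logistic(fixture_cohort$ds$cohort, fixture_cohort$g)
  expect_equal(e$or, exp(e$beta))
  expect_equal(e$ci_lower, exp(e$beta - 1.96 * e$se))
  expect_equal(e$ci_upper, exp(e$beta + 1.96 * e$se))
  expect_lt(e$ci_lower, e$ci_upper)
  expect_equal(e$n_cases, 1200)
  expect_equal(e$n_controls, 1200)
  td <- tidy(e)
  expect_equal(td$estimate[td$term == "grs"], e$beta)
})

test_that("degenerate inputs raise explicit fit errors", {
  coh <- fixture_cohort$ds$cohort
  g <- fixture_cohort$g
  g0 <- g; g0$scaled <- 1 # zero variance
  expect_error(fit_grs_logistic(coh, g0), class = "repromr_fit_error")
  all_case <- coh; all_case$case_status <- "case"
  expect_error(fit_grs_logistic(all_case, g), class = "repromr_fit_error")
  # perfectly separating score
  sep <- g
  sep$scaled <- ifelse(coh$case_status == "case", 10, -10) +
    withr::with_seed(2, rnorm(nrow(coh), 0, 1e-4))
  expect_error(
    suppressWarnings(fit_grs_logistic(coh, sep, covariates = character())),
    class = "repromr_fit_error")
})

test_that("fixed-effects meta-analysis follows the inverse-variance algebra", {
  one <- tibble::tibble(beta = 0.1, se = 0.05)
  expect_equal(meta_fixed(one)$beta, 0.1)
  expect_equal(meta_fixed(one)$se, 0.05)
  two <- meta_fixed(list(one, one))
  expect_equal(two$beta, 0.1)
  expect_equal(two$se, 0.05 / sqrt(2))
  # k copies: se / sqrt(k)
  five <- meta_fixed(list(one, one, one, one, one))
  expect_equal(five$se, 0.05 / sqrt(5))
  # arbitrary triple against an independent implementation
  tr <- list(tibble::tibble(beta = 0.12, se = 0.04),
             tibble::tibble(beta = -0.05, se = 0.11),
             tibble::tibble(beta = 0.02, se = 0.07))
  got <- meta_fixed(tr)
  skip_if_not_installed("metafor")
  or1 <- metafor::rma(yi = c(0.12, -0.05, 0.02), sei = c(0.04, 0.11, 0.07),
                      method = "FE")
  expect_equal(got$beta, as.numeric(or1$beta), tolerance = 1e-10)
  expect_equal(got$se, or1$se, tolerance = 1e-10)
  expect_error(meta_fixed(list()), class = "repromr_invalid_argument")
})

test_that("stratified analysis returns per-stratum fits and a heterogeneity LRT", {
  ds <- fixture_cohort$ds
  res <- stratified_analysis(ds$cohort, fixture_cohort$g, "menopausal_status")
  expect_setequal(res$stratum, c("post", "pre"))
  hp <- attr(res, "heterogeneity_p")
  expect_true(hp > 0 && hp <= 1)
  expect_false(attr(res, "heterogeneity_flagged"))
  td <- tidy(res)
  expect_true("heterogeneity_p" %in% names(td))
})

test_that("single-level stratum is flagged undefined", {
  coh <- fixture_cohort$ds$cohort
  coh$onegroup <- "all"
  res <- stratified_analysis(coh, fixture_cohort$g, "onegroup")
  expect_true(attr(res, "heterogeneity_flagged"))
  expect_true(is.na(attr(res, "heterogeneity_p")))
})

test_that("heterogeneity p is null-calibrated when strata share one effect", {
  pvals <- vapply(1:30, function(r) {
    m <- generate_manifest(10, seed = 400 + r)
    spec <- simulation_spec(n_cases = 500, n_controls = 500, n_snps = 10,
                            bmi_on_exposure = 0, bmi_on_disease = 0,
                            n_studies = 2, seed = 500 + r)
    ds <- generate_cohort(spec, m)
    g <- scale_grs(compute_grs(ds$dosages, ds$manifest), 0.57)
    coh <- ds$cohort
    coh$half <- withr::with_seed(r, sample(c("a", "b"), nrow(coh), TRUE))
    attr(stratified_analysis(coh, g, "half"), "heterogeneity_p")
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("heterogeneity LRT detects genuinely different stratum effects", {
  # two strata with OR 0.8 vs 1.2 per year
  hits <- 0
  reps <- 15
  for (r in 1:reps) {
    m <- generate_manifest(10, seed = 600 + r)
    halves <- lapply(c(log(0.8), log(1.2)), function(th) {
      spec <- simulation_spec(n_cases = 2500, n_controls = 2500, n_snps = 10,
                              causal_logor_per_year = th,
                              bmi_on_exposure = 0, bmi_on_disease = 0,
                              n_studies = 2, seed = 700 + r + round(1e3 * th))
      generate_cohort(spec, m)
    })
    coh <- dplyr::bind_rows(
      dplyr::mutate(halves[[1]]$cohort, half = "a",
                    individual_id = paste0("a", individual_id)),
      dplyr::mutate(halves[[2]]$cohort, half = "b",
                    individual_id = paste0("b", individual_id)))
    dos <- dplyr::bind_rows(
      dplyr::mutate(halves[[1]]$dosages, individual_id = paste0("a", individual_id)),
      dplyr::mutate(halves[[2]]$dosages, individual_id = paste0("b", individual_id)))
    attr(dos, "effect_alleles") <- attr(halves[[1]]$dosages, "effect_alleles")
    g <- scale_grs(compute_grs(dos, m), 0.57)
    hp <- attr(stratified_analysis(coh, g, "half"), "heterogeneity_p")
    hits <- hits + (hp < 0.05)
  }
  expect_gte(hits / reps, 0.8)
})

test_that("case-only site test is well-behaved under the null and degenerate", {
  ds <- fixture_cohort$ds
  res <- site_heterogeneity_case_only(ds$cohort, fixture_cohort$g)
  expect_true(res$pvalue > 0 && res$pvalue <= 1)
  expect_equal(res$n_colon + res$n_rectum, 1200)
  # constant GRS among cases -> error
  g0 <- fixture_cohort$g
  g0$scaled <- 0
  expect_error(site_heterogeneity_case_only(ds$cohort, g0),
               class = "repromr_fit_error")
  # one site absent -> error
  coh <- ds$cohort
  coh$site[coh$site == "rectum"] <- "colon"
  expect_error(site_heterogeneity_case_only(coh, fixture_cohort$g),
               class = "repromr_fit_error")
})

test_that("adjusting for an independent BMI score barely moves the estimate", {
  ds <- fixture_cohort$ds
  g <- fixture_cohort$g
  base <- fit_grs_logistic(ds$cohort, g)
  bmi_g <- tibble::tibble(individual_id = ds$cohort$individual_id,
                          raw = withr::with_seed(3, rnorm(nrow(ds$cohort))))
  adj <- fit_grs_logistic(ds$cohort, g, extra_scores = bmi_g)
  expect_lt(abs(adj$beta - base$beta), 0.5 * base$se)
})
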