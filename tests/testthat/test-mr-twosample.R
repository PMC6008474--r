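test_that("Wald ratios follow the delta method", {
  s <- tibble::tibble(rsid = "a", beta_exposure = 0.5, se_exposure = 0.02,
                      beta_outcome = 0.1, se_outcome = 0.05)
  r <- ratio_estimates(s)
  expect_equal(r$ratio, 0.2)
  expect_equal(r$se_ratio, 0.1)
  expect_equal(r$precision, 1 / r$se_ratio)
  s$beta_outcome <- 0
  expect_equal(ratio_estimates(s)$ratio, 0)
  s$beta_exposure <- 0
  expect_error(suppressWarnings(ratio_estimates(s)),
               class = "repromr_invalid_argument")
})

test_that("ratio SE matches the Monte-Carlo SD for strong instruments", {
  bx <- 0.5; se_x <- 0.02; by <- 0.15; se_y <- 0.04
  sims <- withr::with_seed(10, rnorm(40000, by, se_y) / rnorm(40000, bx, se_x))
  s <- tibble::tibble(beta_exposure = bx, se_exposure = se_x,
                      beta_outcome = by, se_outcome = se_y)
  expect_lt(abs(ratio_estimates(s)$se_ratio - sd(sims)) / sd(sims), 0.1)
})

test_that("IVW equals the precision-weighted ratio mean (brute force)", {
  s <- make_sumstats(5, theta = 0.1, seed = 2)
  est <- mr_ivw(s)
  w <- s$beta_exposure^2 / s$se_outcome^2
  ratios <- s$beta_outcome / s$beta_exposure
  expect_equal(est$beta, sum(w * ratios) / sum(w), tolerance = 1e-10)
  # single SNP: its ratio
  one <- mr_ivw(s[1, ])
  expect_equal(one$beta, ratios[1], tolerance = 1e-12)
  # identical ratios: the common value whatever the weights
  s2 <- s; s2$beta_outcome <- 0.25 * s2$beta_exposure
  expect_equal(mr_ivw(s2)$beta, 0.25, tolerance = 1e-12)
})

test_that("IVW equals the Egger slope with the intercept constrained to zero", {
  s <- make_sumstats(12, theta = 0.05, seed = 3)
  w <- 1 / s$se_outcome^2
  constrained <- lm(beta_outcome ~ 0 + beta_exposure, data = s, weights = w)
  expect_equal(mr_ivw(s)$beta, unname(coef(constrained)), tolerance = 1e-10)
})

test_that("Egger recovers slope and intercept exactly on collinear inputs", {
  s <- make_sumstats(6, seed = 4)
  s$beta_outcome <- 0.5 * s$beta_exposure + 0.01
  e <- suppressWarnings(mr_egger(s))
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0.01, tolerance = 1e-10)
  # any weights: perturb the outcome SEs, the exact line stays exact
  s$se_outcome <- runif(6, 0.01, 0.2)
  e2 <- suppressWarnings(mr_egger(s))
  expect_equal(e2$beta, 0.5, tolerance = 1e-10)
  expect_equal(e2$intercept, 0.01, tolerance = 1e-10)
})

test_that("Egger requires three SNPs and exposure-beta variance", {
  s <- make_sumstats(2, seed = 5)
  expect_error(mr_egger(s), class = "repromr_invalid_argument")
  s3 <- make_sumstats(3, seed = 6)
  s3$beta_exposure <- 0.05
  expect_error(mr_egger(s3), class = "repromr_invalid_argument")
})

test_that("Egger is applied after orienting exposure betas non-negative", {
  s <- make_sumstats(8, theta = 0.2, seed = 7)
  flipped <- s
  flip <- c(1, -1, 1, -1, 1, 1, -1, 1)
  flipped$beta_exposure <- s$beta_exposure * flip
  flipped$beta_outcome <- s$beta_outcome * flip
  e1 <- mr_egger(s); e2 <- mr_egger(flipped)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-12)
  expect_equal(e1$intercept, e2$intercept, tolerance = 1e-12)
})

test_that("weighted median equals the plain median under equal weights", {
  s <- tibble::tibble(beta_exposure = rep(1, 3), se_exposure = 0.01,
                      beta_outcome = c(0.1, 0.3, 0.2), se_outcome = 0.05)
  wm <- mr_weighted_median(s, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.2, tolerance = 1e-12)
})

test_that("a centred dominant weight returns that SNP's ratio", {
  # weights 0.05 / 0.9 / 0.05: the dominant SNP sits exactly at cumulative
  # position 1/2 under the S_j - w_j/2 convention
  se_y <- c(sqrt(0.9 / 0.05), 1, sqrt(0.9 / 0.05))
  s <- tibble::tibble(beta_exposure = 1, se_exposure = 0.01,
                      beta_outcome = c(0.05, 0.2, 0.5), se_outcome = se_y)
  wm <- mr_weighted_median(s, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.2, tolerance = 1e-12)
})

test_that("weighted median is invariant to duplicating every SNP", {
  s <- make_sumstats(9, theta = 0.1, seed = 8)
  a <- mr_weighted_median(s, n_boot = 100, seed = 5)
  b <- mr_weighted_median(dplyr::bind_rows(s, s), n_boot = 100, seed = 5)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
})

test_that("bootstrap is seed-reproducible and guards small n_boot", {
  s <- make_sumstats(10, theta = 0.1, seed = 9)
  a <- mr_weighted_median(s, n_boot = 150, seed = 42)
  b <- mr_weighted_median(s, n_boot = 150, seed = 42)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(s, n_boot = 50, seed = 1),
               class = "repromr_invalid_argument")
  expect_error(mr_weighted_median(s[1, ], n_boot = 100, seed = 1),
               class = "repromr_invalid_argument")
})

test_that("all three estimators agree without pleiotropy", {
  m <- generate_manifest(50, seed = 900)
  disagreements <- 0
  for (r in 1:40) {
    spec <- simulation_spec(n_snps = 50, causal_logor_per_year = -0.02,
                            seed = 900 + r)
    ss <- generate_summary_stats(m, spec)
    ivw <- mr_ivw(ss); egg <- mr_egger(ss)
    wm <- mr_weighted_median(ss, n_boot = 150, seed = r)
    agree <- function(a, b) abs(a$beta - b$beta) <
      2 * sqrt(a$se^2 + b$se^2)
    if (!agree(ivw, egg) || !agree(ivw, wm) || !agree(egg, wm)) {
      disagreements <- disagreements + 1
    }
  }
  expect_lte(disagreements / 40, 0.1)
})

test_that("weighted median beats IVW with 40% invalid instruments", {
  m <- generate_manifest(50, seed = 950)
  wins <- 0
  reps <- 60
  theta <- -0.02
  for (r in 1:reps) {
    spec <- simulation_spec(n_snps = 50, causal_logor_per_year = theta,
                            pleiotropy_frac = 0.4, pleiotropy_mean = 0.05,
                            pleiotropy_sd = 0.01, seed = 9500 + r)
    ss <- generate_summary_stats(m, spec)
    wm <- mr_weighted_median(ss, n_boot = 100, seed = r)
    ivw <- mr_ivw(ss)
    wins <- wins + (abs(wm$beta - theta) < abs(ivw$beta - theta))
  }
  expect_gte(wins / reps, 0.9)
})

test_that("funnel data exposes ratios, precision, overlays and asymmetry", {
  s <- make_sumstats(20, theta = 0.1, seed = 11)
  s$beta_exposure[3] <- 0
  fd <- suppressWarnings(funnel_data(s))
  expect_equal(nrow(fd), 19) # zero-beta row dropped
  expect_true(all(fd$precision > 0))
  expect_s3_class(attr(fd, "ivw"), "mr_estimate")
  expect_s3_class(attr(fd, "egger"), "mr_estimate")
  asym <- attr(fd, "asymmetry")
  expect_true(asym$pvalue > 0 && asym$pvalue <= 1)
  p <- autoplot(fd)
  expect_s3_class(p, "ggplot")
})

test_that("funnel asymmetry p-values are uniform under a symmetric null", {
  m <- generate_manifest(40, seed = 970)
  pvals <- vapply(1:80, function(r) {
    spec <- simulation_spec(n_snps = 40, causal_logor_per_year = 0,
                            seed = 9700 + r)
    attr(funnel_data(generate_summary_stats(m, spec)), "asymmetry")$pvalue
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("mr_twosample_all returns one tidy row per method", {
  s <- make_sumstats(10, theta = 0.1, seed = 12)
  res <- mr_twosample_all(s, n_boot = 100, seed = 4)
  expect_setequal(res$method, c("ivw", "egger", "weighted_median"))
})
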