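#' Two-sample summary-statistics Mendelian randomisation
#'
#' Estimators operating on per-SNP exposure and outcome associations:
#' Wald ratio estimates with first-order delta-method standard errors,
#' the inverse-variance weighted (IVW) estimator, MR-Egger regression (whose
#' intercept tests directional pleiotropy and whose slope is a
#' pleiotropy-adjusted causal estimate under the InSIDE assumption), the
#' weighted median estimator with parametric-bootstrap standard errors, and
#' funnel-plot data with an asymmetry test.
#'
#' @name mr_twosample
NULL

validate_sumstats <- function(stats) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  assert_that(is.data.frame(stats) && all(need %in% names(stats)),
              paste0("summary statistics need columns: ",
                     paste(need, collapse = ", ")))
  assert_that(nrow(stats) >= 1, "empty summary-statistics table",
              class = "repromr_invalid_argument")
  assert_that(all(stats$se_exposure > 0) && all(stats$se_outcome > 0),
              "standard errors must be > 0")
  if (!"rsid" %in% names(stats)) {
    stats$rsid <- sprintf("snp%04d", seq_len(nrow(stats)))
  }
  as_tibble(stats)
}

drop_null_exposure <- function(stats) {
  bad <- stats$beta_exposure == 0
  if (any(bad)) {
    warn(paste0(sum(bad), " SNP(s) with zero exposure beta dropped"))
    stats <- stats[!bad, , drop = FALSE]
  }
  assert_that(nrow(stats) >= 1, "no SNPs left after dropping zero exposure betas",
              class = "repromr_invalid_argument")
  stats
}

#' Per-SNP Wald ratio estimates
#'
#' `ratio = beta_outcome / beta_exposure` (log odds per year);
#' `se_ratio = se_outcome / |beta_exposure|` by the first-order delta method.
#' Rows with zero exposure beta are dropped with a warning.
#'
#' @param stats Summary-statistics tibble (`rsid`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`).
#' @return Tibble with `rsid`, `ratio`, `se_ratio`, `precision`
#'   (= 1/se_ratio).
#' @export
ratio_estimates <- function(stats) {
  stats <- drop_null_exposure(validate_sumstats(stats))
  tibble(rsid = stats$rsid,
         ratio = stats$beta_outcome / stats$beta_exposure,
         se_ratio = stats$se_outcome / abs(stats$beta_exposure),
         precision = abs(stats$beta_exposure) / stats$se_outcome)
}

#' Inverse-variance weighted estimator
#'
#' Slope of the weighted least-squares regression of outcome betas on
#' exposure betas through the origin with weights `1/se_outcome^2` —
#' algebraically the precision-weighted mean of the Wald ratios. The
#' standard error is the fixed-effect one (no over-dispersion scaling).
#'
#' @param stats Summary-statistics tibble.
#' @return An `mr_estimate` (method `"ivw"`).
#' @export
mr_ivw <- function(stats) {
  stats <- drop_null_exposure(validate_sumstats(stats))
  w <- 1 / stats$se_outcome^2
  bx <- stats$beta_exposure
  by <- stats$beta_outcome
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  new_mr_estimate("ivw", beta = beta, se = se, n_snps = nrow(stats))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept, weights `1/se_outcome^2`, after orienting all exposure betas
#' non-negative (Egger regression is not orientation-invariant). The
#' intercept estimates the average directional pleiotropic effect; the slope
#' is the pleiotropy-adjusted causal estimate. Standard errors come from the
#' weighted regression (residual-variance based, so balanced pleiotropy
#' inflates them appropriately).
#'
#' @param stats Summary-statistics tibble with at least 3 SNPs.
#' @return An `mr_estimate` (method `"egger"`) carrying intercept columns.
#' @export
mr_egger <- function(stats) {
  stats <- drop_null_exposure(validate_sumstats(stats))
  assert_that(nrow(stats) >= 3, "MR-Egger needs at least 3 SNPs",
              class = "repromr_invalid_argument")
  flip <- sign(stats$beta_exposure)
  bx <- stats$beta_exposure * flip
  by <- stats$beta_outcome * flip
  assert_that(stats::var(bx) > 0, "zero variance in exposure betas",
              class = "repromr_invalid_argument")
  fit <- lm(by ~ bx, weights = 1 / stats$se_outcome^2)
  sm <- summary(fit)$coefficients
  new_mr_estimate("egger", beta = sm["bx", "Estimate"],
                  se = sm["bx", "Std. Error"], n_snps = nrow(stats),
                  intercept = sm["(Intercept)", "Estimate"],
                  intercept_se = sm["(Intercept)", "Std. Error"])
}

# point estimate of the weighted median: ratios ordered, normalised
# inverse-variance weights accumulated, linear interpolation at cumulative
# weight 1/2 with SNP j sitting at position S_j - w_j/2
weighted_median_point <- function(ratio, weight) {
  # merge exactly tied ratios (e.g. duplicated SNPs) so the estimate is
  # invariant to duplication; distinct ratios are untouched
  if (anyDuplicated(ratio)) {
    first <- match(ratio, ratio)
    agg <- rowsum(weight, group = first)
    ratio <- ratio[as.integer(rownames(agg))]
    weight <- agg[, 1]
  }
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  pos <- cumsum(w) - w / 2
  if (0.5 <= pos[1]) return(r[1])
  if (0.5 >= pos[length(pos)]) return(r[length(r)])
  stats::approx(pos, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Ratio estimates are ordered and weighted by their inverse variance; the
#' estimate is interpolated at cumulative weight one half, and is consistent
#' as long as valid instruments carry at least half the weight. The standard
#' error is a parametric bootstrap: exposure and outcome betas are resampled
#' from normal distributions at their reported SEs, the estimator is
#' recomputed, and the SD over replicates is taken; the 95% CI is
#' estimate +/- 1.96 SE.
#'
#' @param stats Summary-statistics tibble with at least 2 SNPs.
#' @param n_boot Bootstrap replicates, at least 100 (default 10000).
#' @param seed Integer seed for the bootstrap (mandatory).
#' @return An `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(stats, n_boot = 10000, seed) {
  stats <- drop_null_exposure(validate_sumstats(stats))
  assert_that(nrow(stats) >= 2, "weighted median needs at least 2 SNPs",
              class = "repromr_invalid_argument")
  assert_that(is_count(n_boot) && n_boot >= 100,
              "`n_boot` must be at least 100 (smaller values give unstable SEs)",
              class = "repromr_invalid_argument")
  assert_that(!missing(seed), "`seed` is mandatory")

  point_of <- function(bx, by, se_y) {
    ratio <- by / bx
    weight <- (bx / se_y)^2
    weighted_median_point(ratio, weight)
  }
  est <- point_of(stats$beta_exposure, stats$beta_outcome, stats$se_outcome)
  J <- nrow(stats)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(J, stats$beta_exposure, stats$se_exposure)
      by <- rnorm(J, stats$beta_outcome, stats$se_outcome)
      ok <- bx != 0
      point_of(bx[ok], by[ok], stats$se_outcome[ok])
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", beta = est, se = stats::sd(boots),
                  n_snps = J)
}

#' Funnel-plot data and asymmetry test
#'
#' Per-SNP (ratio, precision) pairs for funnel plotting, with the IVW and
#' Egger estimates attached for overlay, plus an Egger-type asymmetry test:
#' the standardised ratio (ratio/se) is regressed on precision and the
#' intercept p-value is reported — symmetric funnels give a null intercept.
#'
#' @param stats Summary-statistics tibble.
#' @return A `funnel_data` tibble (`rsid`, `ratio`, `precision`) with
#'   attributes `ivw`, `egger` (both `mr_estimate`s) and `asymmetry`
#'   (one-row tibble: estimate, se, pvalue).
#' @export
funnel_data <- function(stats) {
  stats <- drop_null_exposure(validate_sumstats(stats))
  rat <- ratio_estimates(stats)
  ivw <- mr_ivw(stats)
  egger <- if (nrow(stats) >= 3) mr_egger(stats) else NULL
  snd <- rat$ratio / rat$se_ratio
  asym <- if (nrow(rat) >= 3) {
    fit <- lm(snd ~ rat$precision)
    sm <- summary(fit)$coefficients
    tibble(estimate = sm[1, "Estimate"], se = sm[1, "Std. Error"],
           pvalue = 2 * pnorm(abs(sm[1, "Estimate"] / sm[1, "Std. Error"]),
                              lower.tail = FALSE))
  } else {
    tibble(estimate = NA_real_, se = NA_real_, pvalue = NA_real_)
  }
  out <- rat[, c("rsid", "ratio", "precision")]
  structure(out, ivw = ivw, egger = egger, asymmetry = asym,
            class = c("funnel_data", class(out)))
}

#' Run a set of two-sample estimators
#'
#' Convenience wrapper returning one tidy row per requested method.
#'
#' @param stats Summary-statistics tibble.
#' @param methods Subset of `c("ivw", "egger", "weighted_median")`.
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @return Tibble of `mr_estimate` rows.
#' @export
mr_twosample_all <- function(stats, methods = c("ivw", "egger", "weighted_median"),
                             n_boot = 10000, seed = 1L) {
  res <- list()
  if ("ivw" %in% methods) res$ivw <- mr_ivw(stats)
  if ("egger" %in% methods) res$egger <- mr_egger(stats)
  if ("weighted_median" %in% methods) {
    res$wm <- mr_weighted_median(stats, n_boot = n_boot, seed = seed)
  }
  out <- dplyr::bind_rows(res)
  class(out) <- setdiff(class(out), "mr_estimate") # multi-row plain tibble
  out
}
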