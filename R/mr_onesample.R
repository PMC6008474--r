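#' One-sample genetic-risk-score Mendelian randomisation
#'
#' Covariate-adjusted logistic regression of case status on the scaled GRS
#' (the one-sample MR estimate, log odds ratio per year of exposure),
#' fixed-effects meta-analysis across consortia, stratified analyses with
#' likelihood-ratio heterogeneity tests, and the case-only test for colon
#' versus rectal effect heterogeneity.
#'
#' @name mr_onesample
NULL

new_mr_estimate <- function(method, beta, se, n_cases = NA_integer_,
                            n_controls = NA_integer_, n_snps = NA_integer_,
                            intercept = NULL, intercept_se = NULL) {
  assert_that(is.finite(beta) && is.finite(se) && se > 0,
              "estimate must have finite beta and positive se",
              class = "repromr_fit_error")
  z <- beta / se
  out <- tibble(
    method = method, beta = beta, se = se, or = exp(beta),
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    pvalue = 2 * pnorm(abs(z), lower.tail = FALSE),
    n_cases = n_cases, n_controls = n_controls, n_snps = n_snps
  )
  if (!is.null(intercept)) {
    zi <- intercept / intercept_se
    out$intercept <- intercept
    out$intercept_se <- intercept_se
    out$intercept_ci_lower <- intercept - 1.96 * intercept_se
    out$intercept_ci_upper <- intercept + 1.96 * intercept_se
    out$intercept_pvalue <- 2 * pnorm(abs(zi), lower.tail = FALSE)
  }
  class(out) <- c("mr_estimate", class(out))
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate: %s> OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$method, x$or, x$ci_lower, x$ci_upper, x$pvalue))
  if ("intercept" %in% names(x)) {
    cat(sprintf("  intercept %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
                x$intercept, x$intercept_ci_lower, x$intercept_ci_upper,
                x$intercept_pvalue))
  }
  invisible(x)
}

# assemble the model frame shared by the one-sample fits; covariates is a
# selection out of c("age", "study", "pcs") plus any literal column names
build_model_frame <- function(cohort, grs, covariates, extra_scores = NULL,
                              grs_col = c("scaled", "raw")) {
  grs_col <- if (is.character(grs_col) && length(grs_col) > 1) {
    if ("scaled" %in% names(grs)) "scaled" else "raw"
  } else {
    match.arg(grs_col)
  }
  assert_that(grs_col %in% names(grs),
              paste0("grs lacks a `", grs_col, "` column"))
  dat <- dplyr::inner_join(cohort,
                           grs[, c("individual_id", grs_col)],
                           by = "individual_id")
  dat$grs <- dat[[grs_col]]
  vars <- "grs"
  if ("age" %in% covariates) vars <- c(vars, "age")
  if ("study" %in% covariates && length(unique(dat$study)) > 1) {
    dat$study <- factor(dat$study)
    vars <- c(vars, "study")
  }
  if ("pcs" %in% covariates) {
    vars <- c(vars, grep("^pc[0-9]+$", names(dat), value = TRUE))
  }
  vars <- c(vars, setdiff(covariates, c("age", "study", "pcs")))
  if (!is.null(extra_scores)) {
    if (is.data.frame(extra_scores)) extra_scores <- list(extra_scores)
    for (i in seq_along(extra_scores)) {
      ex <- extra_scores[[i]]
      col <- if ("scaled" %in% names(ex)) "scaled" else "raw"
      nm <- paste0("extra_score", i)
      dat <- dplyr::left_join(dat, setNames(ex[, c("individual_id", col)],
                                            c("individual_id", nm)),
                              by = "individual_id")
      vars <- c(vars, nm)
    }
  }
  dat <- dat[stats::complete.cases(dat[vars]), , drop = FALSE]
  list(data = dat, vars = vars)
}

check_glm_fit <- function(fit, term = "grs") {
  if (!fit$converged) {
    stop_repromr("logistic regression did not converge", "repromr_fit_error")
  }
  sm <- summary(fit)$coefficients
  assert_that(term %in% rownames(sm),
              paste0("term `", term, "` dropped from the fit (degenerate input)"),
              class = "repromr_fit_error")
  if (sm[term, "Std. Error"] > 1e3 || abs(sm[term, "Estimate"]) > 50) {
    stop_repromr("apparent complete separation in logistic fit",
                 "repromr_fit_error")
  }
  sm
}

#' One-sample MR logistic fit
#'
#' Maximum-likelihood logistic regression of case status on the scaled GRS,
#' adjusted for the selected covariates (age, study, ancestry principal
#' components by default). Convergence uses iteratively reweighted least
#' squares with relative log-likelihood tolerance 1e-8 and up to 100
#' iterations; non-convergence and apparent complete separation raise
#' explicit errors. Complete-case analysis within the model.
#'
#' @param cohort Cohort tibble with `individual_id`, `case_status`, and
#'   covariates.
#' @param grs A `grs_vector`; its `scaled` column is used if present.
#' @param covariates Character selection: any of `"age"`, `"study"`,
#'   `"pcs"`, plus literal column names. Default `c("age","study","pcs")`.
#' @param extra_scores Optional `grs_vector` (or list of them) added as
#'   further adjustment covariates, e.g. a 77-SNP BMI score.
#' @param grs_col `"scaled"` or `"raw"` (default: scaled when available).
#' @return An `mr_estimate` (method `"grs_logistic"`).
#' @export
fit_grs_logistic <- function(cohort, grs, covariates = c("age", "study", "pcs"),
                             extra_scores = NULL,
                             grs_col = c("scaled", "raw")) {
  mf <- build_model_frame(cohort, grs, covariates, extra_scores, grs_col)
  dat <- mf$data
  dat$y <- as.integer(dat$case_status == "case")
  assert_that(sum(dat$y) >= 1 && sum(1 - dat$y) >= 1,
              "need at least one case and one control",
              class = "repromr_fit_error")
  assert_that(stats::var(dat$grs) > 0, "GRS has zero variance",
              class = "repromr_fit_error")
  form <- stats::as.formula(paste("y ~", paste(mf$vars, collapse = " + ")))
  fit <- glm(form, family = stats::binomial(), data = dat,
             control = glm.control(epsilon = 1e-8, maxit = 100))
  sm <- check_glm_fit(fit)
  new_mr_estimate("grs_logistic", beta = sm["grs", "Estimate"],
                  se = sm["grs", "Std. Error"],
                  n_cases = sum(dat$y), n_controls = sum(1 - dat$y),
                  n_snps = attr(grs, "n_snps") %||% NA_integer_)
}

#' Fixed-effects meta-analysis of MR estimates
#'
#' Inverse-variance pooling under a common-effect assumption:
#' `beta = sum(b/se^2) / sum(1/se^2)`, `se = sqrt(1 / sum(1/se^2))`.
#'
#' @param estimates A list of `mr_estimate`s, or a tibble with `beta` and
#'   `se` columns.
#' @return An `mr_estimate` (method `"fixed_effects_meta"`).
#' @export
meta_fixed <- function(estimates) {
  if (is.data.frame(estimates)) estimates <- list(estimates)
  assert_that(length(estimates) >= 1, "`estimates` must be non-empty",
              class = "repromr_invalid_argument")
  tab <- dplyr::bind_rows(lapply(estimates, function(e) {
    tibble(beta = e$beta, se = e$se,
           n_cases = e[["n_cases"]] %||% NA_integer_,
           n_controls = e[["n_controls"]] %||% NA_integer_)
  }))
  assert_that(all(tab$se > 0), "all estimates need se > 0")
  w <- 1 / tab$se^2
  new_mr_estimate("fixed_effects_meta",
                  beta = sum(w * tab$beta) / sum(w), se = 1 / sqrt(sum(w)),
                  n_cases = if (anyNA(tab$n_cases)) NA_integer_ else sum(tab$n_cases),
                  n_controls = if (anyNA(tab$n_controls)) NA_integer_ else
                    sum(tab$n_controls))
}

#' Stratified one-sample MR with heterogeneity LRT
#'
#' Fits the MR logistic model within each level of a stratification variable
#' and tests effect heterogeneity by a likelihood-ratio test comparing the
#' pooled model with and without a GRS-by-stratum interaction (chi-square on
#' levels - 1 degrees of freedom). Individuals with missing stratum are
#' excluded.
#'
#' @param cohort,grs,covariates As in [fit_grs_logistic()].
#' @param stratum Name of the stratification column.
#' @return A `stratified_result`: per-stratum tibble of estimates with
#'   attribute `heterogeneity_p` (NA, flagged, when the stratum has a single
#'   level).
#' @export
stratified_analysis <- function(cohort, grs, stratum,
                                covariates = c("age", "study", "pcs")) {
  assert_that(stratum %in% names(cohort),
              paste0("stratum column `", stratum, "` not in cohort"))
  keep <- !is.na(cohort[[stratum]]) & cohort[[stratum]] != "missing"
  dat <- cohort[keep, , drop = FALSE]
  levels <- sort(unique(as.character(dat[[stratum]])))

  per <- dplyr::bind_rows(lapply(levels, function(lv) {
    est <- fit_grs_logistic(dat[dat[[stratum]] == lv, , drop = FALSE], grs,
                            covariates)
    est$stratum <- lv
    est
  }))

  het_p <- NA_real_
  flagged <- length(levels) < 2
  if (!flagged) {
    mf <- build_model_frame(dat, grs, covariates)
    d <- mf$data
    d$y <- as.integer(d$case_status == "case")
    d$stratum_var <- factor(d[[stratum]])
    base_terms <- paste(c(mf$vars, "stratum_var"), collapse = " + ")
    f0 <- stats::as.formula(paste("y ~", base_terms))
    f1 <- stats::as.formula(paste("y ~", base_terms, "+ grs:stratum_var"))
    m0 <- glm(f0, family = stats::binomial(), data = d,
              control = glm.control(epsilon = 1e-8, maxit = 100))
    m1 <- glm(f1, family = stats::binomial(), data = d,
              control = glm.control(epsilon = 1e-8, maxit = 100))
    het_p <- pchisq(m0$deviance - m1$deviance, df = length(levels) - 1,
                    lower.tail = FALSE)
  }
  structure(per, heterogeneity_p = het_p, heterogeneity_flagged = flagged,
            stratum = stratum,
            class = c("stratified_result", class(per)))
}

#' @export
print.stratified_result <- function(x, ...) {
  cat("<stratified_result> by", attr(x, "stratum"), "\n")
  print(as_tibble(x)[, c("stratum", "n_cases", "n_controls", "or",
                         "ci_lower", "ci_upper", "pvalue")])
  hp <- attr(x, "heterogeneity_p")
  if (isTRUE(attr(x, "heterogeneity_flagged"))) {
    cat("heterogeneity: undefined (single stratum level)\n")
  } else {
    cat("heterogeneity LRT p =", signif(hp, 3), "\n")
  }
  invisible(x)
}

#' Case-only test of colon versus rectal effect heterogeneity
#'
#' Among cases only, logistic regression of tumour site (colon vs rectum) on
#' the GRS adjusted for the usual covariates; the Wald p-value of the GRS
#' term tests whether genetically predicted exposure relates differently to
#' the two sites.
#'
#' @param cohort Cohort tibble (cases are selected internally via
#'   `case_status`; a pre-subset case table also works).
#' @param grs A `grs_vector`.
#' @param covariates Covariate selection, default `c("age","study","pcs")`.
#' @return One-row tibble: `beta`, `se`, `pvalue`, `n_colon`, `n_rectum`.
#' @export
site_heterogeneity_case_only <- function(cohort, grs,
                                         covariates = c("age", "study", "pcs")) {
  cases <- cohort[cohort$case_status == "case" &
                    cohort$site %in% c("colon", "rectum"), , drop = FALSE]
  n_colon <- sum(cases$site == "colon")
  n_rectum <- sum(cases$site == "rectum")
  assert_that(n_colon >= 1 && n_rectum >= 1,
              "need at least one colon and one rectal case",
              class = "repromr_fit_error")
  mf <- build_model_frame(cases, grs, covariates)
  dat <- mf$data
  assert_that(stats::var(dat$grs) > 0, "GRS has zero variance among cases",
              class = "repromr_fit_error")
  dat$y <- as.integer(dat$site == "colon")
  form <- stats::as.formula(paste("y ~", paste(mf$vars, collapse = " + ")))
  fit <- glm(form, family = stats::binomial(), data = dat,
             control = glm.control(epsilon = 1e-8, maxit = 100))
  sm <- check_glm_fit(fit)
  tibble(beta = sm["grs", "Estimate"], se = sm["grs", "Std. Error"],
         pvalue = 2 * pnorm(abs(sm["grs", "Estimate"] / sm["grs", "Std. Error"]),
                            lower.tail = FALSE),
         n_colon = n_colon, n_rectum = n_rectum)
}
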