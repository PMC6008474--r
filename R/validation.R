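#' Instrument diagnostics and study power
#'
#' The instrument-strength F-statistic, a confounder association screen run
#' in controls, and power calculation for a genetic-risk-score instrument on
#' a binary outcome (analytic normal approximation and a simulation mode
#' that draws replicate score-outcome cohorts).
#'
#' @name validation
NULL

#' Instrument-strength F-statistic
#'
#' `F = R^2 (n - K - 1) / ((1 - R^2) K)` with `R^2` the variance of the
#' exposure explained by the instrument, `n` the analysis sample size and
#' `K` the number of instruments (a single GRS counts as one). Values above
#' 10 conventionally denote a strong instrument.
#'
#' @param r2 Explained variance, in [0, 1).
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of instruments (default 1, the GRS convention).
#' @return The F-statistic (vectorised over `r2`).
#' @seealso [instrument_strength()]
#' @export
f_statistic <- function(r2, n, k = 1) {
  assert_that(all(r2 >= 0 & r2 < 1), "`r2` must be in [0, 1)",
              class = "repromr_domain_error")
  assert_that(all(k >= 1), "`k` must be >= 1", class = "repromr_domain_error")
  assert_that(all(n > k + 1), "`n` must exceed k + 1",
              class = "repromr_domain_error")
  r2 * (n - k - 1) / ((1 - r2) * k)
}

#' Tabulate instrument strength
#'
#' @inheritParams f_statistic
#' @param threshold Strength cutoff (default 10).
#' @return Tibble with `r2`, `n`, `k`, `f`, `strong`.
#' @export
instrument_strength <- function(r2, n, k = 1, threshold = 10) {
  f <- f_statistic(r2, n, k)
  tibble(r2 = r2, n = n, k = k, f = f, strong = f > threshold)
}

#' Confounder association screen
#'
#' Tests, among controls, the association between the GRS and a set of
#' disease risk factors: linear regression for continuous factors, logistic
#' regression for binary factors, multinomial logistic regression (with a
#' likelihood-ratio p) for factors with more than two levels. A factor with
#' a single observed level is flagged and gets no p-value. Raw p-values are
#' reported without multiplicity correction.
#'
#' @param grs A `grs_vector`.
#' @param cohort Cohort tibble; rows with `case_status == "control"` are
#'   used.
#' @param factors Character vector of cohort columns to screen; defaults to
#'   the standard set (BMI, smoking, family history, aspirin use, education,
#'   both MHT types) intersected with available columns.
#' @return Tibble: `risk_factor`, `model`, `estimate`, `pvalue`, `n`,
#'   `flagged`.
#' @export
confounder_screen <- function(grs, cohort, factors = NULL) {
  factors <- factors %||% intersect(
    c("bmi", "smoking", "family_history", "aspirin_use", "education",
      "mht_combined", "mht_estrogen_only"),
    names(cohort))
  assert_that(length(factors) > 0, "no screenable factors found")
  ctrl <- cohort[cohort$case_status == "control", , drop = FALSE]
  dat <- dplyr::inner_join(ctrl, grs[, c("individual_id",
                                         intersect("scaled", names(grs)),
                                         "raw")],
                           by = "individual_id")
  dat$grs <- if ("scaled" %in% names(dat)) dat$scaled else dat$raw

  rows <- lapply(factors, function(fc) {
    v <- dat[[fc]]
    keep <- !is.na(v) & v != "missing" & !is.na(dat$grs)
    v <- v[keep]
    g <- dat$grs[keep]
    n <- length(v)
    if (n < 10 || length(unique(v)) < 2) {
      return(tibble(risk_factor = fc, model = NA_character_,
                    estimate = NA_real_, pvalue = NA_real_, n = n,
                    flagged = TRUE))
    }
    if (is.numeric(v)) {
      fit <- lm(v ~ g)
      sm <- summary(fit)$coefficients
      tibble(risk_factor = fc, model = "linear",
             estimate = sm["g", "Estimate"],
             pvalue = sm["g", "Pr(>|t|)"], n = n, flagged = FALSE)
    } else if (length(unique(v)) == 2) {
      y <- as.integer(factor(v)) - 1L
      fit <- glm(y ~ g, family = stats::binomial())
      sm <- summary(fit)$coefficients
      tibble(risk_factor = fc, model = "logistic",
             estimate = sm["g", "Estimate"],
             pvalue = sm["g", "Pr(>|z|)"], n = n, flagged = FALSE)
    } else {
      full <- nnet::multinom(factor(v) ~ g, trace = FALSE)
      null <- nnet::multinom(factor(v) ~ 1, trace = FALSE)
      lr <- null$deviance - full$deviance
      df <- length(unique(v)) - 1
      tibble(risk_factor = fc, model = "multinomial", estimate = NA_real_,
             pvalue = pchisq(lr, df = df, lower.tail = FALSE), n = n,
             flagged = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Power of the GRS instrument Wald test
#'
#' Analytic mode uses the normal approximation for a two-sided Wald test of
#' a single genetic score instrument on a binary outcome:
#' `power = Phi(|log OR| sqrt(N R^2 phi (1 - phi)) - z) +
#'          Phi(-|log OR| sqrt(N R^2 phi (1 - phi)) - z)`
#' with `phi` the case fraction and `z` the two-sided critical value; at the
#' null it reduces exactly to `alpha`. Simulation mode draws replicate
#' score-outcome cohorts at the requested sizes — standard-normal score, an
#' exposure of which the score explains `r2`, logistic disease risk at
#' `or_per_sd` per SD of exposure, retrospective sampling to exact counts —
#' and reports the rejection fraction of the score's Wald test.
#'
#' @param n_cases,n_controls Case and control counts.
#' @param r2 Variance of the exposure explained by the instrument, in (0,1).
#' @param or_per_sd Detectable odds ratio per SD of exposure (> 0).
#' @param alpha Two-sided significance level, in (0, 0.5); default 0.05.
#' @param method `"analytic"` (default) or `"simulation"`.
#' @param n_reps Simulation replicates (at least 500; default 2000).
#' @param seed Seed for simulation mode.
#' @return Power as a fraction in [0, 1].
#' @export
mr_power <- function(n_cases, n_controls, r2, or_per_sd, alpha = 0.05,
                     method = c("analytic", "simulation"), n_reps = 2000,
                     seed = NULL) {
  method <- match.arg(method)
  assert_that(is_count(n_cases) && is_count(n_controls),
              "`n_cases` and `n_controls` must be counts")
  assert_that(is_fraction(r2), "`r2` must be in (0,1)")
  assert_that(or_per_sd > 0, "`or_per_sd` must be > 0")
  assert_that(is_fraction(alpha, hi = 0.5), "`alpha` must be in (0, 0.5)")
  N <- n_cases + n_controls
  phi <- n_cases / N
  if (method == "analytic") {
    z <- qnorm(1 - alpha / 2)
    shift <- abs(log(or_per_sd)) * sqrt(N * r2 * phi * (1 - phi))
    return(pnorm(shift - z) + pnorm(-shift - z))
  }
  assert_that(is_count(n_reps) && n_reps >= 500,
              "simulation mode needs `n_reps` >= 500")
  assert_that(!is.null(seed), "simulation mode needs a `seed`")
  b <- log(or_per_sd)
  with_seed(seed, {
    rejections <- vapply(seq_len(n_reps), function(r) {
      pool <- ceiling(2.3 * max(n_cases, n_controls))
      s <- rnorm(pool)
      x <- sqrt(r2) * s + sqrt(1 - r2) * rnorm(pool)
      case <- rbinom(pool, 1L, plogis(b * x)) == 1L
      n_case_pool <- sum(case)
      if (n_case_pool < n_cases || pool - n_case_pool < n_controls) {
        return(NA) # counted as failure to draw; practically unreachable
      }
      sel <- c(sample(which(case), n_cases), sample(which(!case), n_controls))
      y <- rep(c(1L, 0L), c(n_cases, n_controls))
      fit <- suppressWarnings(
        glm.fit(cbind(1, s[sel]), y, family = stats::binomial(),
                control = glm.control(epsilon = 1e-8, maxit = 50)))
      cf <- fit$coefficients[2]
      # Wald se from the IRLS weights
      X <- cbind(1, s[sel])
      W <- fit$weights
      V <- solve(crossprod(X * sqrt(W)))
      zstat <- cf / sqrt(V[2, 2])
      abs(zstat) > qnorm(1 - alpha / 2)
    }, logical(1))
    mean(rejections, na.rm = TRUE)
  })
}
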