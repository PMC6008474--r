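#' Weighted genetic risk scores
#'
#' A genetic risk score (GRS) is the plain weighted sum of imputed allele
#' doses, `raw_k = sum_n beta_n G_kn`, over the instrument SNPs; it is not
#' divided by the SNP count. Raw scores are converted to year units by
#' dividing by a calibration constant, the reciprocal of the first-stage
#' slope of self-reported age on the raw score (defaults 0.57 for menarche,
#' 0.98 for menopause); the scaled score is then the predicted exposure in
#' years, and logistic odds ratios on it read as risk change per year of
#' exposure.
#'
#' @name grs
NULL

DEFAULT_SCALING_BETA <- c(menarche = 0.57, menopause = 0.98)

#' Compute a raw weighted genetic risk score
#'
#' Missing dosages are mean-imputed per SNP (from controls when a control
#' mask is given, the standard GRS practice, unbiased under missingness at
#' random), or raise an error in `missing = "error"` mode. If the dosage
#' matrix carries an `effect_alleles` attribute (as written by
#' [generate_cohort()] and [read_dosages()]), instruments whose effect allele
#' is the complementary coding are counted as `2 - G`, making the score
#' invariant to allele recoding.
#'
#' @param dosages Dosage tibble: `individual_id` plus one column per rsid.
#' @param instruments Instrument manifest; every rsid must be a dosage
#'   column.
#' @param missing `"mean_impute"` (default) or `"error"`.
#' @param controls Optional logical vector marking controls, used for mean
#'   imputation.
#' @return A `grs_vector`: tibble with `individual_id` and `raw`; attributes
#'   `trait` and `n_snps`.
#' @export
compute_grs <- function(dosages, instruments,
                        missing = c("mean_impute", "error"), controls = NULL) {
  missing <- match.arg(missing)
  instruments <- validate_manifest(instruments, "instruments")
  absent <- setdiff(instruments$rsid, names(dosages))
  if (length(absent)) {
    stop_repromr(paste0("instrument(s) absent from dosage matrix: ",
                        paste(absent, collapse = ", ")),
                 "repromr_missing_column")
  }
  mat <- as.matrix(dosages[instruments$rsid])
  assert_that(all(mat >= 0 & mat <= 2, na.rm = TRUE),
              "dosages must lie in [0, 2]")
  if (anyNA(mat)) {
    if (missing == "error") {
      stop_repromr("missing dosage values with missing = \"error\"",
                   "repromr_missing_dosage")
    }
    ref <- if (is.null(controls)) rep(TRUE, nrow(mat)) else controls
    fill <- colMeans(mat[ref, , drop = FALSE], na.rm = TRUE)
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- fill[idx[, 2]]
  }
  beta <- instruments$beta
  coding <- attr(dosages, "effect_alleles", exact = TRUE)
  if (!is.null(coding)) {
    known <- intersect(instruments$rsid, names(coding))
    flipped <- known[coding[known] != instruments$effect_allele[
      match(known, instruments$rsid)]]
    if (length(flipped)) {
      j <- match(flipped, instruments$rsid)
      mat[, j] <- 2 - mat[, j]
    }
  }
  out <- tibble(individual_id = dosages$individual_id,
                raw = as.vector(mat %*% beta))
  attr(out, "trait") <- unique(instruments$trait)[1]
  attr(out, "n_snps") <- nrow(instruments)
  class(out) <- c("grs_vector", class(out))
  out
}

#' Fit the year-scaling calibration regression
#'
#' Per study, the first-stage ordinary least squares of self-reported age
#' (years) on the raw GRS is fitted; the scaling beta is the reciprocal of
#' that slope (delta-method standard error), so that dividing the raw score
#' by it yields the predicted exposure in years — the two-stage
#' least-squares construction under which the logistic coefficient of the
#' scaled score is the causal log odds ratio per year. For perfectly
#' calibrated GWAS weights the scaling beta is 1; the published values are
#' 0.57 (menarche) and 0.98 (menopause). Per-study betas are pooled by
#' inverse-variance fixed-effects meta-analysis. Studies with fewer than
#' `min_n` complete pairs or with degenerate variance are dropped with a
#' warning.
#'
#' @param grs A `grs_vector` (or tibble with a `raw` column).
#' @param age Self-reported exposure age, years (may contain `NA`).
#' @param study Optional study labels; `NULL` treats the data as one study.
#' @param min_n Minimum complete pairs per study (default 30).
#' @return A `scaling_fit`: list with `per_study` tibble (study, beta, se,
#'   n) and `pooled` tibble (beta, se).
#' @export
fit_scaling <- function(grs, age, study = NULL, min_n = 30) {
  raw <- if (is.data.frame(grs)) grs$raw else grs
  assert_that(!is.null(raw), "`grs` must carry a `raw` column")
  assert_that(length(age) == length(raw), "`age` must match `grs` length")
  study <- study %||% rep("all", length(raw))
  ok <- stats::complete.cases(raw, age)
  dat <- tibble(raw = raw[ok], age = age[ok], study = study[ok])

  fits <- dat |>
    dplyr::group_by(.data$study) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < min_n) {
        warn(paste0("study ", key$study, " excluded: fewer than ", min_n,
                    " complete (score, age) pairs"))
        return(NULL)
      }
      if (stats::var(d$age) == 0 || stats::var(d$raw) == 0) {
        warn(paste0("study ", key$study, " excluded: degenerate variance"))
        return(NULL)
      }
      fit <- lm(age ~ raw, data = d)
      k <- unname(coef(fit)["raw"])
      se_k <- summary(fit)$coefficients["raw", "Std. Error"]
      if (abs(k) < 4 * se_k) {
        warn(paste0("study ", key$study,
                    " excluded: first-stage slope indistinguishable from zero"))
        return(NULL)
      }
      # scaling beta = 1 / first-stage slope, delta-method se
      tibble(study = key$study, beta = 1 / k, se = se_k / k^2, n = nrow(d))
    }) |>
    dplyr::bind_rows()
  assert_that(nrow(fits) > 0, "no study provided usable calibration data",
              class = "repromr_scaling_error")

  w <- 1 / fits$se^2
  pooled <- tibble(beta = sum(w * fits$beta) / sum(w), se = 1 / sqrt(sum(w)))
  structure(list(per_study = fits, pooled = pooled), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit> pooled beta =", signif(x$pooled$beta, 4),
      "( se", signif(x$pooled$se, 3), ") from", nrow(x$per_study), "study(ies)\n")
  invisible(x)
}

#' Scale a raw GRS into year units
#'
#' Divides the raw score by the scaling slope. Supply a number, a
#' [fit_scaling()] result (its pooled slope is used), or nothing — in which
#' case the trait's default calibration constant applies (0.57 menarche,
#' 0.98 menopause).
#'
#' @param grs A `grs_vector` with a `raw` column.
#' @param scaling_beta Scalar, `scaling_fit`, or `NULL` for the trait
#'   default.
#' @return The `grs_vector` with a `scaled` column (years) and attribute
#'   `scaling_beta`.
#' @export
scale_grs <- function(grs, scaling_beta = NULL) {
  assert_that(is.data.frame(grs) && "raw" %in% names(grs),
              "`grs` must carry a `raw` column")
  if (inherits(scaling_beta, "scaling_fit")) {
    scaling_beta <- scaling_beta$pooled$beta
  }
  if (is.null(scaling_beta)) {
    trait <- attr(grs, "trait", exact = TRUE) %||% ""
    scaling_beta <- unname(DEFAULT_SCALING_BETA[trait])
    if (is.na(scaling_beta)) {
      stop_repromr("no default scaling beta for this trait; supply `scaling_beta`",
                   "repromr_scaling_error")
    }
  }
  assert_that(is.numeric(scaling_beta) && length(scaling_beta) == 1 &&
                scaling_beta != 0, "`scaling_beta` must be a nonzero scalar",
              class = "repromr_scaling_error")
  grs$scaled <- grs$raw / scaling_beta
  attr(grs, "scaling_beta") <- scaling_beta
  grs
}

#' Combine scaled scores into the lifetime-exposure score
#'
#' Elementwise sum of the scaled menarche score (built from the instrument
#' set re-harmonised to menarche-decreasing alleles) and the scaled menopause
#' score; higher values mean longer endogenous oestrogen exposure.
#'
#' @param menarche_scaled,menopause_scaled `grs_vector`s with `scaled`
#'   columns over the same individuals in the same order.
#' @return A `grs_vector` with trait `"lifetime"`.
#' @export
lifetime_grs <- function(menarche_scaled, menopause_scaled) {
  assert_that(all(c("individual_id", "scaled") %in% names(menarche_scaled)) &&
                all(c("individual_id", "scaled") %in% names(menopause_scaled)),
              "both components must be scaled grs_vectors")
  assert_that(nrow(menarche_scaled) == nrow(menopause_scaled),
              "component length mismatch")
  assert_that(all(menarche_scaled$individual_id ==
                    menopause_scaled$individual_id),
              "components must cover the same individuals in the same order")
  out <- tibble(individual_id = menarche_scaled$individual_id,
                raw = menarche_scaled$raw + menopause_scaled$raw,
                scaled = menarche_scaled$scaled + menopause_scaled$scaled)
  attr(out, "trait") <- "lifetime"
  attr(out, "n_snps") <- sum(attr(menarche_scaled, "n_snps") %||% NA,
                             attr(menopause_scaled, "n_snps") %||% NA)
  class(out) <- c("grs_vector", class(out))
  out
}
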