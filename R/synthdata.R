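#' Synthetic cohorts for reproductive-timing Mendelian randomisation
#'
#' The generator emulates the statistical structure of a female case-control
#' colorectal-cancer consortium with genetic instruments for age at menarche
#' and age at menopause: a manifest of GWAS instruments with curation flags,
#' imputed allele-dosage matrices, a phenotype/covariate table with exact
#' case/control counts, and two-sample summary statistics. Every stochastic
#' operation takes an explicit seed and leaves the global RNG untouched.
#'
#' @name synthdata
NULL

# study-condition defaults per trait: exposure mean/SD (years), explained
# variance of the instrument, and the year-scaling slope the first-stage
# regression should recover
TRAIT_DEFAULTS <- list(
  menarche  = list(mean = 13, sd = 1.5, r2 = 0.069, scaling_beta = 0.57),
  menopause = list(mean = 50, sd = 4.8, r2 = 0.057, scaling_beta = 0.98)
)

#' Simulation specification
#'
#' Bundles the parameters of one synthetic case-control cohort. Defaults are
#' the conditions of the motivating consortium analysis: 12,944 cases and
#' 10,741 controls, a 358-SNP menarche instrument explaining R-squared 0.069
#' of a 1.5-year-SD exposure, no causal effect on disease, BMI acting weakly
#' on both exposure and disease, and 26 contributing studies.
#'
#' @param n_cases,n_controls Exact case and control counts.
#' @param n_snps Number of instrument SNPs.
#' @param target_r2 Variance of the exposure explained by the true genetic
#'   score, in (0, 1).
#' @param causal_logor_per_year Log odds ratio on disease per year of
#'   exposure (0 = no causal effect).
#' @param exposure_mean_years,exposure_sd_years Exposure distribution.
#' @param bmi_on_exposure Years of exposure per kg/m2 of BMI (confounder path
#'   into the exposure; default -0.05, earlier menarche with higher childhood
#'   BMI).
#' @param bmi_on_disease Log odds of disease per kg/m2 (default 0.02).
#' @param pleiotropy_frac Fraction of SNPs with direct disease effects.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-allele direct
#'   log-odds effects (mean 0 = balanced, nonzero = directional).
#' @param n_studies Number of study labels.
#' @param trait `"menarche"`, `"menopause"` or `"lifetime"`.
#' @param seed Integer seed; mandatory.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cases = 12944, n_controls = 10741,
                            n_snps = 358, target_r2 = 0.069,
                            causal_logor_per_year = 0,
                            exposure_mean_years = 13,
                            exposure_sd_years = 1.5,
                            bmi_on_exposure = -0.05, bmi_on_disease = 0.02,
                            pleiotropy_frac = 0, pleiotropy_mean = 0,
                            pleiotropy_sd = 0,
                            n_studies = 26, trait = "menarche", seed) {
  assert_that(is_count(n_cases) && is_count(n_controls) && is_count(n_snps),
              "`n_cases`, `n_controls`, `n_snps` must be counts >= 1")
  assert_that(is_fraction(target_r2), "`target_r2` must be in (0,1)")
  assert_that(is_fraction(pleiotropy_frac, open = FALSE),
              "`pleiotropy_frac` must be in [0,1]")
  assert_that(exposure_sd_years > 0, "`exposure_sd_years` must be > 0")
  assert_that(is_count(n_studies), "`n_studies` must be a count")
  assert_that(!missing(seed) && is_count(abs(seed) + 1),
              "`seed` is mandatory")
  spec <- list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
               target_r2 = target_r2,
               causal_logor_per_year = causal_logor_per_year,
               exposure_mean_years = exposure_mean_years,
               exposure_sd_years = exposure_sd_years,
               bmi_on_exposure = bmi_on_exposure,
               bmi_on_disease = bmi_on_disease,
               pleiotropy_frac = pleiotropy_frac,
               pleiotropy_mean = pleiotropy_mean,
               pleiotropy_sd = pleiotropy_sd,
               n_studies = n_studies, trait = trait, seed = as.integer(seed))
  structure(spec, class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec>", x$n_cases, "cases /", x$n_controls, "controls,",
      x$n_snps, "SNPs, R2 =", x$target_r2, ", log-OR/year =",
      x$causal_logor_per_year, ", seed =", x$seed, "\n")
  invisible(x)
}

default_score_sd <- function(trait) {
  # first-stage slope of exposure on score is 1/scaling_beta, so the score SD
  # that reproduces the published calibration is sqrt(R2) * sd * scaling_beta
  d <- TRAIT_DEFAULTS[[trait]] %||% TRAIT_DEFAULTS$menarche
  sqrt(d$r2) * d$sd * d$scaling_beta
}

#' Generate an instrument manifest with curation flags
#'
#' Draws `n_total` GWAS-style instrument records for one trait: allele
#' frequencies in [0.05, 0.95], genome-wide-significant p-values, per-allele
#' betas (years) scaled so the theoretical score SD matches field-realistic
#' magnitudes, and curation flags reproducing the published accounting:
#' `n_sex_chr` variants on sex chromosomes, `n_missing` variants absent from
#' the genotype data of which `n_no_proxy` have no qualifying proxy, and
#' `n_correlated` correlated pairs (each pair loses its higher-p member at
#' pruning). [curate_instruments()] on the result therefore leaves
#' `n_total - n_sex_chr - n_no_proxy - n_correlated` records.
#'
#' @param n_total Total records.
#' @param n_sex_chr Records on sex chromosomes.
#' @param n_missing Records absent from genotype data (need a proxy).
#' @param n_no_proxy Of those, records with no qualifying proxy.
#' @param n_correlated Number of correlated pairs (r-squared > 0.01).
#' @param seed Integer seed.
#' @param trait `"menarche"` or `"menopause"`.
#' @param target_score_sd Theoretical SD (years) of the true weighted score;
#'   defaults to the trait's study value.
#' @return Manifest tibble; the companion proxy and LD tables are recoverable
#'   via [manifest_proxy_table()] and [manifest_ld_table()].
#' @export
generate_manifest <- function(n_total, n_sex_chr = 0, n_missing = 0,
                              n_no_proxy = 0, n_correlated = 0, seed,
                              trait = "menarche", target_score_sd = NULL) {
  assert_that(is_count(n_total), "`n_total` must be a count >= 1")
  ok_counts <- n_sex_chr >= 0 && n_missing >= 0 && n_no_proxy >= 0 &&
    n_correlated >= 0 && n_no_proxy <= n_missing && n_missing <= n_total &&
    n_sex_chr + n_correlated <= n_total &&
    n_sex_chr + n_missing + 2 * n_correlated <= n_total
  assert_that(ok_counts, "inconsistent curation counts",
              class = "repromr_invalid_counts")
  target_score_sd <- target_score_sd %||% default_score_sd(trait)

  with_seed(seed, {
    prefix <- if (trait == "menopause") "rs2" else "rs1"
    rsid <- sprintf("%s%06d", prefix, seq_len(n_total))
    eaf <- runif(n_total, 0.05, 0.95)
    pvalue <- 10^runif(n_total, -30, -7.31) # all genome-wide significant
    alleles <- t(vapply(seq_len(n_total),
                        function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))
    beta_raw <- abs(rnorm(n_total))
    # calibrate betas so the theoretical score SD hits the target
    vg <- sum(beta_raw^2 * 2 * eaf * (1 - eaf))
    beta <- beta_raw * target_score_sd / sqrt(vg)
    z <- qnorm(pvalue / 2, lower.tail = FALSE)
    se <- beta / z

    manifest <- tibble(
      rsid = rsid,
      chrom = as.character(sample(1:22, n_total, replace = TRUE)),
      pos = sample.int(2.4e8, n_total),
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta, se = se, pvalue = pvalue, trait = trait,
      sex_chromosome = FALSE, needs_proxy = FALSE,
      proxy_rsid = NA_character_, proxy_r2 = NA_real_,
      correlated_partner = NA_character_, pair_r2 = NA_real_,
      bmi_associated = FALSE
    )

    idx <- sample.int(n_total) # random, disjoint flag assignment
    sex_idx <- head(idx, n_sex_chr); idx <- setdiff(idx, sex_idx)
    miss_idx <- head(idx, n_missing); idx <- setdiff(idx, miss_idx)
    manifest$sex_chromosome[sex_idx] <- TRUE
    manifest$chrom[sex_idx] <- "X"
    manifest$needs_proxy[miss_idx] <- TRUE
    with_proxy <- head(miss_idx, n_missing - n_no_proxy)
    manifest$proxy_rsid[with_proxy] <- paste0(manifest$rsid[with_proxy], "p")
    manifest$proxy_r2[with_proxy] <- runif(length(with_proxy), 0.83, 1)
    if (n_correlated > 0) {
      pair_idx <- matrix(head(idx, 2 * n_correlated), ncol = 2)
      a <- pair_idx[, 1]; b <- pair_idx[, 2]
      manifest$correlated_partner[a] <- manifest$rsid[b]
      manifest$correlated_partner[b] <- manifest$rsid[a]
      r2p <- runif(n_correlated, 0.02, 0.95)
      manifest$pair_r2[a] <- r2p
      manifest$pair_r2[b] <- r2p
    }
    harmonise_instruments(manifest)
  })
}

# population-level genotype draw for one manifest, with imputation-style
# shrink of hard calls toward 2*eaf (per-SNP quality in [0.9, 1])
draw_dosages <- function(n, manifest, impute_noise = TRUE) {
  J <- nrow(manifest)
  G <- matrix(rbinom(n * J, 2L, rep(manifest$eaf, each = n)), nrow = n)
  colnames(G) <- manifest$rsid
  if (impute_noise) {
    q <- runif(J, 0.9, 1)
    G <- sweep(G, 2, q, `*`) +
      matrix(rep((1 - q) * 2 * manifest$eaf, each = n), nrow = n)
  }
  G
}

#' Generate a synthetic case-control cohort
#'
#' Simulates a population in which the exposure (age at menarche or
#' menopause, years) is the manifest-weighted allele score plus a BMI
#' confounder term and a residual calibrated so the empirical R-squared of
#' the true score on the exposure matches `spec$target_r2`; disease status
#' follows a logistic model with `causal_logor_per_year` per year of
#' exposure, the BMI effect, and per-allele direct (pleiotropic) effects for
#' a random SNP subset. Cases and controls are then sampled retrospectively
#' to the exact requested counts (logistic odds ratios are invariant to
#' outcome-dependent sampling). If the manifest carries both menarche and
#' menopause records, both exposures are generated and the causal effect
#' applies per year of the exposure window (menopause age minus menarche
#' age).
#'
#' @param spec A [simulation_spec()].
#' @param manifest Instrument manifest (curated; used as-is).
#' @param impute_noise Mimic imputation by shrinking integer dosages toward
#'   2 x frequency with per-SNP quality in [0.9, 1]? Default `TRUE` (mean
#'   observed quality ~0.97, as in the consortium data).
#' @return A `synthetic_dataset`: list with `manifest`, `dosages` (tibble,
#'   attribute `effect_alleles` recording the dosage allele coding), `cohort`
#'   and `true_params`.
#' @export
generate_cohort <- function(spec, manifest, impute_noise = TRUE) {
  assert_that(inherits(spec, "simulation_spec"), "`spec` must be a simulation_spec")
  manifest <- validate_manifest(manifest)
  assert_that(nrow(manifest) > 0, "`manifest` must be non-empty")

  trait_col <- manifest[["source_trait"]] %||% manifest$trait
  two_traits <- all(c("menarche", "menopause") %in% trait_col)
  if (!two_traits) trait_col <- manifest$trait

  n_need <- c(cases = spec$n_cases, controls = spec$n_controls)
  with_seed(spec$seed, {
    bmi_mean <- 26; bmi_sd <- 4.5

    exposure_part <- function(rows, G, mean_y, sd_y, r2) {
      beta <- manifest$beta[rows]
      f <- manifest$eaf[rows]
      mu_g <- sum(beta * 2 * f)
      var_g <- sum(beta^2 * 2 * f * (1 - f))
      assert_that(var_g > 0, "all-zero instrument weights",
                  class = "repromr_calibration_error")
      k <- sqrt(r2) * sd_y / sqrt(var_g)
      resid_var <- sd_y^2 * (1 - r2) - (spec$bmi_on_exposure * bmi_sd)^2
      assert_that(resid_var > 0,
                  "target_r2 unreachable: confounder variance exceeds residual budget",
                  class = "repromr_calibration_error")
      score <- as.vector(G[, manifest$rsid[rows], drop = FALSE] %*% beta)
      list(k = k, mu_g = mu_g, score = score, resid_sd = sqrt(resid_var),
           mean_y = mean_y)
    }

    # pleiotropic SNP subset and direct effects, fixed once per dataset
    J <- nrow(manifest)
    n_pleio <- round(spec$pleiotropy_frac * J)
    pleio_idx <- if (n_pleio > 0) sample.int(J, n_pleio) else integer()
    delta <- numeric(J)
    if (n_pleio > 0) {
      delta[pleio_idx] <- rnorm(n_pleio, spec$pleiotropy_mean, spec$pleiotropy_sd)
    }

    chunks <- list()
    chunk <- ceiling(2.4 * max(n_need))
    tries <- 0
    n_case_pool <- 0; n_ctrl_pool <- 0
    repeat {
      tries <- tries + 1
      assert_that(tries <= 8, "could not reach requested case/control counts",
                  class = "repromr_calibration_error")
      Ghard <- matrix(rbinom(chunk * J, 2L, rep(manifest$eaf, each = chunk)),
                      nrow = chunk, dimnames = list(NULL, manifest$rsid))
      bmi <- rnorm(chunk, bmi_mean, bmi_sd)

      if (two_traits) {
        mena <- exposure_part(which(trait_col == "menarche"), Ghard,
                              TRAIT_DEFAULTS$menarche$mean,
                              TRAIT_DEFAULTS$menarche$sd, spec$target_r2)
        meno <- exposure_part(which(trait_col == "menopause"), Ghard,
                              TRAIT_DEFAULTS$menopause$mean,
                              TRAIT_DEFAULTS$menopause$sd,
                              TRAIT_DEFAULTS$menopause$r2)
        # menarche manifest rows are coded on the decreasing allele, so the
        # weighted score *reduces* menarche age
        x_mena <- mena$mean_y - mena$k * (mena$score - mena$mu_g) +
          spec$bmi_on_exposure * (bmi - bmi_mean) +
          rnorm(chunk, 0, mena$resid_sd)
        x_meno <- meno$mean_y + meno$k * (meno$score - meno$mu_g) +
          rnorm(chunk, 0, meno$resid_sd)
        x_causal <- x_meno - x_mena # exposure window, years
        x_center <- TRAIT_DEFAULTS$menopause$mean - TRAIT_DEFAULTS$menarche$mean
      } else {
        part <- exposure_part(seq_len(J), Ghard, spec$exposure_mean_years,
                              spec$exposure_sd_years, spec$target_r2)
        x_mena <- x_meno <- NULL
        x_causal <- part$mean_y + part$k * (part$score - part$mu_g) +
          spec$bmi_on_exposure * (bmi - bmi_mean) +
          rnorm(chunk, 0, part$resid_sd)
        x_center <- part$mean_y
      }

      eta <- spec$causal_logor_per_year * (x_causal - x_center) +
        spec$bmi_on_disease * (bmi - bmi_mean) +
        if (n_pleio > 0) as.vector(Ghard %*% delta) else 0
      case <- rbinom(chunk, 1L, plogis(eta)) == 1L

      chunks[[tries]] <- list(
        G = Ghard, case = case, bmi = bmi, x_causal = x_causal,
        x_mena = x_mena %||% rep(NA_real_, chunk),
        x_meno = x_meno %||% rep(NA_real_, chunk)
      )
      n_case_pool <- n_case_pool + sum(case)
      n_ctrl_pool <- n_ctrl_pool + sum(!case)
      if (n_case_pool >= n_need["cases"] && n_ctrl_pool >= n_need["controls"]) {
        break
      }
      chunk <- chunk * 2
    }

    pool_case <- unlist(lapply(chunks, `[[`, "case"))
    sel <- c(sample(which(pool_case), n_need["cases"]),
             sample(which(!pool_case), n_need["controls"]))
    pull_pool <- function(field) unlist(lapply(chunks, `[[`, field))[sel]
    take <- tibble(case = pool_case[sel], bmi = pull_pool("bmi"),
                   x_causal = pull_pool("x_causal"),
                   x_mena = pull_pool("x_mena"),
                   x_meno = pull_pool("x_meno"))
    n <- nrow(take)
    Gsel <- do.call(rbind, lapply(chunks, `[[`, "G"))[sel, , drop = FALSE]
    rm(chunks)

    if (impute_noise) {
      q <- runif(J, 0.9, 1)
      Gsel <- sweep(Gsel, 2, q, `*`) +
        matrix(rep((1 - q) * 2 * manifest$eaf, each = n), nrow = n)
    }

    ids <- sprintf("id%06d", seq_len(n))
    study_labels <- sprintf("study%02d", seq_len(spec$n_studies))
    study <- sample(study_labels, n, replace = TRUE)
    consortium <- ifelse(match(study, study_labels) <= ceiling(spec$n_studies / 2),
                         "GECCO", "CORECT")
    is_case <- take$case
    site <- ifelse(is_case,
                   sample(c("colon", "rectum"), n, replace = TRUE,
                          prob = c(0.773, 0.227)),
                   "none")
    menop_status <- sample(c("pre", "post", "missing"), n, replace = TRUE,
                           prob = c(0.09, 0.86, 0.05))
    mht_lvls <- c("ever", "never", "missing")
    mht_combined <- ifelse(menop_status == "post",
                           sample(mht_lvls, n, replace = TRUE,
                                  prob = c(0.17, 0.73, 0.10)), "never")
    mht_estrogen <- ifelse(menop_status == "post",
                           sample(mht_lvls, n, replace = TRUE,
                                  prob = c(0.22, 0.68, 0.10)), "never")
    bmi_cat <- cut(take$bmi, c(-Inf, 18.5, 25, 30, Inf),
                   labels = c("underweight", "normal", "overweight", "obese"),
                   right = FALSE)
    self_mena <- if (two_traits) take$x_mena else {
      if (spec$trait == "menarche") take$x_causal else
        rnorm(n, TRAIT_DEFAULTS$menarche$mean, TRAIT_DEFAULTS$menarche$sd)
    }
    self_meno <- if (two_traits) take$x_meno else {
      if (spec$trait == "menopause") take$x_causal else
        rnorm(n, TRAIT_DEFAULTS$menopause$mean, TRAIT_DEFAULTS$menopause$sd)
    }

    cohort <- tibble(
      individual_id = ids,
      case_status = ifelse(is_case, "case", "control"),
      site = site,
      age = round(pmin(pmax(rnorm(n, 64, 8), 30), 90)),
      study = study, consortium = consortium,
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
      bmi = take$bmi, bmi_category = as.character(bmi_cat),
      mht_combined = mht_combined, mht_estrogen_only = mht_estrogen,
      menopausal_status = menop_status,
      self_reported_menarche = self_mena,
      self_reported_menopause = self_meno,
      aspirin_use = sample(c("ever", "never"), n, TRUE, prob = c(0.35, 0.65)),
      smoking = sample(c("ever", "never"), n, TRUE, prob = c(0.45, 0.55)),
      family_history = sample(c("yes", "no"), n, TRUE, prob = c(0.12, 0.88)),
      education = sample(c("basic", "secondary", "tertiary"), n, TRUE,
                         prob = c(0.35, 0.4, 0.25))
    )

    dosages <- dplyr::bind_cols(tibble(individual_id = ids),
                                as_tibble(as.data.frame(Gsel)))
    attr(dosages, "effect_alleles") <-
      setNames(manifest$effect_allele, manifest$rsid)

    structure(list(manifest = manifest, dosages = dosages, cohort = cohort,
                   true_params = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", nrow(x$cohort), "individuals (",
      sum(x$cohort$case_status == "case"), "cases ),",
      nrow(x$manifest), "SNPs\n")
  invisible(x)
}

#' Generate two-sample MR summary statistics
#'
#' Per-SNP exposure betas and SEs are taken from the manifest; outcome
#' (log-odds per allele) betas are the ratio-implied values — causal effect
#' per year times the exposure beta, plus any direct pleiotropic effect —
#' with normal noise at outcome SEs sized for a case-control GWAS of
#' `spec$n_cases + spec$n_controls` individuals.
#'
#' @param manifest Instrument manifest.
#' @param spec A [simulation_spec()]; supplies the causal effect, pleiotropy
#'   settings, sample sizes and seed.
#' @return Tibble with `rsid`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`; attribute `delta` records the simulated
#'   direct effects.
#' @export
generate_summary_stats <- function(manifest, spec) {
  manifest <- validate_manifest(manifest)
  assert_that(nrow(manifest) > 0, "`manifest` must be non-empty")
  assert_that(inherits(spec, "simulation_spec"), "`spec` must be a simulation_spec")
  with_seed(derive_seed(spec$seed, 7L), {
    J <- nrow(manifest)
    N <- spec$n_cases + spec$n_controls
    phi <- spec$n_cases / N
    se_out <- 1 / sqrt(2 * manifest$eaf * (1 - manifest$eaf) * N * phi * (1 - phi))
    n_pleio <- round(spec$pleiotropy_frac * J)
    delta <- numeric(J)
    if (n_pleio > 0) {
      delta[sample.int(J, n_pleio)] <-
        rnorm(n_pleio, spec$pleiotropy_mean, spec$pleiotropy_sd)
    }
    by <- rnorm(J, spec$causal_logor_per_year * manifest$beta + delta, se_out)
    out <- tibble(rsid = manifest$rsid, beta_exposure = manifest$beta,
                  se_exposure = manifest$se, beta_outcome = by,
                  se_outcome = se_out)
    attr(out, "delta") <- delta
    out
  })
}
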