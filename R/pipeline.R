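#' Pipeline orchestration
#'
#' [run_config()] assembles and validates the configuration of a full
#' analysis run; [run_pipeline()] executes it: curation, genotype QC, GRS
#' construction and year-scaling, the one-sample MR fit with BMI sensitivity
#' variants, stratified analyses, two-sample estimators, diagnostics
#' (F-statistic, confounder screen, Egger intercept, funnel data) and the
#' power section. Every stage is a pure function of (inputs, config, seed);
#' errors are rethrown with the stage name attached.
#'
#' @name pipeline
NULL

resolve_input <- function(x, reader, what, stage) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (!file.exists(x)) {
      stop_repromr(paste0("stage ", stage, ": input file for ", what,
                          " not found: ", x),
                   "repromr_config_error")
    }
    return(reader(x))
  }
  x
}

#' Assemble a pipeline configuration
#'
#' Inputs may be in-memory tibbles or file paths (read with the matching
#' [io] reader at run time).
#'
#' @param manifest Instrument manifest (tibble or TSV path). Curation flags,
#'   proxies and LD may be encoded in it (see [generate_manifest()]).
#' @param dosages Dosage matrix (tibble or TSV path); `NULL` skips all
#'   one-sample stages.
#' @param cohort Cohort table (tibble or CSV path); required with
#'   `dosages`.
#' @param proxies,ld Optional proxy/LD tables (tibbles or TSV paths).
#' @param summary_stats Optional two-sample summary statistics (tibble or
#'   TSV path); `NULL` skips the two-sample stage.
#' @param trait Exposure trait label; also selects the default scaling beta.
#' @param scaling_beta Scalar year-scaling slope, `"fit"` to calibrate from
#'   the cohort's self-reported ages, or `NULL` for the trait default.
#' @param covariates Covariate selection for the one-sample fits.
#' @param strata Stratification columns for [stratified_analysis()].
#' @param bmi_grs Optional `grs_vector` used as an adjustment score.
#' @param restricted_exclude Optional rsids excluded for the restricted
#'   score (`NULL` uses the manifest's `bmi_associated` flags when present).
#' @param qc Logical: run [qc_genotypes()] before scoring? Default `TRUE`.
#' @param twosample List of two-sample settings: `methods`, `n_boot`.
#' @param power List with `r2` and `or_per_sd` (vector) for the power
#'   section, or `NULL` to skip.
#' @param seed Integer seed, mandatory.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest, dosages = NULL, cohort = NULL,
                       proxies = NULL, ld = NULL, summary_stats = NULL,
                       trait = "menarche", scaling_beta = NULL,
                       covariates = c("age", "study", "pcs"),
                       strata = character(), bmi_grs = NULL,
                       restricted_exclude = NULL, qc = TRUE,
                       twosample = list(methods = c("ivw", "egger",
                                                    "weighted_median"),
                                        n_boot = 10000),
                       power = NULL, seed) {
  assert_that(!missing(seed), "`seed` is mandatory",
              class = "repromr_config_error")
  assert_that(!is.null(manifest), "`manifest` is required",
              class = "repromr_config_error")
  if (!is.null(dosages)) {
    assert_that(!is.null(cohort), "`cohort` is required when `dosages` given",
                class = "repromr_config_error")
  }
  structure(list(manifest = manifest, dosages = dosages, cohort = cohort,
                 proxies = proxies, ld = ld, summary_stats = summary_stats,
                 trait = trait, scaling_beta = scaling_beta,
                 covariates = covariates, strata = strata, bmi_grs = bmi_grs,
                 restricted_exclude = restricted_exclude, qc = qc,
                 twosample = twosample, power = power,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "repromr_config_error")) stop(e)
    stop_repromr(paste0("stage ", stage, ": ", conditionMessage(e)),
                 "repromr_stage_error")
  })
}

#' Execute a configured analysis
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; results are written there as TSV and a
#'   machine-readable JSON bundle, together with a run manifest of input
#'   hashes and the seed.
#' @return An `mr_report` list: `main` (Table-1-shaped estimates),
#'   `stratified`, `diagnostics`, `power`, `scaling`, `session`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  assert_that(inherits(config, "run_config"), "`config` must come from run_config()")

  manifest <- stage_wrap("curate",
                         resolve_input(config$manifest, read_instruments,
                                       "manifest", "curate"))
  proxies <- resolve_input(config$proxies, read_proxy_table, "proxies", "curate")
  ld <- resolve_input(config$ld, read_ld_table, "ld", "curate")
  curated <- stage_wrap("curate",
                        curate_instruments(manifest, proxies = proxies, ld = ld))

  dosages <- resolve_input(config$dosages, read_dosages, "dosages", "qc")
  cohort <- resolve_input(config$cohort, read_cohort, "cohort", "qc")
  sstats <- resolve_input(config$summary_stats, read_summary_stats,
                          "summary_stats", "twosample")

  main <- list()
  strat <- list()
  diagnostics <- list()
  scaling <- NULL

  if (!is.null(dosages)) {
    controls <- cohort$case_status == "control"
    if (isTRUE(config$qc)) {
      qc_res <- stage_wrap("qc", qc_genotypes(dosages, controls))
      dosages <- qc_res$dosages
      diagnostics$qc_report <- qc_res$report
      curated <- curated[curated$rsid %in% names(dosages), , drop = FALSE]
    }
    stage_wrap("grs", {
      grs_raw <- compute_grs(dosages, curated, controls = controls)
      sb <- config$scaling_beta
      self_col <- paste0("self_reported_", config$trait)
      if (identical(sb, "fit") && self_col %in% names(cohort)) {
        scaling <- fit_scaling(grs_raw, cohort[[self_col]], cohort$study)
        sb <- scaling$pooled$beta
      }
      grs <- scale_grs(grs_raw, sb)
    })

    stage_wrap("mr1s", {
      main$grs <- fit_grs_logistic(cohort, grs, config$covariates)
      if (!is.null(config$bmi_grs)) {
        main$grs_bmi_adjusted <-
          fit_grs_logistic(cohort, grs, config$covariates,
                           extra_scores = config$bmi_grs)
        main$grs_bmi_adjusted$method <- "grs_bmi_adjusted"
      }
      restricted <- restrict_bmi_associated(curated, config$restricted_exclude)
      if (nrow(restricted) < nrow(curated) && nrow(restricted) > 0) {
        r_raw <- compute_grs(dosages, restricted, controls = controls)
        r_scaled <- scale_grs(r_raw, attr(grs, "scaling_beta"))
        main$grs_restricted <- fit_grs_logistic(cohort, r_scaled,
                                                config$covariates)
        main$grs_restricted$method <- "grs_restricted"
      }
    })

    stage_wrap("strata", {
      for (sv in config$strata) {
        strat[[sv]] <- stratified_analysis(cohort, grs, sv, config$covariates)
      }
      if ("site" %in% names(cohort) &&
          all(c("colon", "rectum") %in% cohort$site)) {
        diagnostics$site_case_only <-
          site_heterogeneity_case_only(cohort, grs, config$covariates)
      }
    })

    stage_wrap("validate", {
      diagnostics$confounder_screen <- confounder_screen(grs, cohort)
    })
  }

  if (!is.null(sstats)) {
    stage_wrap("mr2s", {
      ts <- config$twosample
      if ("ivw" %in% ts$methods) main$ivw <- mr_ivw(sstats)
      if ("egger" %in% ts$methods) main$egger <- mr_egger(sstats)
      if ("weighted_median" %in% ts$methods) {
        main$weighted_median <-
          mr_weighted_median(sstats, n_boot = ts$n_boot %||% 10000,
                             seed = derive_seed(config$seed, 11L))
      }
      diagnostics$funnel <- funnel_data(sstats)

    })
  }

  power_tab <- NULL
  if (!is.null(config$power)) {
    power_tab <- stage_wrap("power", {
      p <- config$power
      nc <- p$n_cases %||% sum(cohort$case_status == "case")
      nk <- p$n_controls %||% sum(cohort$case_status == "control")
      dplyr::bind_rows(lapply(p$or_per_sd, function(or) {
        tibble(or_per_sd = or, r2 = p$r2,
               power_analytic = mr_power(nc, nk, p$r2, or),
               f_statistic = f_statistic(p$r2, nc + nk, 1))
      }))
    })
  }

  report <- structure(list(
    main = dplyr::bind_rows(main),
    stratified = strat,
    diagnostics = diagnostics,
    power = power_tab,
    scaling = scaling,
    instruments = curated,
    session = list(
      seed = config$seed,
      input_hashes = list(
        manifest = rlang::hash(manifest),
        dosages = if (!is.null(dosages)) rlang::hash(dosages),
        cohort = if (!is.null(cohort)) rlang::hash(cohort),
        summary_stats = if (!is.null(sstats)) rlang::hash(sstats))
    )
  ), class = "mr_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<mr_report>\n")
  if (nrow(x$main %||% tibble())) {
    print(x$main[, c("method", "or", "ci_lower", "ci_upper", "pvalue")])
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `main_results.tsv`, one TSV per stratified analysis, a diagnostics
#' JSON, a power TSV and `run_manifest.json` (seed plus input hashes).
#' Output is deterministic: identical report objects produce byte-identical
#' files.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$main) && nrow(report$main)) {
    readr::write_tsv(report$main, file.path(dir, "main_results.tsv"))
  }
  for (nm in names(report$stratified)) {
    readr::write_tsv(tidy(report$stratified[[nm]]),
                     file.path(dir, paste0("stratified_", nm, ".tsv")))
  }
  diag <- report$diagnostics
  if (!is.null(diag$confounder_screen)) {
    readr::write_tsv(diag$confounder_screen,
                     file.path(dir, "confounder_screen.tsv"))
  }
  if (!is.null(diag$funnel)) {
    readr::write_tsv(as_tibble(diag$funnel), file.path(dir, "funnel.tsv"))
  }
  if (!is.null(report$power)) {
    readr::write_tsv(report$power, file.path(dir, "power.tsv"))
  }
  jsonlite::write_json(
    list(main = report$main, session = report$session),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(report$session, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
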