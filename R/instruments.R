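#' Instrument curation
#'
#' Tools that reproduce the curation steps applied to published reproductive
#' timing instruments before genetic-risk-score construction: allele
#' harmonisation to the trait-increasing allele, substitution of missing
#' variants by linkage-disequilibrium proxies, pruning of correlated
#' instruments, genotype quality control, construction of the combined
#' lifetime-exposure instrument set, and removal of BMI-associated variants
#' for the restricted score.
#'
#' An instrument manifest is a tibble with one row per SNP and at least the
#' columns `rsid`, `effect_allele`, `other_allele`, `eaf`, `beta` (years per
#' effect allele), `se`, `pvalue` and `trait`. Curation flag columns
#' (`sex_chromosome`, `needs_proxy`, `proxy_rsid`, `proxy_r2`,
#' `correlated_partner`, `pair_r2`, `bmi_associated`) are optional and are
#' produced by [generate_manifest()].
#'
#' @name instruments
NULL

MANIFEST_CORE_COLS <- c("rsid", "effect_allele", "other_allele", "eaf",
                        "beta", "se", "pvalue", "trait")

validate_manifest <- function(manifest, arg = "manifest") {
  assert_that(is.data.frame(manifest), paste0("`", arg, "` must be a data frame"))
  missing <- setdiff(MANIFEST_CORE_COLS, names(manifest))
  assert_that(length(missing) == 0,
              paste0("`", arg, "` lacks columns: ", paste(missing, collapse = ", ")))
  assert_that(!anyDuplicated(manifest$rsid),
              paste0("`", arg, "` has duplicated rsids"))
  assert_that(all(manifest$se > 0, na.rm = TRUE), "`se` must be > 0")
  invisible(as_tibble(manifest))
}

#' Harmonise instruments to the trait-increasing allele
#'
#' Rows with a negative per-allele effect are flipped (effect and other
#' alleles swapped, effect-allele frequency replaced by its complement, beta
#' negated) so that every beta is non-negative and the effect allele is the
#' allele that increases the trait. The operation is idempotent. Palindromic
#' (A/T, C/G) variants with effect-allele frequency in [0.4, 0.6] are flagged
#' in a `palindromic` column but kept; set `drop_palindromic = TRUE` to
#' remove them.
#'
#' @param manifest Instrument manifest tibble (see [instruments]).
#' @param drop_palindromic Drop flagged strand-ambiguous variants? Default
#'   `FALSE`, which preserves the published instrument counts.
#' @return The harmonised manifest.
#' @export
harmonise_instruments <- function(manifest, drop_palindromic = FALSE) {
  manifest <- validate_manifest(manifest)
  flip <- !is.na(manifest$beta) & manifest$beta < 0
  if (any(flip)) {
    ea <- manifest$effect_allele[flip]
    manifest$effect_allele[flip] <- manifest$other_allele[flip]
    manifest$other_allele[flip] <- ea
    manifest$eaf[flip] <- 1 - manifest$eaf[flip]
    manifest$beta[flip] <- -manifest$beta[flip]
  }
  pal <- is_palindromic(manifest$effect_allele, manifest$other_allele) &
    manifest$eaf >= 0.4 & manifest$eaf <= 0.6
  manifest$palindromic <- pal
  if (drop_palindromic) manifest <- manifest[!pal, , drop = FALSE]
  manifest
}

#' Substitute missing instruments by LD proxies
#'
#' Records flagged `needs_proxy` are replaced by their best available proxy
#' with pairwise r-squared above `r2_min` (default 0.8); the substituted
#' record keeps the original effect size but adopts the proxy rsid, and its
#' effect allele is re-harmonised so the beta stays non-negative. Records with
#' no qualifying proxy are dropped and listed in the `dropped` attribute.
#'
#' @param manifest Instrument manifest with a logical `needs_proxy` column.
#' @param proxies Proxy table: tibble with columns `missing_rsid`,
#'   `proxy_rsid`, `r2` and optionally `sign` (+1 if the proxy allele tags the
#'   trait-increasing allele, -1 otherwise; default +1).
#' @param r2_min Minimum r-squared for a proxy to qualify (default 0.8).
#' @return Manifest with proxies substituted; attribute `dropped` holds a
#'   tibble of removed records and reasons.
#' @export
substitute_proxies <- function(manifest, proxies = NULL, r2_min = 0.8) {
  manifest <- validate_manifest(manifest)
  assert_that(is_fraction(r2_min), "`r2_min` must be in (0,1)")
  needs <- if ("needs_proxy" %in% names(manifest)) {
    !is.na(manifest$needs_proxy) & manifest$needs_proxy
  } else {
    rep(FALSE, nrow(manifest))
  }
  if (!any(needs)) {
    attr(manifest, "dropped") <- tibble(rsid = character(), reason = character())
    return(manifest)
  }
  if (is.null(proxies) || nrow(proxies) == 0) {
    proxies <- tibble(missing_rsid = character(), proxy_rsid = character(),
                      r2 = numeric())
  }
  assert_that(all(c("missing_rsid", "proxy_rsid", "r2") %in% names(proxies)),
              "`proxies` needs columns missing_rsid, proxy_rsid, r2")
  assert_that(all(proxies$r2 >= 0 & proxies$r2 <= 1), "proxy r2 must be in [0,1]")
  if (!"sign" %in% names(proxies)) proxies$sign <- 1

  best <- proxies |>
    dplyr::filter(.data$r2 > r2_min) |>
    dplyr::group_by(.data$missing_rsid) |>
    dplyr::slice_max(.data$r2, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  keep <- rep(TRUE, nrow(manifest))
  dropped <- list()
  for (i in which(needs)) {
    hit <- best[best$missing_rsid == manifest$rsid[i], ]
    if (nrow(hit) == 0) {
      keep[i] <- FALSE
      dropped[[length(dropped) + 1]] <-
        tibble(rsid = manifest$rsid[i], reason = "no_proxy")
    } else {
      manifest$rsid[i] <- hit$proxy_rsid
      manifest$beta[i] <- manifest$beta[i] * hit$sign
      if ("needs_proxy" %in% names(manifest)) manifest$needs_proxy[i] <- FALSE
    }
  }
  out <- harmonise_instruments(manifest[keep, , drop = FALSE])
  attr(out, "dropped") <- if (length(dropped)) {
    dplyr::bind_rows(dropped)
  } else {
    tibble(rsid = character(), reason = character())
  }
  out
}

# victim of one offending pair: higher p-value, ties broken by the
# lexicographically larger rsid (deterministic and order-free)
pair_victim <- function(rsid_a, rsid_b, p_a, p_b) {
  if (p_a > p_b) return(rsid_a)
  if (p_b > p_a) return(rsid_b)
  if (rsid_a > rsid_b) rsid_a else rsid_b
}

#' Prune correlated instruments
#'
#' For every pair of instruments with pairwise r-squared above `r2_max`
#' (default 0.01) the member with the higher exposure p-value is removed,
#' iterating until no offending pair remains. Ties are broken by dropping the
#' lexicographically larger rsid, making the result independent of row order.
#'
#' @param manifest Instrument manifest.
#' @param ld Long-format LD table: tibble with columns `rsid_a`, `rsid_b`,
#'   `r2`.
#' @param r2_max Maximum tolerated pairwise r-squared (default 0.01).
#' @return Pruned manifest, input row order preserved; attribute `removed`
#'   lists dropped rsids.
#' @export
prune_correlated <- function(manifest, ld = NULL, r2_max = 0.01) {
  manifest <- validate_manifest(manifest)
  assert_that(is_fraction(r2_max, open = FALSE), "`r2_max` must be in [0,1]")
  if (is.null(ld) || nrow(ld) == 0) {
    attr(manifest, "removed") <- character()
    return(manifest)
  }
  assert_that(all(c("rsid_a", "rsid_b", "r2") %in% names(ld)),
              "`ld` needs columns rsid_a, rsid_b, r2")
  assert_that(all(ld$r2 >= 0 & ld$r2 <= 1), "ld r2 must be in [0,1]")
  ld <- ld[ld$r2 > r2_max & ld$rsid_a != ld$rsid_b, , drop = FALSE]
  pval <- setNames(manifest$pvalue, manifest$rsid)
  alive <- setNames(rep(TRUE, nrow(manifest)), manifest$rsid)
  removed <- character()
  repeat {
    act <- ld[ld$rsid_a %in% names(alive)[alive] &
                ld$rsid_b %in% names(alive)[alive], , drop = FALSE]
    if (nrow(act) == 0) break
    victims <- vapply(seq_len(nrow(act)), function(i) {
      pair_victim(act$rsid_a[i], act$rsid_b[i],
                  pval[[act$rsid_a[i]]], pval[[act$rsid_b[i]]])
    }, character(1))
    victims <- unique(victims)
    # remove the single globally worst victim, then re-evaluate
    vp <- pval[victims]
    worst <- victims[vp == max(vp)]
    worst <- max(worst) # lexicographic tie-break
    alive[worst] <- FALSE
    removed <- c(removed, worst)
  }
  out <- manifest[alive[manifest$rsid], , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Genotype quality control
#'
#' Removes SNP columns of a dosage matrix that fail call rate, Hardy-Weinberg
#' equilibrium in controls, or minor-allele-frequency thresholds. HWE is
#' tested by a 1-df chi-square goodness of fit on hard-called genotypes
#' (dosages rounded to the nearest integer) among controls only.
#'
#' @param dosages Dosage tibble: `individual_id` plus one numeric column per
#'   rsid, values in [0, 2] (`NA` = missing).
#' @param controls Logical vector marking control individuals (same order as
#'   rows of `dosages`).
#' @param callrate_min Minimum per-SNP call rate (default 0.98).
#' @param hwe_alpha HWE p-value threshold; SNPs with control HWE p below this
#'   are removed (default 1e-4).
#' @param maf_min SNPs with minor allele frequency at or below this are
#'   removed (default 0.01).
#' @return List with `dosages` (filtered) and `report`, a tibble with one row
#'   per SNP: call rate, MAF, HWE p, `removed`, `reason`.
#' @export
qc_genotypes <- function(dosages, controls, callrate_min = 0.98,
                         hwe_alpha = 1e-4, maf_min = 0.01) {
  assert_that(is.data.frame(dosages) && "individual_id" %in% names(dosages),
              "`dosages` must contain an `individual_id` column")
  snp_cols <- setdiff(names(dosages), "individual_id")
  assert_that(length(controls) == nrow(dosages),
              "`controls` must have one entry per individual")
  mat <- as.matrix(dosages[snp_cols])

  callrate <- colMeans(!is.na(mat))
  freq <- colMeans(mat, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)

  hwe_p <- vapply(snp_cols, function(s) {
    g <- round(mat[controls, s])
    g <- g[!is.na(g)]
    n <- length(g)
    if (n == 0) return(NA_real_)
    counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    p <- (2 * counts[3] + counts[2]) / (2 * n)
    if (p <= 0 || p >= 1) return(1) # monomorphic: no testable departure
    expct <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((counts - expct)^2 / expct)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))

  reason <- vapply(seq_along(snp_cols), function(i) {
    r <- character()
    if (callrate[i] < callrate_min) r <- c(r, "callrate")
    if (!is.na(hwe_p[i]) && hwe_p[i] < hwe_alpha) r <- c(r, "hwe")
    if (maf[i] <= maf_min) r <- c(r, "maf")
    paste(r, collapse = ",")
  }, character(1))

  report <- tibble(rsid = snp_cols, callrate = unname(callrate),
                   maf = unname(maf), hwe_p = unname(hwe_p),
                   removed = nzchar(reason), reason = reason)
  kept <- snp_cols[!report$removed]
  out <- dosages[c("individual_id", kept)]
  ea <- attr(dosages, "effect_alleles", exact = TRUE)
  if (!is.null(ea)) attr(out, "effect_alleles") <- ea[kept]
  list(dosages = out, report = report)
}

#' Combine instruments for the lifetime oestrogen-exposure score
#'
#' Menarche instruments are re-harmonised to the menarche-DECREASING allele
#' (earlier menarche lengthens exposure) and appended to the menopause
#' instruments, which stay harmonised to the menopause-increasing allele; the
#' combined score therefore rises with longer endogenous oestrogen exposure.
#' Cross-trait pairs with r-squared above `r2_max` are pruned by the usual
#' higher-p-value rule.
#'
#' @param menarche,menopause Curated single-trait manifests.
#' @param cross_ld Optional LD table of cross-trait pairs (`rsid_a`, `rsid_b`,
#'   `r2`).
#' @param r2_max Maximum tolerated cross-trait r-squared (default 0.01).
#' @return Combined manifest with a `source_trait` column.
#' @export
combine_lifetime_instruments <- function(menarche, menopause, cross_ld = NULL,
                                         r2_max = 0.01) {
  menarche <- validate_manifest(menarche, "menarche")
  if (nrow(menarche) > 0) {
    # flip to the trait-decreasing allele; beta magnitude now counts years of
    # extra exposure per allele
    ea <- menarche$effect_allele
    menarche$effect_allele <- menarche$other_allele
    menarche$other_allele <- ea
    menarche$eaf <- 1 - menarche$eaf
    menarche$source_trait <- "menarche"
  }
  if (!is.null(menopause) && nrow(menopause) > 0) {
    menopause <- validate_manifest(menopause, "menopause")
    menopause$source_trait <- "menopause"
  } else {
    menopause <- menarche[0, , drop = FALSE]
  }
  dup <- intersect(menarche$rsid, menopause$rsid)
  in_ld <- if (is.null(cross_ld)) character() else c(cross_ld$rsid_a, cross_ld$rsid_b)
  bad <- setdiff(dup, in_ld)
  assert_that(length(bad) == 0,
              paste0("rsid(s) present in both traits but absent from cross_ld: ",
                     paste(bad, collapse = ", ")))
  combined <- dplyr::bind_rows(menarche, menopause)
  combined$trait <- "lifetime"
  if (length(dup)) {
    # keep the menopause copy; the duplicate pair is resolved like any
    # perfectly correlated pair
    drop_idx <- which(combined$rsid %in% dup &
                        combined$source_trait == "menarche")
    combined <- combined[-drop_idx, , drop = FALSE]
  }
  prune_correlated(combined, cross_ld, r2_max)
}

#' Restrict a manifest by excluding BMI-associated instruments
#'
#' Drops every record whose rsid appears in `bmi_assoc` (or, with
#' `bmi_assoc = NULL`, every record flagged `bmi_associated`). Used to build
#' the restricted menarche score that excludes the 42 BMI-associated SNPs.
#'
#' @param manifest Instrument manifest.
#' @param bmi_assoc Character vector of rsids to exclude, or `NULL` to use the
#'   manifest's `bmi_associated` flag column.
#' @return Restricted manifest.
#' @export
restrict_bmi_associated <- function(manifest, bmi_assoc = NULL) {
  manifest <- validate_manifest(manifest)
  if (is.null(bmi_assoc)) {
    if (!"bmi_associated" %in% names(manifest)) return(manifest)
    keep <- !(manifest$bmi_associated %in% TRUE)
  } else {
    keep <- !(manifest$rsid %in% bmi_assoc)
  }
  manifest[keep, , drop = FALSE]
}

#' Run the full single-trait curation sequence
#'
#' Drops sex-chromosome variants, substitutes proxies for missing variants,
#' and prunes correlated pairs, mirroring the published curation narrative
#' (proxy substitution before pruning).
#'
#' @param manifest Instrument manifest with curation flag columns.
#' @param proxies Proxy table; defaults to the one encoded in the manifest
#'   flags (see [manifest_proxy_table()]).
#' @param ld LD table; defaults to the one encoded in the manifest flags.
#' @param r2_proxy Minimum proxy r-squared (default 0.8).
#' @param r2_prune Maximum instrument pairwise r-squared (default 0.01).
#' @return Curated manifest.
#' @export
curate_instruments <- function(manifest, proxies = NULL, ld = NULL,
                               r2_proxy = 0.8, r2_prune = 0.01) {
  manifest <- validate_manifest(manifest)
  if (is.null(proxies)) proxies <- manifest_proxy_table(manifest)
  if (is.null(ld)) ld <- manifest_ld_table(manifest)
  if ("sex_chromosome" %in% names(manifest)) {
    manifest <- manifest[!(manifest$sex_chromosome %in% TRUE), , drop = FALSE]
  }
  manifest <- substitute_proxies(manifest, proxies, r2_min = r2_proxy)
  prune_correlated(manifest, ld, r2_max = r2_prune)
}

#' Extract the proxy table encoded in a generated manifest
#' @param manifest Manifest from [generate_manifest()].
#' @return Tibble with `missing_rsid`, `proxy_rsid`, `r2`, `sign`.
#' @export
manifest_proxy_table <- function(manifest) {
  if (!all(c("needs_proxy", "proxy_rsid", "proxy_r2") %in% names(manifest))) {
    return(tibble(missing_rsid = character(), proxy_rsid = character(),
                  r2 = numeric(), sign = numeric()))
  }
  rows <- manifest$needs_proxy %in% TRUE & !is.na(manifest$proxy_rsid)
  tibble(missing_rsid = manifest$rsid[rows],
         proxy_rsid = manifest$proxy_rsid[rows],
         r2 = manifest$proxy_r2[rows],
         sign = 1)
}

#' Extract the LD table encoded in a generated manifest
#' @param manifest Manifest from [generate_manifest()].
#' @return Tibble with `rsid_a`, `rsid_b`, `r2`, one row per correlated pair.
#' @export
manifest_ld_table <- function(manifest) {
  if (!all(c("correlated_partner", "pair_r2") %in% names(manifest))) {
    return(tibble(rsid_a = character(), rsid_b = character(), r2 = numeric()))
  }
  rows <- !is.na(manifest$correlated_partner) &
    manifest$rsid < manifest$correlated_partner
  tibble(rsid_a = manifest$rsid[rows],
         rsid_b = manifest$correlated_partner[rows],
         r2 = manifest$pair_r2[rows])
}
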