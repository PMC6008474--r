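# Small fixtures built in code; all deterministic.

# bare-bones manifest with chosen betas / p-values, harmonised
make_manifest <- function(rsid, beta, pvalue = rep(1e-9, length(rsid)),
                          eaf = rep(0.3, length(rsid)), trait = "menarche") {
  tibble::tibble(
    rsid = rsid, chrom = "1", pos = seq_along(rsid),
    effect_allele = "A", other_allele = "G",
    eaf = eaf, beta = beta, se = abs(beta) / 5 + 0.01, pvalue = pvalue,
    trait = trait
  )
}

# dosage tibble from a plain matrix (rows individuals, cols rsids)
make_dosages <- function(mat, rsid, effect_allele = NULL) {
  colnames(mat) <- rsid
  out <- dplyr::bind_cols(
    tibble::tibble(individual_id = sprintf("id%03d", seq_len(nrow(mat)))),
    tibble::as_tibble(as.data.frame(mat))
  )
  if (!is.null(effect_allele)) {
    attr(out, "effect_alleles") <- stats::setNames(effect_allele, rsid)
  }
  out
}

# independent greedy pruning oracle: repeatedly drop the highest-p SNP that
# participates in any offending pair (lexicographic tie-break)
prune_oracle <- function(manifest, ld, r2_max = 0.01) {
  surv <- manifest$rsid
  p <- stats::setNames(manifest$pvalue, manifest$rsid)
  repeat {
    off <- ld[ld$r2 > r2_max & ld$rsid_a %in% surv & ld$rsid_b %in% surv, ]
    if (nrow(off) == 0) return(surv)
    involved <- unique(c(off$rsid_a, off$rsid_b))
    worst <- involved[p[involved] == max(p[involved])]
    surv <- setdiff(surv, max(worst))
  }
}

# quick null two-sample table: ratio-implied outcome betas at a given truth
make_sumstats <- function(n_snp, theta = 0, seed = 1, se_out = 0.02,
                          delta = rep(0, n_snp)) {
  withr::with_seed(seed, {
    bx <- abs(stats::rnorm(n_snp, 0.05, 0.015)) + 0.01
    tibble::tibble(
      rsid = sprintf("s%03d", seq_len(n_snp)),
      beta_exposure = bx,
      se_exposure = bx / 20,
      beta_outcome = stats::rnorm(n_snp, theta * bx + delta, se_out),
      se_outcome = se_out
    )
  })
}
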