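test_that("harmonisation flips negative betas and is idempotent", {
  m <- make_manifest(c("rs1", "rs2"), beta = c(0.1, -0.2))
  h <- harmonise_instruments(m)
  expect_true(all(h$beta >= 0))
  expect_equal(h$effect_allele, c("A", "G"))
  expect_equal(h$eaf, c(0.3, 0.7))
  expect_identical(harmonise_instruments(h)[names(h)], h[names(h)])
})

test_that("palindromic variants with mid-range eaf are flagged, kept by default", {
  m <- make_manifest(c("rs1", "rs2"), beta = c(0.1, 0.1), eaf = c(0.5, 0.5))
  m$effect_allele <- c("A", "A")
  m$other_allele <- c("T", "G")
  h <- harmonise_instruments(m)
  expect_equal(h$palindromic, c(TRUE, FALSE))
  expect_equal(nrow(h), 2)
  expect_equal(harmonise_instruments(m, drop_palindromic = TRUE)$rsid, "rs2")
})

test_that("proxy substitution replaces, drops, and re-harmonises", {
  m <- make_manifest(paste0("rs", 1:5), beta = rep(0.1, 5))
  m$needs_proxy <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  proxies <- tibble::tibble(
    missing_rsid = c("rs1", "rs2", "rs2", "rs3"),
    proxy_rsid = c("px1", "px2a", "px2b", "px3"),
    r2 = c(0.95, 0.85, 0.99, 0.5), # rs3's only proxy fails the threshold
    sign = c(1, 1, -1, 1)
  )
  out <- substitute_proxies(m, proxies, r2_min = 0.8)
  expect_setequal(out$rsid, c("px1", "px2b", "rs4", "rs5"))
  expect_equal(attr(out, "dropped")$rsid, "rs3")
  # rs2's best proxy tags the trait-decreasing allele; beta re-harmonised
  expect_true(all(out$beta >= 0))
  expect_equal(out$effect_allele[out$rsid == "px2b"], "G")
})

test_that("identity when no proxies needed", {
  m <- make_manifest(c("rs1", "rs2"), beta = c(0.1, 0.2))
  out <- substitute_proxies(m, NULL)
  expect_equal(out$rsid, m$rsid)
  expect_equal(nrow(attr(out, "dropped")), 0)
})

test_that("the published proxy accounting is reproduced (42 missing, 7 dropped)", {
  m <- generate_manifest(389, n_sex_chr = 12, n_missing = 42, n_no_proxy = 7,
                         n_correlated = 12, seed = 101)
  m <- m[!m$sex_chromosome, ]
  out <- substitute_proxies(m, manifest_proxy_table(m))
  expect_equal(nrow(out), 377 - 7)
  expect_equal(nrow(attr(out, "dropped")), 7)
})

test_that("pruning drops the higher-p member of each correlated pair", {
  m <- make_manifest(c("rsA", "rsB", "rsC", "rsD"), beta = rep(0.1, 4),
                     pvalue = c(1e-10, 1e-8, 1e-12, 1e-9))
  ld <- tibble::tibble(rsid_a = c("rsA", "rsC"), rsid_b = c("rsB", "rsD"),
                       r2 = c(0.5, 0.9))
  out <- prune_correlated(m, ld)
  expect_equal(out$rsid, c("rsA", "rsC"))
  expect_setequal(attr(out, "removed"), c("rsB", "rsD"))
})

test_that("pruning matches a brute-force oracle on random small sets", {
  for (s in 1:20) {
    n <- withr::with_seed(s, sample(5:20, 1))
    m <- withr::with_seed(s, make_manifest(
      sprintf("rs%02d", sample(n)), beta = runif(n, 0.01, 0.2),
      pvalue = 10^runif(n, -12, -8)))
    pairs <- withr::with_seed(s + 100, {
      k <- sample(0:5, 1)
      if (k == 0) {
        tibble::tibble(rsid_a = character(), rsid_b = character(), r2 = numeric())
      } else {
        tibble::tibble(rsid_a = sample(m$rsid, k, replace = TRUE),
                       rsid_b = sample(m$rsid, k, replace = TRUE),
                       r2 = runif(k, 0, 1))
      }
    })
    pairs <- pairs[pairs$rsid_a != pairs$rsid_b, ]
    got <- prune_correlated(m, pairs)$rsid
    expect_setequal(got, prune_oracle(m, pairs))
  }
})

test_that("curation is order-independent and preserves row order", {
  m <- generate_manifest(60, n_sex_chr = 2, n_missing = 6, n_no_proxy = 2,
                         n_correlated = 5, seed = 33)
  base <- curate_instruments(m)
  for (s in 1:5) {
    perm <- withr::with_seed(s, m[sample(nrow(m)), ])
    expect_setequal(curate_instruments(perm)$rsid, base$rsid)
  }
  ld <- manifest_ld_table(m)
  pr <- prune_correlated(m, ld)
  expect_identical(pr$rsid, m$rsid[m$rsid %in% pr$rsid])
})

test_that("genotype QC removes SNPs by MAF, HWE, and call rate with reasons", {
  set.seed(42)
  n <- 2000
  controls <- rep(c(TRUE, FALSE), each = n / 2)
  good <- rbinom(n, 2, 0.3)
  rare <- rbinom(n, 2, 0.005)
  # gross heterozygote deficit in controls
  hwe_bad <- sample(c(0, 2), n, replace = TRUE, prob = c(0.7, 0.3))
  low_call <- good
  low_call[seq_len(0.05 * n)] <- NA
  d <- make_dosages(cbind(good, rare, hwe_bad, low_call),
                    c("ok", "rare", "hwebad", "lowcall"))
  res <- qc_genotypes(d, controls)
  rep <- res$report
  expect_false(rep$removed[rep$rsid == "ok"])
  expect_match(rep$reason[rep$rsid == "rare"], "maf")
  expect_match(rep$reason[rep$rsid == "hwebad"], "hwe")
  expect_match(rep$reason[rep$rsid == "lowcall"], "callrate")
  expect_equal(names(res$dosages), c("individual_id", "ok"))
})

test_that("HWE threshold is exclusive at the boundary direction stated", {
  # exact chi-square p slightly below 1e-4 must be removed
  set.seed(7)
  n <- 4000
  g <- rbinom(n, 2, 0.4)
  # perturb until p is small but nonzero
  p <- 1
  while (p >= 1e-4) {
    i <- sample(which(g == 1), 20)
    g[i] <- sample(c(0, 2), 20, replace = TRUE)
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    f <- (2 * cnt[3] + cnt[2]) / (2 * n)
    e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    p <- pchisq(sum((cnt - e)^2 / e), 1, lower.tail = FALSE)
  }
  d <- make_dosages(cbind(g), "snp")
  rep <- qc_genotypes(d, rep(TRUE, n))$report
  expect_true(rep$removed)
  expect_match(rep$reason, "hwe")
})

test_that("lifetime combination flips menarche alleles and prunes cross-trait pairs", {
  mena <- make_manifest(paste0("a", 1:6), beta = rep(0.1, 6),
                        pvalue = rep(1e-9, 6))
  meno <- make_manifest(paste0("b", 1:6), beta = rep(0.3, 6),
                        pvalue = rep(1e-12, 6), trait = "menopause")
  cross <- tibble::tibble(rsid_a = paste0("a", 1:4), rsid_b = paste0("b", 1:4),
                          r2 = c(0.5, 0.2, 0.9, 0.05))
  out <- combine_lifetime_instruments(mena, meno, cross)
  expect_equal(nrow(out), 8) # 4 pairs -> 4 removals
  # menarche members have higher p, so they are the removed ones
  expect_setequal(setdiff(c(paste0("a", 1:6), paste0("b", 1:6)), out$rsid),
                  paste0("a", 1:4))
  flipped <- out[out$source_trait == "menarche", ]
  expect_true(all(flipped$effect_allele == "G")) # decreasing allele
  expect_equal(unique(out$trait), "lifetime")
})

test_that("empty menopause list yields the sign-flipped menarche list", {
  mena <- make_manifest(c("a1", "a2"), beta = c(0.1, 0.2))
  out <- combine_lifetime_instruments(mena, NULL)
  expect_equal(nrow(out), 2)
  expect_equal(out$effect_allele, c("G", "G"))
  expect_equal(out$eaf, c(0.7, 0.7))
})

test_that("duplicated rsid across traits without cross-LD entry errors", {
  mena <- make_manifest("shared", beta = 0.1)
  meno <- make_manifest("shared", beta = 0.3, trait = "menopause")
  expect_error(combine_lifetime_instruments(mena, meno, NULL),
               "cross_ld")
})

test_that("restricted score excludes flagged SNPs: 358 -> 316", {
  m <- generate_manifest(389, 12, 42, 7, 12, seed = 44)
  cur <- curate_instruments(m)
  expect_equal(nrow(cur), 358)
  excl <- cur$rsid[1:42]
  expect_equal(nrow(restrict_bmi_associated(cur, excl)), 316)
  expect_equal(nrow(restrict_bmi_associated(cur, character())), 358)
  expect_equal(nrow(restrict_bmi_associated(cur, c("rsX", "rsY"))), 358)
})
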