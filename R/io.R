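#' File formats
#'
#' Readers and writers for the tabular formats used throughout: GWAS-summary
#' TSV instrument manifests, dosage matrices as TSV (rows individuals,
#' columns rsids), cohort tables as CSV, long-format LD and proxy tables as
#' TSV, and two-sample summary statistics as TSV.
#'
#' @name io
NULL

#' @rdname io
#' @param manifest Instrument manifest tibble.
#' @param path File path.
#' @export
write_instruments <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' @rdname io
#' @export
read_instruments <- function(path) {
  validate_manifest(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname io
#' @param dosages Dosage tibble (`individual_id` + one column per rsid). Its
#'   `effect_alleles` attribute, if any, is written as a companion two-column
#'   TSV next to the matrix (suffix `.alleles.tsv`) so the allele coding
#'   survives the round trip.
#' @export
write_dosages <- function(dosages, path) {
  readr::write_tsv(dosages, path)
  ea <- attr(dosages, "effect_alleles", exact = TRUE)
  if (!is.null(ea)) {
    readr::write_tsv(tibble(rsid = names(ea), effect_allele = unname(ea)),
                     paste0(path, ".alleles.tsv"))
  }
  invisible(path)
}

#' @rdname io
#' @export
read_dosages <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  side <- paste0(path, ".alleles.tsv")
  if (file.exists(side)) {
    al <- readr::read_tsv(side, show_col_types = FALSE)
    attr(out, "effect_alleles") <- setNames(al$effect_allele, al$rsid)
  }
  out
}

#' @rdname io
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname io
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname io
#' @export
read_ld_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_that(all(c("rsid_a", "rsid_b", "r2") %in% names(out)),
              "LD table needs columns rsid_a, rsid_b, r2")
  out
}

#' @rdname io
#' @export
read_proxy_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_that(all(c("missing_rsid", "proxy_rsid", "r2") %in% names(out)),
              "proxy table needs columns missing_rsid, proxy_rsid, r2")
  out
}

#' @rdname io
#' @param stats Summary-statistics tibble.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}

#' @rdname io
#' @export
read_summary_stats <- function(path) {
  validate_sumstats(readr::read_tsv(path, show_col_types = FALSE))
}
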