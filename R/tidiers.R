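#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR estimate
#'
#' One row per model term (slope, and intercept for Egger) in broom layout.
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `p.value`,
#'   `conf.low`, `conf.high` (on the log-odds scale).
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- tibble(term = "grs", estimate = x$beta, std.error = x$se,
                p.value = x$pvalue,
                conf.low = log(x$ci_lower), conf.high = log(x$ci_upper))
  if ("intercept" %in% names(x)) {
    out <- dplyr::bind_rows(out, tibble(
      term = "intercept", estimate = x$intercept, std.error = x$intercept_se,
      p.value = x$intercept_pvalue,
      conf.low = x$intercept_ci_lower, conf.high = x$intercept_ci_upper))
  }
  out
}

#' Glance at an MR estimate
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the odds-ratio scale summary and sample
#'   sizes.
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, or = x$or, ci_lower = x$ci_lower,
         ci_upper = x$ci_upper, p.value = x$pvalue,
         n_cases = x$n_cases, n_controls = x$n_controls, n_snps = x$n_snps)
}

#' Tidy a scaling fit
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return Per-study rows plus a pooled row.
#' @export
tidy.scaling_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$per_study,
    tibble(study = "pooled", beta = x$pooled$beta, se = x$pooled$se,
           n = sum(x$per_study$n))
  )
}

#' Glance at a scaling fit
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(beta = x$pooled$beta, se = x$pooled$se,
         n_studies = nrow(x$per_study), n = sum(x$per_study$n))
}

#' Tidy a stratified result
#' @param x A `stratified_result`.
#' @param ... Unused.
#' @return Per-stratum estimates with the heterogeneity p attached as a
#'   column.
#' @export
tidy.stratified_result <- function(x, ...) {
  out <- as_tibble(x)
  out$heterogeneity_p <- attr(x, "heterogeneity_p")
  out
}

#' Forest plot of a stratified analysis
#'
#' @param object A `stratified_result`.
#' @param ... Unused.
#' @return A ggplot: odds ratio per year with 95% CI per stratum.
#' @export
autoplot.stratified_result <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio per year (95% CI)",
                  y = attr(object, "stratum"))
}

#' Funnel plot of per-SNP ratio estimates
#'
#' Plots each SNP's Wald ratio against its precision with the IVW estimate
#' (solid) and Egger slope (dashed) overlaid; asymmetry suggests
#' directional pleiotropy.
#'
#' @param object A `funnel_data` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.funnel_data <- function(object, ...) {
  ivw <- attr(object, "ivw")
  egger <- attr(object, "egger")
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Ratio estimate (log OR per year)",
                  y = "Precision (1 / SE of ratio)")
  if (!is.null(ivw)) {
    p <- p + ggplot2::geom_vline(xintercept = ivw$beta, colour = "steelblue")
  }
  if (!is.null(egger)) {
    p <- p + ggplot2::geom_vline(xintercept = egger$beta,
                                 colour = "firebrick", linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.funnel_data
#' @param stats Summary-statistics tibble (convenience wrapper building the
#'   funnel data first).
#' @export
plot_funnel <- function(stats) {
  autoplot(funnel_data(stats))
}
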