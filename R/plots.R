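#' Plot a cumulative incidence surface
#'
#' One curve per (sex, birth year) stratum, cumulative incidence against
#' age.
#'
#' @param surface An `incidence_surface`.
#' @return A ggplot object.
#' @export
plot_incidence <- function(surface) {
  tab <- export_incidence(surface)
  tab$stratum <- paste(tab$sex,
                       ifelse(is.na(tab$birth_year), "",
                              tab$birth_year))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$age, y = .data$cum_inc,
                                    colour = .data$sex,
                                    group = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (years)", y = "cumulative incidence",
                  colour = "sex") +
    ggplot2::theme_minimal()
}

#' QQ plot of GWAS p values
#'
#' Observed against expected -log10 p values under the uniform null, the
#' standard inflation diagnostic.
#'
#' @param object A `gwas_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_result <- function(object, ...) {
  p <- sort(object$p[!is.na(object$p)])
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(length(p))),
    observed = -log10(p)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Scatter plot of paired chi-squared statistics
#'
#' Per-variant chi-squared statistics of one phenotype construction against
#' another over the comparison's variant selection, with the identity line
#' and the through-origin regression line whose slope measures the relative
#' effective-sample-size gain.
#'
#' @param object A `chisq_comparison` from [compare_chisq()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chisq_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$chisq_b, y = .data$chisq_a)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "black") +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "blue") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = bquote(chi^2 ~ .(unname(object$labels["b"]))),
      y = bquote(chi^2 ~ .(unname(object$labels["a"]))),
      subtitle = sprintf("slope %.2f (relative gain %+.0f%%)",
                         object$slope, 100 * object$gain)
    ) +
    ggplot2::theme_minimal()
}
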