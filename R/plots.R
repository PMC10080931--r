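#' Scatter plot of harmonized SNP effects
#'
#' Plots outcome betas against exposure betas with +/- 1 SE error bars and,
#' when fits are supplied, the fitted causal slopes (through the origin for
#' IVW and weighted median; with intercept for MR-Egger).
#'
#' @param pairs Harmonized pair tibble.
#' @param fits Optional named list of `mr_fit` / `mr_egger_fit` objects.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(pairs, fits = NULL) {
  d <- kept_pairs(pairs)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                   ymax = .data$beta_out + .data$se_out),
      colour = "grey70", width = 0
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                   xmax = .data$beta_exp + .data$se_exp),
      colour = "grey70", height = 0
    ) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    ab <- dplyr::bind_rows(lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      if (inherits(f, "mr_egger_fit")) {
        tibble::tibble(method = nm, intercept = f$intercept$beta,
                       slope = f$slope$beta)
      } else {
        tibble::tibble(method = nm, intercept = 0, slope = f$beta)
      }
    }))
    p <- p + ggplot2::geom_abline(
      data = ab,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$method)
    ) +
      ggplot2::labs(colour = "method")
  }
  p
}

#' Forest plot of MR results
#'
#' One row per outcome x method with the odds ratio and its 95% confidence
#' interval on a log-scaled axis; the vertical line marks the null OR of 1.
#'
#' @param results An `mr_results` tibble from [run_univariable()].
#' @return A ggplot object.
#' @export
plot_forest <- function(results) {
  d <- tibble::as_tibble(results)
  d$label <- paste(d$outcome, d$method, sep = " / ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significance), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, shape = "evidence") +
    ggplot2::theme_minimal()
}

#' @method autoplot mr_results
#' @export
autoplot.mr_results <- function(object, ...) plot_forest(object)
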