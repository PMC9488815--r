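#' Forest plot of odds ratios
#'
#' Draws estimates (points) with 95% CIs (horizontal bars) on a log OR
#' axis, one row per label — the layout of the per-outcome MR and
#' multivariable-regression figures.
#'
#' @param data tibble with columns `label`, `or`, `ci_low`, `ci_high`
#'   (CI bounds on the OR scale).
#' @param xlab x-axis label.
#' @return a ggplot object.
#' @export
plot_forest <- function(data, xlab = "Odds ratio (95% CI)") {
  stopifnot(all(c("label", "or", "ci_low", "ci_high") %in% names(data)))
  data$label <- factor(data$label, levels = rev(unique(data$label)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of SNP-outcome against SNP-exposure associations
#'
#' Each retained SNP of a harmonized set as a point with +/- 1 SE error
#' bars, overlaid with the IVW line through the origin and the MR-Egger
#' fit; a visible Egger intercept signals unbalanced horizontal pleiotropy.
#'
#' @param h a `harmonized_set` with at least 3 retained SNPs.
#' @return a ggplot object.
#' @export
plot_snp_effects <- function(h) {
  hr <- retained(orient_exposure(h))
  ivw <- mr_ivw(hr, "fixed")
  egg <- mr_egger(hr)
  ggplot2::ggplot(hr, ggplot2::aes(x = .data$beta_exposure,
                                   y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta_outcome - .data$se_outcome,
                   ymax = .data$beta_outcome + .data$se_outcome),
      linewidth = 0.3, colour = "grey60"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta_exposure - .data$se_exposure,
                   xmax = .data$beta_exposure + .data$se_exposure),
      linewidth = 0.3, colour = "grey60"
    ) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta,
                         colour = "#2166ac") +
    ggplot2::geom_abline(intercept = egg$intercept$estimate,
                         slope = egg$slope$beta, colour = "#b2182b",
                         linetype = "dashed") +
    ggplot2::labs(x = "SNP-exposure association",
                  y = "SNP-outcome association (log OR)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot harmonized_set
#' @export
autoplot.harmonized_set <- function(object, ...) plot_snp_effects(object)

#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  contrib <- attr(object, "contributions")
  data <- tibble::tibble(
    label = c(contrib$study, "Combined (fixed effects)"),
    or = exp(c(contrib$beta, object$beta)),
    ci_low = exp(c(contrib$beta - Z95 * contrib$se, object$ci_low)),
    ci_high = exp(c(contrib$beta + Z95 * contrib$se, object$ci_high))
  )
  plot_forest(data)
}
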