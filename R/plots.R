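#' @export
autoplot.autozyg_grid <- function(object, ...) {
  tab <- object$table |>
    dplyr::filter(!.data$skipped) |>
    tidyr::pivot_longer(c("beta_new", "beta_old"), names_to = "component",
                        names_prefix = "beta_", values_to = "beta") |>
    dplyr::mutate(se = ifelse(.data$component == "new", object$table$se_new[
      match(.data$threshold, object$table$threshold)],
      object$table$se_old[match(.data$threshold, object$table$threshold)]))
  unit <- if (object$source == "pedigree_t") "ancestral generations (t)"
          else "length threshold m (Mb)"
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$threshold, y = .data$beta,
                                         colour = .data$component)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$beta - .data$se,
                                      ymax = .data$beta + .data$se,
                                      fill = .data$component),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unit, y = "standardized depression coefficient",
                  title = paste0("Grid search (", object$trait, ", ",
                                 object$source, ")")) +
    ggplot2::theme_minimal()
  if (!is.na(object$selected_threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = object$selected_threshold,
                                 linetype = 2)
  }
  p
}

#' @export
autoplot.length_mixture <- function(object, lengths_mb = NULL, ...) {
  xs <- seq(object$means[1L] - 3 * sqrt(object$variances[1L]),
            object$means[2L] + 3 * sqrt(object$variances[2L]),
            length.out = 400)
  dens <- tibble(
    x = rep(xs, 2L),
    component = rep(c("short", "long"), each = length(xs)),
    density = c(object$weights[1L] * dnorm(xs, object$means[1L],
                                           sqrt(object$variances[1L])),
                object$weights[2L] * dnorm(xs, object$means[2L],
                                           sqrt(object$variances[2L]))))
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                          colour = .data$component))
  if (!is.null(lengths_mb)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble(x = log10(lengths_mb)),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(.data$density)),
      bins = 40, inherit.aes = FALSE, fill = "grey85", colour = NA)
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(object$boundary_mb),
                        linetype = 2) +
    ggplot2::labs(x = "log10 segment length (Mb)", y = "density",
                  title = sprintf("ROH length mixture (boundary %.1f Mb)",
                                  object$boundary_mb)) +
    ggplot2::theme_minimal()
}

#' Plot the contribution of new inbreeding across thresholds
#'
#' @param curve Output of [contribution_curve()].
#' @return A ggplot.
#' @export
plot_contribution <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "threshold", y = "new / total inbreeding") +
    ggplot2::theme_minimal()
}
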