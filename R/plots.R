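#' Plot a power contour grid
#'
#' Renders the output of [power_contour()] as a filled tile/contour map of
#' power over the within-subcluster ICC and the between/within ratio.
#' Infeasible grid points are left blank.
#'
#' @param data A tibble from [power_contour()].
#' @param contour Overlay contour lines at `breaks`.
#' @param breaks Contour levels.
#' @return A ggplot object.
#' @export
plot_power_contour <- function(data, contour = TRUE,
                               breaks = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(all(c("icc0", "ratio", "power") %in% names(data)))
  lab <- if (data$varied[1L] == "covariate") {
    c(expression(rho[0]), expression(rho[1] / rho[0]))
  } else {
    c(expression(alpha[0]), expression(alpha[1] / alpha[0]))
  }
  p <- ggplot2::ggplot(dplyr::filter(data, .data$feasible),
                       ggplot2::aes(x = .data$icc0, y = .data$ratio)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$power)) +
    ggplot2::scale_fill_viridis_c(name = "Power", limits = c(0, 1)) +
    ggplot2::labs(x = lab[[1L]], y = lab[[2L]]) +
    ggplot2::theme_minimal()
  if (contour && length(unique(data$icc0)) > 2 &&
      length(unique(data$ratio)) > 2) {
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$power),
                                   breaks = breaks, colour = "white")
  }
  p
}

#' Plot power against the number of clusters
#'
#' Power curve of the two-sided Wald test as `n_c` varies, for a fixed unit
#' variance; useful to visualize the effect of feasibility rounding.
#'
#' @param unit_variance Unit variance (scalar or `variance_result`).
#' @param n_s,m Trial dimensions.
#' @param effect Effect size.
#' @param alpha Type I error rate.
#' @param n_c Vector of cluster counts to evaluate.
#' @param reference `"normal"` or `"t"`.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(unit_variance, n_s, m, effect, alpha = 0.05,
                             n_c = seq(4L, 60L, by = 2L),
                             reference = "normal") {
  pw <- vapply(n_c, function(k) {
    wald_power(unit_variance, k, n_s, m, effect, alpha, reference)
  }, numeric(1L))
  ggplot2::ggplot(tibble::tibble(n_c = n_c, power = pw),
                  ggplot2::aes(x = .data$n_c, y = .data$power)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2) +
    ggplot2::labs(x = "Number of clusters", y = "Power") +
    ggplot2::theme_minimal()
}
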