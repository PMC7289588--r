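#' Histogram of a delta population
#'
#' @param object A `nanosip_popsummary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nanosip_popsummary <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$bin_low[1:2]),
                      fill = "grey30") +
    ggplot2::geom_vline(xintercept = s$mean, color = "red") +
    ggplot2::labs(
      x = expression(delta ~ "(‰)"), y = "count",
      title = sprintf("%s (%s basis): %.1f ± %.1f‰ (n = %d)",
                      s$class, s$basis, s$mean, s$sd, s$n)) +
    ggplot2::theme_minimal()
}

#' Delta13C vs delta15N enrichment biplot with 95% ellipses
#'
#' @param cells Cell table from [label_cells()] (cell basis) or a tibble
#'   with `delta13C`, `delta15N`, `class` columns (pixel basis).
#' @param basis `"cell"` or `"pixel"`; picks the column pair.
#' @return A ggplot with one 95% confidence ellipse per class (classes
#'   with at least 3 non-collinear points).
#' @export
plot_biplot <- function(cells, basis = c("cell", "pixel")) {
  basis <- match.arg(basis)
  if (basis == "cell") {
    df <- tibble::tibble(delta13C = cells$delta13C_cell,
                         delta15N = cells$delta15N_cell,
                         class = cells$class)
  } else {
    df <- tibble::tibble(delta13C = cells$delta13C,
                         delta15N = cells$delta15N, class = cells$class)
  }
  df <- df[stats::complete.cases(df), ]
  ell <- dplyr::group_modify(dplyr::group_by(df, .data$class),
    function(d, g) {
      out <- try(ellipse_95(cbind(d$delta13C, d$delta15N)), silent = TRUE)
      if (inherits(out, "try-error")) return(tibble::tibble())
      ellipse_boundary(out)
    })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta13C, y = .data$delta15N,
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_path(data = ell,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data$class)) +
    ggplot2::labs(x = expression(delta^13 * C ~ "(‰)"),
                  y = expression(delta^15 * N ~ "(‰)")) +
    ggplot2::theme_minimal()
}

#' Standard-curve plot
#'
#' @param object A `nanosip_stdcurve`.
#' @param ... Unused.
#' @return A ggplot of Cq against log10(copies) with the fitted line.
#' @export
autoplot.nanosip_stdcurve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = log10(.data$copies), y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::labs(x = "log10(copies)", y = "Cq",
                  title = sprintf("slope %.4f, efficiency %.1f%%",
                                  object$slope, 100 * object$efficiency)) +
    ggplot2::theme_minimal()
}

#' Replicate-signature plot
#'
#' @param signature Tibble from [replicate_signature()].
#' @return A ggplot of the mean signature with SD error bars.
#' @export
plot_signature <- function(signature) {
  ggplot2::ggplot(signature,
                  ggplot2::aes(x = .data$bin_mid, y = .data$mean_count)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_count - .data$sd_count,
      ymax = .data$mean_count + .data$sd_count), width = 0) +
    ggplot2::labs(x = expression(delta ~ "(‰)"), y = "mean count") +
    ggplot2::theme_minimal()
}
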