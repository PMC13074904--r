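#' @export
autoplot.srr_radial <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$R), .data$R > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$rho_mm, .data$R)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(rho ~ "(mm)"), y = "R")
}

#' @export
autoplot.srr_image <- function(object, ...) {
  d <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                          col = seq_len(ncol(object$values)))
  d$value <- as.vector(object$values)
  d$log10_value <- log10(pmax(d$value, max(d$value) * 1e-8))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$log10_value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "log10")
}

#' Overlay a simulated and a measured radial curve
#'
#' @param R_MC,R_exp_sc `srr_radial` curves.
#' @param window optional `srr_window` drawn as vertical bounds.
#' @return A ggplot.
#' @export
plot_fit_overlay <- function(R_MC, R_exp_sc, window = NULL) {
  d <- dplyr::bind_rows(
    tibble(rho_mm = R_MC$rho_mm, R = R_MC$R, curve = "Monte Carlo"),
    tibble(rho_mm = R_exp_sc$rho_mm, R = R_exp_sc$R, curve = "measured"))
  d <- dplyr::filter(d, !is.na(.data$R), .data$R > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$rho_mm, .data$R,
                                       color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(rho ~ "(mm)"), y = expression(R ~ (mm^-2)))
  if (!is.null(window))
    p <- p + ggplot2::geom_vline(xintercept = c(window$rho_0, window$rho_m),
                                 linetype = 2)
  p
}
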