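#' Plot an MSD curve
#'
#' Points with standard-error bars per lag, one colour per component.
#'
#' @param object An `msd_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$t_lag_us / 1000, y = .data$msd_um2, colour = .data$component
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$msd_um2 - .data$se_um2,
      ymax = .data$msd_um2 + .data$se_um2
    ), width = 0) +
    ggplot2::labs(x = "time lag (ms)", y = expression(MSD ~ (mu * m^2)),
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Plot a diffusion map
#'
#' Tile map of the local diffusion coefficient or anomalous exponent over
#' valid bins.
#'
#' @param object A `diffusion_map` from [map_diffusion()].
#' @param quantity `"D"` or `"alpha"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_map <- function(object, quantity = c("D", "alpha"), ...) {
  quantity <- match.arg(quantity)
  df <- object[object$valid, ]
  df$value <- if (quantity == "D") df$D_um2s else df$alpha
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x_nm / 1000, y = .data$y_nm / 1000, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(
      name = if (quantity == "D") expression(D ~ (mu * m^2 / s))
      else expression(alpha)
    ) +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m))) +
    ggplot2::theme_classic()
}

#' Plot a super-resolution rendering
#'
#' @param object An `smlm_image` from [render_smlm()].
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.smlm_image <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(
    iy = seq_len(nrow(img)), ix = seq_len(ncol(img))
  )
  df$value <- as.vector(img)[(df$ix - 1L) * nrow(img) + df$iy]
  df$x_nm <- object$origin["x"] + (df$ix - 0.5) * object$pixel_nm
  df$y_nm <- object$origin["y"] + (df$iy - 0.5) * object$pixel_nm
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "counts") +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_classic()
}

#' Plot a conditional-probability decay with its fitted model
#'
#' @param object A `pcc_result` from [fret_pcc()].
#' @param fit Optional `fret_kinetics` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcc_result <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$t_lag_us / 1000, y = .data$p_cc
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$p_cc - .data$se, ymax = .data$p_cc + .data$se
    ), width = 0) +
    ggplot2::labs(x = "time lag (ms)", y = expression(P[cc])) +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    t_us <- seq(0, max(object$t_lag_us), length.out = 100)
    curve <- tibble::tibble(
      t_lag_us = t_us,
      p_cc = (1 - fit$F_c) * exp(-fit$k_eff * t_us * 1e-6) + fit$F_c
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "red")
  }
  p
}

#' Display one readout frame of a stack
#'
#' @param stack A `frame_stack`.
#' @param frame Frame index.
#' @param trim Quantile used to clip the colour scale.
#' @return A ggplot raster of the frame (row 0 at the top, matching chip
#'   orientation).
#' @export
plot_frame <- function(stack, frame = 1L, trim = 0.999) {
  m <- stack$frames[[frame]]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$counts <- pmin(as.vector(m)[(df$col - 1L) * nrow(m) + df$row],
                    stats::quantile(m, trim))
  ggplot2::ggplot(df, ggplot2::aes(.data$col - 1L, .data$row - 1L,
                                   fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_classic()
}
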