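# ggplot2 views of the main result types.

#' @export
autoplot.depth_map <- function(object, ...) {
  df <- tibble::tibble(
    x = as.vector(row(object$depth_um)),
    y = as.vector(col(object$depth_um)),
    depth_um = as.vector(object$depth_um)
  )
  ggplot2::ggplot(df[is.finite(df$depth_um), ], ggplot2::aes(
    .data$x, .data$y,
    fill = .data$depth_um
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "depth (µm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (samples)", y = "y (samples)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.depth_calibration <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$known_um, .data$estimated_um)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "black") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      x = "known depth (µm)", y = "estimated depth (µm)",
      subtitle = sprintf(
        "gradient %.3f, R² = %.5f, RMSE = %.1f µm",
        object$gradient, object$r_squared, object$rmse_um
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.posture_basis <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$segment, .data$loading)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mode, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "body segment", y = "eigenworm loading") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rhodonea_fit <- function(object, ...) {
  pr <- object$projections
  fits <- object$fits
  curves <- purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    f <- fits[i, ]
    d <- pr[pr$mode == f$mode, ]
    t <- seq(min(d$time_s), max(d$time_s), length.out = 1000)
    p <- rhodonea_pair(t, f$A, f$k, f$a, f$c)
    tibble::tibble(mode = f$mode, a_theta = p$theta, a_phi = p$phi)
  })
  ggplot2::ggplot(pr, ggplot2::aes(.data$a_theta, .data$a_phi)) +
    ggplot2::geom_path(data = curves, colour = "grey60") +
    ggplot2::geom_point(size = 0.6, colour = "steelblue") +
    ggplot2::facet_wrap(~mode, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = expression(a^theta), y = expression(a^phi),
      subtitle = sprintf(
        "k = %.2f ± %.2f", object$k_mean,
        if (is.na(object$k_sd)) 0 else object$k_sd
      )
    ) +
    ggplot2::theme_minimal()
}

#' 3D skeleton trajectory as paired planar projections
#'
#' @param skeletons Skeleton tibble over frames.
#' @return A ggplot (xy and xz projections, faceted).
#' @export
plot_skeletons <- function(skeletons) {
  long <- dplyr::bind_rows(
    skeletons %>% mutate(h = .data$x_um, v = .data$y_um, proj = "xy"),
    skeletons %>% mutate(h = .data$x_um, v = .data$z_um, proj = "xz")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$h, .data$v,
    group = .data$frame, colour = .data$time_s
  )) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::facet_wrap(~proj, scales = "free_y") +
    ggplot2::scale_colour_viridis_c(name = "time (s)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y or z (µm)") +
    ggplot2::theme_minimal()
}
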