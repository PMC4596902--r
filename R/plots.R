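#' Plot an image, optionally with the segmentation outline
#'
#' Renders an [rgb_image()] (or [gray_image()]) with ggplot2; when a
#' `labeled_objects` result is supplied its object pixels are tinted red over
#' the photograph, mirroring the usual segmentation overlay.
#'
#' @param img An [rgb_image()] or [gray_image()].
#' @param labels Optional `labeled_objects` overlay.
#' @return A ggplot object.
#' @export
plot_image <- function(img, labels = NULL) {
  px <- unclass(img)
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))
  px <- px / 255
  if (!is.null(labels)) {
    sel <- labels$label_map > 0L
    r <- px[, , 1]
    g <- px[, , 2]
    b <- px[, , 3]
    r[sel] <- 1
    g[sel] <- 0.1
    b[sel] <- 0.1
    px[, , 1] <- r
    px[, , 2] <- g
    px[, , 3] <- b
  }
  h <- dim(px)[1]
  w <- dim(px)[2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(px, xmin = 0, xmax = w, ymin = 0, ymax = h) +
    ggplot2::scale_x_continuous(limits = c(0, w), expand = c(0, 0)) +
    ggplot2::scale_y_continuous(limits = c(0, h), expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.synthetic_scene <- function(object, ...) {
  plot_image(object$image) +
    ggplot2::ggtitle(sprintf("synthetic bunch, O = %d tips", object$truth$O))
}

#' @export
autoplot.shoot_lda <- function(object, ...) {
  d <- tidy(object)
  d_long <- tidyr::pivot_longer(
    d[, c("feature", "tolerance", "f_to_remove", "wilks_lambda")],
    -"feature",
    names_to = "diagnostic", values_to = "value"
  )
  ggplot2::ggplot(d_long, ggplot2::aes(x = .data$feature, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~diagnostic, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Discriminant diagnostics per selected variable"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.agreement_report <- function(object, ...) {
  d <- object$data
  g <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$O, y = .data$E)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "manual count O", y = "image-analysis count E",
      title = sprintf(
        "E = %.2f O %+.1f;  R² = %.3f, RMSE = %.1f",
        g$slope, g$intercept, g$r_squared, g$rmse
      )
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Feature-space view of classified objects
#'
#' Scatter of two morphometric features coloured by predicted class — a quick
#' check that shoots and non-shoots separate in shape space.
#'
#' @param classified Output of [classify_objects()].
#' @param x,y Feature column names (defaults `SF_elong` vs `SF_sfer`).
#' @return A ggplot object.
#' @export
plot_feature_space <- function(classified, x = "SF_elong", y = "SF_sfer") {
  ggplot2::ggplot(
    classified,
    ggplot2::aes(x = .data[[x]], y = .data[[y]], colour = .data$.class)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}
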