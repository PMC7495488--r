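# broom-style tidiers and ggplot2 autoplot methods.

#' @export
tidy.metric_curve <- function(x, ...) {
  dplyr::mutate(x$points, metric = x$metric_name,
                fitted = predict(x, x$points$imaging_rate_ipm))
}

#' @export
glance.metric_curve <- function(x, ...) {
  resid <- x$points$value - predict(x, x$points$imaging_rate_ipm)
  pars <- if (x$model == "monotone-interp") NA_integer_ else length(x$fit$coef)
  tibble::tibble(metric = x$metric_name, model = x$model,
                 n_points = nrow(x$points), n_parameters = pars,
                 rmse = sqrt(mean(resid^2)))
}

#' @export
tidy.eir_result <- function(x, ...) {
  tibble::tibble(
    component = c("eir_psnr", "eir_ssim", "eir"),
    rate_ipm = c(x$eir_psnr_ipm, x$eir_ssim_ipm, x$eir_ipm),
    criterion = c(x$criteria$psnr_criterion_db, x$criteria$ssim_criterion, NA))
}

#' @export
glance.eir_result <- function(x, ...) {
  tibble::tibble(eir_psnr_ipm = x$eir_psnr_ipm, eir_ssim_ipm = x$eir_ssim_ipm,
                 eir_ipm = x$eir_ipm)
}

#' @export
tidy.denoiser <- function(x, ...) summary(x)

#' @export
glance.denoiser <- function(x, ...) {
  tibble::tibble(family = x$spec$family, n_filters_F = x$spec$n_filters_F,
                 kernel_K = x$spec$kernel_K, n_layers_L = x$spec$n_layers_L,
                 n_convolutions = length(x$layers),
                 parameters = count_parameters(x),
                 trained = !is.null(x$history))
}

#' Plot a metric curve with its fit
#'
#' Observed points, the fitted monotone model on a log-rate axis, and the
#' quality criterion as a dashed line.
#'
#' @param object A [fit_metric_curve()] result.
#' @param criterion Optional criterion to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metric_curve <- function(object, criterion = NULL, ...) {
  pts <- object$points
  grid <- exp(seq(log(min(pts$imaging_rate_ipm)),
                  log(max(pts$imaging_rate_ipm)), length.out = 200))
  fitted <- tibble::tibble(imaging_rate_ipm = grid,
                           value = predict(object, grid))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$imaging_rate_ipm,
                                         y = .data$value)) +
    ggplot2::geom_line(data = fitted, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "imaging rate (images/min)",
                  y = toupper(object$metric_name))
  if (!is.null(criterion)) {
    p <- p + ggplot2::geom_hline(yintercept = criterion,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot EIR components
#'
#' Bar chart of the criterion-crossing rates and their harmonic mean for
#' one or more EIR results (e.g. raw versus denoised arms).
#'
#' @param object An `eir_result` or named list of them.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eir_result <- function(object, ...) {
  d <- dplyr::mutate(tidy(object), arm = "result")
  plot_eir_bars(d)
}

plot_eir_bars <- function(d) {
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$rate_ipm,
                                  fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "imaging rate (images/min)")
}

#' Compare raw and denoised EIR results
#'
#' @param raw,denoised `eir_result` objects.
#' @return A ggplot of the paired bars.
#' @export
plot_eir_comparison <- function(raw, denoised) {
  d <- dplyr::bind_rows(dplyr::mutate(tidy(raw), arm = "raw"),
                        dplyr::mutate(tidy(denoised), arm = "denoised"))
  plot_eir_bars(d)
}

#' Display a phantom or image matrix
#'
#' @param object A `nerve_phantom`.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.nerve_phantom <- function(object, ...) {
  img <- object$intensity
  d <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  d$intensity <- as.vector(img)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
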