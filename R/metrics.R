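# Image-quality metrics. PSNR is the standard 10*log10(R^2 / MSE); SSIM is
# the windowed luminance/contrast/structure index with Gaussian weighting
# (11x11 window, sigma 1.5, k1 = 0.01, k2 = 0.03 — the de-facto standard
# parameters), computed with edge-replicated filtering and a border crop of
# the filter radius before averaging.

check_same_shape <- function(image, reference) {
  if (!is.matrix(image) || !is.matrix(reference) ||
      !all(dim(image) == dim(reference))) {
    abort("`image` and `reference` must be matrices of identical shape",
          class = "carsdenoise_data_error")
  }
}

default_data_range <- function(reference, data_range) {
  if (!is.null(data_range)) {
    check_scalar_number(data_range, "data_range", lower = 1e-300)
    return(data_range)
  }
  # Unstated detector bit depth: default to the reference image's own
  # dynamic range, recorded by callers that persist results.
  dr <- diff(range(reference))
  if (dr <= 0) abort("reference has zero dynamic range; supply `data_range`",
                     class = "carsdenoise_data_error")
  dr
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels. Identical images have zero
#' MSE and return `Inf`.
#'
#' @param image,reference Numeric matrices of identical shape.
#' @param data_range Peak-to-peak signal range. Defaults to the dynamic
#'   range of `reference`.
#' @return PSNR in dB (scalar; `Inf` when the images are identical).
#' @export
#' @examples
#' a <- matrix(runif(64), 8, 8)
#' psnr(a, a)                         # Inf
#' psnr(a + 0.1, a, data_range = 1)   # 20 dB
psnr <- function(image, reference, data_range = NULL) {
  check_same_shape(image, reference)
  dr <- default_data_range(reference, data_range)
  mse <- mean((image - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(dr^2 / mse)
}

# Separable Gaussian filter with edge replication ('nearest' padding),
# kernel radius = floor(truncate * sigma + 0.5).
gaussian_filter2 <- function(x, sigma, truncate = 3.5) {
  r <- as.integer(truncate * sigma + 0.5)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  H <- nrow(x); W <- ncol(x)
  xp <- x[c(rep(1L, r), seq_len(H), rep(H, r)), , drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * xp[(t - 1L) + seq_len(H), , drop = FALSE]
  xp <- out[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * xp[, (t - 1L) + seq_len(W), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' Mean SSIM over a Gaussian-weighted sliding window. Symmetric in its two
#' arguments and equal to 1 for identical images.
#'
#' @inheritParams psnr
#' @param sigma Gaussian window standard deviation (default 1.5, i.e. an
#'   11x11 window).
#' @param k1,k2 Stabilisation constants (defaults 0.01, 0.03).
#' @return Scalar SSIM in \[-1, 1\].
#' @export
ssim <- function(image, reference, data_range = NULL, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03) {
  check_same_shape(image, reference)
  r <- as.integer(3.5 * sigma + 0.5)
  if (min(dim(image)) < 2L * r + 1L) {
    abort("image smaller than the SSIM window", class = "carsdenoise_data_error")
  }
  dr <- default_data_range(reference, data_range)
  c1 <- (k1 * dr)^2
  c2 <- (k2 * dr)^2
  ux <- gaussian_filter2(image, sigma)
  uy <- gaussian_filter2(reference, sigma)
  uxx <- gaussian_filter2(image * image, sigma)
  uyy <- gaussian_filter2(reference * reference, sigma)
  uxy <- gaussian_filter2(image * reference, sigma)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  vxy <- uxy - ux * uy
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
       ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  H <- nrow(s); W <- ncol(s)
  mean(s[(r + 1):(H - r), (r + 1):(W - r)])
}

#' Evaluate PSNR and SSIM for image pairs in a tibble
#'
#' Convenience wrapper that maps [psnr()] and [ssim()] over list-columns of
#' images and returns a long tibble, one row per (record, metric).
#'
#' @param data A tibble with list-columns of image matrices.
#' @param image,reference Column names (strings) of the test and reference
#'   images.
#' @param data_range Passed to the metrics; default uses each reference's
#'   dynamic range.
#' @return `data` without the image columns, expanded with `metric` and
#'   `value` columns.
#' @export
evaluate_metrics <- function(data, image = "input", reference = "target",
                             data_range = NULL) {
  imgs <- data[[image]]
  refs <- data[[reference]]
  keep <- data[!vapply(data, is.list, logical(1))]
  res <- purrr::map2(imgs, refs, function(a, b) {
    tibble::tibble(metric = c("psnr", "ssim"),
                   value = c(psnr(a, b, data_range), ssim(a, b, data_range)))
  })
  tidyr::unnest(dplyr::mutate(keep, .res = res), ".res")
}
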