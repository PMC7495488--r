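# Synthetic nerve phantoms: bright, elongated, gently wiggling fibre bundles
# over a dark background, with optional sparse blob-like lipid clutter. The
# phantom is the noise-free specimen signal that the acquisition simulator
# degrades frame by frame.

#' Specify a synthetic nerve phantom
#'
#' A phantom is a clean 2-D intensity field containing `n_fibers` elongated
#' curvilinear structures (myelinated-nerve stand-ins) over a uniform
#' background, plus `n_blobs` Gaussian blobs emulating sparse lipid-rich
#' clutter. Geometry is deliberately simple: only the statistical role of
#' the structures (bright, elongated, locally smooth) matters downstream.
#'
#' @param height_px,width_px Image dimensions in pixels (at least 16).
#' @param n_fibers Number of fibre bundles (non-negative).
#' @param fiber_width_px Full width at half maximum of a fibre profile, px.
#' @param fiber_orientation_deg Mean fibre orientation; 0 is horizontal,
#'   matching nerve bundles lying across the field of view.
#' @param fiber_wiggle Amplitude (px) of the sinusoidal fibre curvature.
#' @param fiber_intensity Peak fibre intensity above background (must exceed
#'   `background_level`).
#' @param n_blobs Number of clutter blobs.
#' @param background_level Uniform background intensity (non-negative).
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(height_px = 64, width_px = 64, n_fibers = 2)
#' ph <- generate_phantom(spec, seed = 1)
#' range(ph$intensity)
phantom_spec <- function(height_px = 500, width_px = 500,
                         n_fibers = 6, fiber_width_px = 8,
                         fiber_orientation_deg = 0, fiber_wiggle = 6,
                         fiber_intensity = 1, n_blobs = 10,
                         background_level = 0.05) {
  check_scalar_number(height_px, "height_px", lower = 16)
  check_scalar_number(width_px, "width_px", lower = 16)
  check_scalar_number(n_fibers, "n_fibers", lower = 0)
  check_scalar_number(fiber_width_px, "fiber_width_px", lower = 1e-8)
  check_scalar_number(fiber_orientation_deg, "fiber_orientation_deg")
  check_scalar_number(fiber_wiggle, "fiber_wiggle", lower = 0)
  check_scalar_number(fiber_intensity, "fiber_intensity", lower = 1e-12)
  check_scalar_number(n_blobs, "n_blobs", lower = 0)
  check_scalar_number(background_level, "background_level", lower = 0)
  if (fiber_intensity <= background_level) {
    abort("`fiber_intensity` must exceed `background_level`",
          class = "carsdenoise_config_error")
  }
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    n_fibers = as.integer(n_fibers), fiber_width_px = fiber_width_px,
    fiber_orientation_deg = fiber_orientation_deg,
    fiber_wiggle = fiber_wiggle, fiber_intensity = fiber_intensity,
    n_blobs = as.integer(n_blobs), background_level = background_level
  ), class = "phantom_spec")
}

#' Generate a nerve phantom
#'
#' Renders the clean intensity field described by a [phantom_spec()].
#' Deterministic given `(spec, seed)`: the same pair always yields a
#' bit-identical field.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed controlling fibre placement and clutter.
#' @return An object of class `nerve_phantom` with elements `intensity`
#'   (height x width numeric matrix, all values non-negative and finite),
#'   `spec` and `seed`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  if (!inherits(spec, "phantom_spec")) {
    abort("`spec` must be a `phantom_spec`", class = "carsdenoise_config_error")
  }
  H <- spec$height_px
  W <- spec$width_px
  y <- matrix(seq_len(H), H, W)          # row coordinate
  x <- matrix(seq_len(W), H, W, byrow = TRUE)

  img <- with_seed_(seed, {
    fibers <- matrix(0, H, W)
    if (spec$n_fibers > 0) {
      sigma <- spec$fiber_width_px / (2 * sqrt(2 * log(2)))  # FWHM -> sd
      for (f in seq_len(spec$n_fibers)) {
        th <- (spec$fiber_orientation_deg + runif(1, -5, 5)) * pi / 180
        u <- x * cos(th) + y * sin(th)
        v <- -x * sin(th) + y * cos(th)
        vr <- range(v)
        v0 <- vr[1] + runif(1, 0.15, 0.85) * diff(vr)
        span <- diff(range(u))
        lam1 <- runif(1, 0.5, 1) * span
        lam2 <- lam1 / 3
        ph1 <- runif(1, 0, 2 * pi)
        ph2 <- runif(1, 0, 2 * pi)
        vline <- v0 + spec$fiber_wiggle *
          (sin(2 * pi * u / lam1 + ph1) + 0.5 * sin(2 * pi * u / lam2 + ph2))
        prof <- spec$fiber_intensity * exp(-(v - vline)^2 / (2 * sigma^2))
        fibers <- pmax(fibers, prof)
      }
    }
    blobs <- matrix(0, H, W)
    if (spec$n_blobs > 0) {
      for (b in seq_len(spec$n_blobs)) {
        cx <- runif(1, 1, W)
        cy <- runif(1, 1, H)
        bs <- runif(1, 2, 6)
        amp <- spec$fiber_intensity * runif(1, 0.3, 0.8)
        blobs <- blobs + amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * bs^2))
      }
    }
    spec$background_level + fibers + blobs
  })

  structure(list(intensity = img, spec = spec, seed = as.integer(seed)),
            class = "nerve_phantom")
}

#' @export
print.nerve_phantom <- function(x, ...) {
  cat(sprintf("<nerve_phantom %dx%d, %d fibres, %d blobs, seed %d>\n",
              x$spec$height_px, x$spec$width_px, x$spec$n_fibers,
              x$spec$n_blobs, x$seed))
  invisible(x)
}
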