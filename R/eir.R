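# Equivalent Imaging Rate (EIR). Image quality falls as the imaging rate
# rises (fewer frames averaged per image). Fitting a monotone model to
# (rate, metric) observations and solving for the rate at which the fitted
# curve crosses a quality criterion (PSNR = 30 dB, SSIM = 0.8 by default)
# gives the criterion-crossing rates EIR_PSNR and EIR_SSIM; their harmonic
# mean is the EIR — the fastest rate at which images remain effectively
# indistinguishable from the long-exposure reference.

#' EIR quality criteria
#'
#' @param psnr_criterion_db PSNR criterion in dB (default 30, a standard
#'   "visually indistinguishable" threshold).
#' @param ssim_criterion SSIM criterion in (0, 1) (default 0.8).
#' @return An object of class `eir_criteria`.
#' @export
eir_criteria <- function(psnr_criterion_db = 30, ssim_criterion = 0.8) {
  check_scalar_number(psnr_criterion_db, "psnr_criterion_db", lower = 1e-12)
  check_scalar_number(ssim_criterion, "ssim_criterion", lower = 1e-12,
                      upper = 1 - 1e-12)
  structure(list(psnr_criterion_db = psnr_criterion_db,
                 ssim_criterion = ssim_criterion), class = "eir_criteria")
}

#' Fit a monotone metric-versus-rate curve
#'
#' Three monotone models of metric value against imaging rate are offered:
#' `"log-linear"` (`v = a + b * log(rate)`, the closed form that frame
#' averaging implies for PSNR), `"logistic"` (a 3-parameter logistic in
#' `log(rate)`, suited to SSIM which saturates at both ends), and
#' `"monotone-interp"` (model-free piecewise-linear interpolation in
#' `log(rate)`).
#'
#' @param data A data frame with columns `imaging_rate_ipm` and `value`
#'   (optionally `spread`).
#' @param metric_name `"psnr"` or `"ssim"` (bookkeeping only).
#' @param model `"log-linear"`, `"logistic"` or `"monotone-interp"`.
#' @return An object of class `metric_curve`; use [predict()] to evaluate it
#'   at any positive rate and [equivalent_rate()] to invert it.
#' @export
#' @examples
#' d <- tibble::tibble(imaging_rate_ipm = c(1, 3, 10, 30),
#'                     value = 40 - 10 * log10(c(1, 3, 10, 30)))
#' cv <- fit_metric_curve(d, "psnr", "log-linear")
#' equivalent_rate(cv, 30)   # 10
fit_metric_curve <- function(data, metric_name = c("psnr", "ssim"),
                             model = c("log-linear", "logistic",
                                       "monotone-interp")) {
  metric_name <- match.arg(metric_name)
  model <- match.arg(model)
  rate <- data$imaging_rate_ipm
  value <- data$value
  if (any(!is.finite(rate)) || any(rate <= 0) || anyDuplicated(rate)) {
    abort("rates must be positive, finite and distinct",
          class = "carsdenoise_data_error")
  }
  if (any(!is.finite(value))) {
    abort("metric values must be finite", class = "carsdenoise_data_error")
  }
  min_pts <- if (model == "monotone-interp") 2L else 3L
  if (length(rate) < min_pts) {
    abort(sprintf("model '%s' needs at least %d points", model, min_pts),
          class = "carsdenoise_fit_error")
  }
  o <- order(rate)
  lr <- log(rate[o]); v <- value[o]

  fit <- switch(model,
    "log-linear" = {
      m <- lm(v ~ lr)
      list(coef = coef(m))
    },
    "logistic" = {
      # v = L / (1 + exp((lr - x0) / s)): decreasing in rate for s > 0
      L0 <- max(v) * 1.02
      x00 <- lr[which.min(abs(v - max(v) / 2))]
      m <- minpack.lm::nlsLM(
        v ~ L / (1 + exp((lr - x0) / s)),
        start = list(L = L0, x0 = x00, s = diff(range(lr)) / 4 + 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      list(coef = coef(m))
    },
    "monotone-interp" = list(lr = lr, v = v)
  )
  structure(list(points = tibble::tibble(imaging_rate_ipm = rate[o], value = v),
                 metric_name = metric_name, model = model, fit = fit),
            class = "metric_curve")
}

#' Evaluate a fitted metric curve
#'
#' @param object A [fit_metric_curve()] result.
#' @param rate Positive imaging rates (images/min).
#' @param ... Unused.
#' @return Fitted metric values at `rate`.
#' @export
predict.metric_curve <- function(object, rate, ...) {
  lr <- log(rate)
  switch(object$model,
    "log-linear" = unname(object$fit$coef[1] + object$fit$coef[2] * lr),
    "logistic" = {
      p <- object$fit$coef
      unname(p["L"] / (1 + exp((lr - p["x0"]) / p["s"])))
    },
    "monotone-interp" =
      approx(object$fit$lr, object$fit$v, xout = lr, rule = 2)$y
  )
}

#' Rate at which a metric curve crosses a criterion
#'
#' Solves `fitted_value(rate) = criterion` by bracketed root finding over
#' `[min_rate / 10, max_rate * 10]` (the observed rates extended one decade
#' each way; the interpolation model is clamped to the observed range).
#'
#' @param curve A [fit_metric_curve()] result.
#' @param criterion Metric value to invert at.
#' @param tol Root-finding tolerance on the rate.
#' @return The crossing rate in images/min.
#' @export
equivalent_rate <- function(curve, criterion, tol = 1e-9) {
  rng <- range(curve$points$imaging_rate_ipm)
  lo <- if (curve$model == "monotone-interp") rng[1] else rng[1] / 10
  hi <- if (curve$model == "monotone-interp") rng[2] else rng[2] * 10
  f <- function(r) predict(curve, r) - criterion
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    abort(sprintf("criterion %g not attained by the fitted %s curve within [%g, %g] images/min",
                  criterion, curve$metric_name, lo, hi),
          class = "carsdenoise_criterion_error")
  }
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Harmonic mean of two positive rates
#' @param a,b Positive rates.
#' @return `2 * a * b / (a + b)`.
#' @export
harmonic_mean <- function(a, b) {
  check_scalar_number(a, "a", lower = 1e-300)
  check_scalar_number(b, "b", lower = 1e-300)
  2 * a * b / (a + b)
}

new_eir_result <- function(eir_psnr, eir_ssim, criteria) {
  structure(list(eir_psnr_ipm = eir_psnr, eir_ssim_ipm = eir_ssim,
                 eir_ipm = harmonic_mean(eir_psnr, eir_ssim),
                 criteria = criteria), class = "eir_result")
}

#' Equivalent imaging rate from fitted curves
#'
#' Inverts the PSNR curve at the PSNR criterion and the SSIM curve at the
#' SSIM criterion, and combines the two crossing rates by their harmonic
#' mean.
#'
#' @param psnr_curve,ssim_curve [fit_metric_curve()] results.
#' @param criteria An [eir_criteria()].
#' @return An object of class `eir_result` with `eir_psnr_ipm`,
#'   `eir_ssim_ipm` and `eir_ipm` (unrounded; [print()] shows one decimal).
#' @export
compute_eir <- function(psnr_curve, ssim_curve, criteria = eir_criteria()) {
  a <- equivalent_rate(psnr_curve, criteria$psnr_criterion_db)
  b <- equivalent_rate(ssim_curve, criteria$ssim_criterion)
  new_eir_result(a, b, criteria)
}

#' Equivalent imaging rate from known crossing rates
#'
#' @param eir_psnr_ipm,eir_ssim_ipm Criterion-crossing rates, images/min.
#' @param criteria An [eir_criteria()].
#' @return An `eir_result`.
#' @export
#' @examples
#' eir_from_rates(12.5, 4.8)   # EIR 6.94, printed as 6.9
eir_from_rates <- function(eir_psnr_ipm, eir_ssim_ipm,
                           criteria = eir_criteria()) {
  new_eir_result(eir_psnr_ipm, eir_ssim_ipm, criteria)
}

#' @export
print.eir_result <- function(x, ...) {
  cat(sprintf("Equivalent imaging rate (criteria: PSNR %.4g dB, SSIM %.4g)\n",
              x$criteria$psnr_criterion_db, x$criteria$ssim_criterion))
  cat(sprintf("  EIR_PSNR: %.1f images/min\n", x$eir_psnr_ipm))
  cat(sprintf("  EIR_SSIM: %.1f images/min\n", x$eir_ssim_ipm))
  cat(sprintf("  EIR:      %.1f images/min (harmonic mean)\n", x$eir_ipm))
  invisible(x)
}
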