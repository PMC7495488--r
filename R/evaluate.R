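# Evaluation harness: exhaustive 3:1:1 nested cross-validation splits,
# hyperparameter grid search, and the statistical machinery for comparing
# denoisers (Friedman rank test, two-tailed paired t, Bonferroni-Holm).

#' Enumerate nested cross-validation splits
#'
#' Every ordered choice of (test, validation) position among `n` distinct
#' positions, with the remaining positions as the training set: `n (n - 1)`
#' plans, e.g. 20 for the canonical 5 positions at 3:1:1.
#'
#' @param position_ids Vector of distinct position identifiers.
#' @return A tibble with columns `plan`, `test_id`, `val_id` and the
#'   list-column `train_ids`.
#' @export
nested_splits <- function(position_ids) {
  if (anyDuplicated(position_ids)) {
    abort("position ids must be distinct", class = "carsdenoise_config_error")
  }
  n <- length(position_ids)
  if (n < 3) {
    abort("need at least 3 positions for a 3-way split",
          class = "carsdenoise_config_error")
  }
  plans <- tidyr::expand_grid(test_id = position_ids, val_id = position_ids)
  plans <- dplyr::filter(plans, .data$test_id != .data$val_id)
  plans$train_ids <- purrr::map2(plans$test_id, plans$val_id, function(te, va) {
    setdiff(position_ids, c(te, va))
  })
  dplyr::mutate(plans, plan = dplyr::row_number(), .before = 1)
}

#' Grid search over architecture hyperparameters
#'
#' Trains one model per (F, K, L) combination and returns the combination
#' with the best validation score. Ties break deterministically to the
#' first combination in canonical F, K, L order. Combinations that fail to
#' build or train are recorded and skipped with a warning.
#'
#' @param space A grid tibble as from [grid_space()].
#' @param patches,val_patches Training and validation patch tibbles.
#' @param config A [train_config()].
#' @param metric Selection metric: `"psnr"` (default) or `"ssim"`,
#'   evaluated on the validation patches.
#' @return A list with `best_spec` (an [arch_spec()]), `best_model`, and
#'   `results` (one row per combination with its validation score).
#' @export
grid_search <- function(space, patches, val_patches, config = train_config(),
                        metric = c("psnr", "ssim")) {
  metric <- match.arg(metric)
  if (!nrow(space)) {
    abort("empty grid", class = "carsdenoise_config_error")
  }
  score_one <- function(model) {
    vals <- purrr::map2_dbl(val_patches$input, val_patches$target,
      function(a, b) {
        y <- denoise(model, a)
        if (metric == "psnr") psnr(y, b) else ssim(y, b)
      })
    mean(vals)
  }
  results <- purrr::pmap_dfr(space, function(family, n_filters_F, kernel_K,
                                             n_layers_L) {
    row <- tibble::tibble(family = family, n_filters_F = n_filters_F,
                          kernel_K = kernel_K, n_layers_L = n_layers_L,
                          score = NA_real_, failed = FALSE)
    tryCatch({
      sp <- arch_spec(family, n_filters_F, kernel_K, n_layers_L)
      model <- train_denoiser(patches, sp, config, val_patches)
      row$score <- score_one(model)
      attr(row, "model") <- model
    }, error = function(e) {
      warn(sprintf("grid combination (%s, %d, %d, %d) failed: %s",
                   family, n_filters_F, kernel_K, n_layers_L,
                   conditionMessage(e)))
      row$failed <<- TRUE
    })
    row
  })
  ok <- which(!results$failed & is.finite(results$score))
  if (!length(ok)) {
    abort("every grid combination failed", class = "carsdenoise_fit_error")
  }
  best_i <- ok[which.max(results$score[ok])]   # first max in canonical order
  best_spec <- arch_spec(results$family[best_i], results$n_filters_F[best_i],
                         results$kernel_K[best_i], results$n_layers_L[best_i])
  best_model <- train_denoiser(patches, best_spec, config, val_patches)
  list(best_spec = best_spec, best_model = best_model, results = results)
}

# Tie-corrected Friedman chi-squared statistic; subjects in rows, models in
# columns. Used internally for the permutation null; the user-facing test
# delegates the observed statistic and chi-squared p to stats::friedman.test.
friedman_stat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  cm <- colMeans(r)
  num <- n * sum((cm - (k + 1) / 2)^2)
  den <- sum((r - (k + 1) / 2)^2) / (n * (k - 1))
  num / den
}

#' Friedman rank test across models
#'
#' Rank-based test of whether several models (columns) perform equally
#' across subjects (rows), with a chi-squared reference distribution or an
#' optional within-subject permutation null.
#'
#' @param values A numeric matrix or data frame, subjects x models.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for the permutation null.
#' @param seed Seed for the permutation null.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`, plus
#'   the attribute `mean_ranks` (average rank per model).
#' @export
friedman_rank_test <- function(values, p_method = c("chisq", "permutation"),
                               n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  m <- as.matrix(values)
  if (nrow(m) < 2 || ncol(m) < 2 || anyNA(m)) {
    abort("need >= 2 models and >= 2 subjects with no missing cells",
          class = "carsdenoise_data_error")
  }
  ft <- friedman.test(m)
  stat <- unname(ft$statistic)
  ranks <- t(apply(m, 1, rank))
  if (!is.finite(stat)) {
    # every subject ties all models: no rank information at all
    warn("constant rows: the Friedman statistic is degenerate (taken as 0)")
    out <- tibble::tibble(statistic = 0, df = unname(ft$parameter),
                          p_value = 1, method = p_method)
    attr(out, "mean_ranks") <- colMeans(ranks)
    return(out)
  }
  if (p_method == "chisq") {
    p <- ft$p.value
  } else {
    obs <- friedman_stat(m)
    p <- with_seed_(seed, {
      k <- ncol(m)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        perm <- t(apply(m, 1, sample))
        if (friedman_stat(perm) >= obs - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (n_perm + 1)
    })
  }
  out <- tibble::tibble(statistic = stat, df = unname(ft$parameter),
                        p_value = p, method = p_method)
  attr(out, "mean_ranks") <- colMeans(ranks)
  out
}

#' Two-tailed paired t-test
#'
#' @param a,b Paired numeric vectors (same subjects, same order).
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p_value`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort("`a` and `b` must be paired vectors of equal length >= 2",
          class = "carsdenoise_data_error")
  }
  d <- a - b
  if (sd(d) == 0) {
    abort("zero-variance differences: paired t-test is degenerate",
          class = "carsdenoise_degenerate_error")
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value)
}

#' Bonferroni-Holm step-down correction
#'
#' Sorts the p-values ascending, compares the i-th smallest against
#' `alpha / (m - i + 1)`, and stops at the first failure; also reports the
#' monotone Holm-adjusted p-values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise error level.
#' @return A tibble in the input order: `p_value`, `p_adjusted`, `reject`.
#' @export
holm_adjust <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "carsdenoise_data_error")
  }
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  m <- length(p_values)
  o <- order(p_values)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[o[i]] <= alpha / (m - i + 1)) reject_sorted[i] <- TRUE
    else break
  }
  reject <- logical(m)
  reject[o] <- reject_sorted
  tibble::tibble(p_value = p_values,
                 p_adjusted = p.adjust(p_values, method = "holm"),
                 reject = reject)
}

style_patches <- function(data, ids, patch_cfg, seed) {
  extract_patches(data[data$position %in% ids, , drop = FALSE],
                  patch_cfg, seed)
}

#' Run the nested cross-validation protocol
#'
#' For each of the `n (n - 1)` split plans, trains/fine-tunes a model on
#' the 3 training positions, selects on the validation position, and
#' evaluates PSNR and SSIM on the held-out test position. Four learning
#' styles are available: `"microscopy"` (the pre-trained model applied
#' directly), `"endoscopy"` (trained from scratch on the small dataset),
#' `"finetune"` (pre-trained then retrained) and `"ensemble"` (the mean of
#' the four fine-tuned models that share a test position — the only
#' grouping in which all members are blind to that position). A leakage
#' audit verifies that no reported test metric involves a model whose
#' training or validation saw the test position.
#'
#' @param data A dataset tibble (as from [simulate_dataset()]) with columns
#'   `position`, `input`, `target`.
#' @param spec An [arch_spec()].
#' @param config A [train_config()]; `seed` also drives the per-plan
#'   substreams.
#' @param patch_cfg A [patch_config()].
#' @param styles Subset of `c("microscopy", "endoscopy", "finetune",
#'   "ensemble")`.
#' @param pretrained A trained `denoiser` (required for the microscopy,
#'   finetune and ensemble styles).
#' @return A list: `results` (tidy tibble of style, plan, test position,
#'   metric, value), `models` (the per-plan fine-tuned/scratch models),
#'   `leakage_audit` (one row per reported value with a `violation` flag),
#'   and `plans`.
#' @export
run_protocol <- function(data, spec, config = train_config(),
                         patch_cfg = patch_config(),
                         styles = c("finetune", "ensemble"),
                         pretrained = NULL) {
  styles <- match.arg(styles, c("microscopy", "endoscopy", "finetune",
                                "ensemble"), several.ok = TRUE)
  needs_pre <- any(styles %in% c("microscopy", "finetune", "ensemble"))
  if (needs_pre && is.null(pretrained)) {
    abort("styles using pre-training require a `pretrained` model",
          class = "carsdenoise_config_error")
  }
  positions <- unique(data$position)
  plans <- nested_splits(positions)
  test_image <- function(id) {
    row <- data[data$position == id, ][1, ]
    list(input = row$input[[1]], target = row$target[[1]])
  }

  models <- list()
  results <- list()
  audit <- list()
  add_result <- function(style, plan_id, test_id, img_out, target, seen_ids) {
    res <- tibble::tibble(
      style = style, plan = plan_id, test_position = test_id,
      metric = c("psnr", "ssim"),
      value = c(psnr(img_out, target), ssim(img_out, target)))
    results[[length(results) + 1L]] <<- res
    audit[[length(audit) + 1L]] <<- tibble::tibble(
      style = style, plan = plan_id, test_position = test_id,
      violation = test_id %in% seen_ids)
  }

  for (pl in seq_len(nrow(plans))) {
    plan <- plans[pl, ]
    tr_ids <- plan$train_ids[[1]]
    seen <- c(tr_ids, plan$val_id)
    pseed <- substream_seed(config$seed, pl)
    cfg_pl <- config
    cfg_pl$seed <- as.integer(pseed %% 2147483647)
    tr_p <- style_patches(data, tr_ids, patch_cfg, substream_seed(pseed, 1))
    va_p <- style_patches(data, plan$val_id, patch_cfg, substream_seed(pseed, 2))
    ti <- test_image(plan$test_id)

    if ("endoscopy" %in% styles) {
      m <- train_denoiser(tr_p, spec, cfg_pl, va_p)
      models[[paste0("endoscopy_", pl)]] <- m
      add_result("endoscopy", pl, plan$test_id, denoise(m, ti$input),
                 ti$target, seen)
    }
    if (any(c("finetune", "ensemble") %in% styles)) {
      m <- fine_tune(pretrained, tr_p, cfg_pl, va_p)
      models[[paste0("finetune_", pl)]] <- m
      if ("finetune" %in% styles) {
        add_result("finetune", pl, plan$test_id, denoise(m, ti$input),
                   ti$target, seen)
      }
    }
  }

  if ("microscopy" %in% styles) {
    for (id in positions) {
      ti <- test_image(id)
      add_result("microscopy", NA_integer_, id, denoise(pretrained, ti$input),
                 ti$target, character(0))
    }
  }
  if ("ensemble" %in% styles) {
    for (id in positions) {
      pls <- plans$plan[plans$test_id == id]
      members <- models[paste0("finetune_", pls)]
      ens <- ensemble_model(unname(members), strict = length(members) == 4L)
      ti <- test_image(id)
      seen <- unique(unlist(plans$train_ids[plans$test_id == id]))
      seen <- c(seen, plans$val_id[plans$test_id == id])
      add_result("ensemble", NA_integer_, id, ensemble_predict(ens, ti$input),
                 ti$target, setdiff(seen, NA))
    }
  }

  list(results = dplyr::bind_rows(results), models = models,
       leakage_audit = dplyr::bind_rows(audit), plans = plans)
}

#' Summarise protocol results as a comparison table
#'
#' @param results The `results` tibble from [run_protocol()].
#' @return Mean and standard deviation of each metric per style, one row
#'   per (style, metric).
#' @export
summarise_protocol <- function(results) {
  dplyr::summarise(dplyr::group_by(results, .data$style, .data$metric),
                   mean = mean(.data$value), sd = sd(.data$value),
                   n = dplyr::n(), .groups = "drop")
}

#' Metric-versus-rate sweep, raw and denoised
#'
#' Acquires images of held-out phantoms across a range of frame counts
#' (imaging rates), scores each against its long-exposure ground truth, and
#' optionally scores a denoiser's outputs on the same inputs — the data
#' behind an EIR comparison.
#'
#' @param phantoms List of `nerve_phantom` objects (test positions).
#' @param n_frames_levels Integer vector of frame counts (each gives rate
#'   `60 / (frame_exposure_s * n)`).
#' @param noise A [noise_spec()].
#' @param model Optional `denoiser` or `denoiser_ensemble` for the denoised
#'   arm, or a list of them named by frame count (`"1"`, `"3"`, ...) to use
#'   a model trained at each imaging rate.
#' @param frame_exposure_s Per-frame exposure, seconds.
#' @param gt_frames Frames in the ground-truth average.
#' @param seed Integer seed.
#' @return A tibble: `arm` (`"raw"`/`"denoised"`), `imaging_rate_ipm`,
#'   `n_frames`, `metric`, `value` (mean over phantoms), `spread` (sd).
#' @export
rate_sweep <- function(phantoms, n_frames_levels, noise = noise_spec(),
                       model = NULL, frame_exposure_s = 1.6,
                       gt_frames = 100L, seed = 1L) {
  rows <- list()
  for (p in seq_along(phantoms)) {
    ph <- phantoms[[p]]
    pseed <- substream_seed(seed, p)
    gt <- acquire_image(ph, acquisition_spec(frame_exposure_s, gt_frames),
                        noise, substream_seed(pseed, 1e6))
    for (l in seq_along(n_frames_levels)) {
      k <- n_frames_levels[l]
      acq <- acquisition_spec(frame_exposure_s, k)
      img <- acquire_image(ph, acq, noise, substream_seed(pseed, l))
      arms <- list(raw = img)
      mk <- if (is.list(model) && !inherits(model, c("denoiser", "denoiser_ensemble"))) {
        model[[as.character(k)]]
      } else model
      if (!is.null(mk)) arms$denoised <- denoise(mk, img)
      for (arm_name in names(arms)) {
        vals <- c(psnr(arms[[arm_name]], gt), ssim(arms[[arm_name]], gt))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phantom = p, arm = arm_name, imaging_rate_ipm = acq$imaging_rate_ipm,
          n_frames = k, metric = c("psnr", "ssim"), value = vals)
      }
    }
  }
  dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(rows), .data$arm,
                    .data$imaging_rate_ipm, .data$n_frames, .data$metric),
    spread = sd(.data$value), value = mean(.data$value), .groups = "drop")
}

#' EIR from a rate sweep
#'
#' Fits the default monotone models (log-linear for PSNR, logistic for
#' SSIM) to one arm of a [rate_sweep()] table and computes the EIR.
#'
#' @param sweep A [rate_sweep()] result.
#' @param arm `"raw"` or `"denoised"`.
#' @param criteria An [eir_criteria()].
#' @param ssim_model Curve model for the SSIM arm (default `"logistic"`).
#' @return An `eir_result`.
#' @export
eir_from_sweep <- function(sweep, arm = "raw", criteria = eir_criteria(),
                           ssim_model = "logistic") {
  s <- sweep[sweep$arm == arm, ]
  pc <- fit_metric_curve(s[s$metric == "psnr", ], "psnr", "log-linear")
  sc <- fit_metric_curve(s[s$metric == "ssim", ], "ssim", ssim_model)
  compute_eir(pc, sc, criteria)
}
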