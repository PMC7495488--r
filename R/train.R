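# Training pipeline: patch extraction (random crops, no flips/rotations by
# default — raster-scanned detectors have a directional temporal response,
# so mirrored patches are not valid observations), MSE loss, Adam, and the
# pre-train -> fine-tune -> 4-model-ensemble protocol.

#' Training configuration
#'
#' Defaults follow the standard denoiser-training recipe: mini-batches of
#' 32 patches, MSE loss, Adam with beta1 = 0.9, beta2 = 0.999,
#' epsilon = 1e-8, learning rate 1e-3. The checkpoint with the best
#' validation PSNR is returned.
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment/stabilisation parameters.
#' @param max_epochs Number of passes over the training patches.
#' @param seed Integer seed governing initialisation and shuffling.
#' @param val_fraction Fraction of patches held out for validation when no
#'   explicit validation set is supplied.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         max_epochs = 200L, seed = 1L, val_fraction = 0.2) {
  check_scalar_number(batch_size, "batch_size", lower = 1)
  check_scalar_number(learning_rate, "learning_rate", lower = 1e-300)
  check_scalar_number(max_epochs, "max_epochs", lower = 0)
  check_scalar_number(val_fraction, "val_fraction", lower = 0, upper = 0.9)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), val_fraction = val_fraction,
                 loss = "mse", selection = "best_val_psnr"),
            class = "train_config")
}

#' Patch-extraction configuration
#'
#' @param patch_px Square crop size in pixels (100 suits W5/DN; N2N needs a
#'   multiple of 32, 128 at full scale).
#' @param n_patches_per_image Random crops per source image (default 50).
#' @param allow_flip_rotation If `TRUE`, augment with random flips and
#'   90-degree rotations. Off by default: raster-scan electronics make
#'   flipped images physically invalid.
#' @return An object of class `patch_config`.
#' @export
patch_config <- function(patch_px = 100L, n_patches_per_image = 50L,
                         allow_flip_rotation = FALSE) {
  check_scalar_number(patch_px, "patch_px", lower = 1)
  check_scalar_number(n_patches_per_image, "n_patches_per_image", lower = 1)
  structure(list(patch_px = as.integer(patch_px),
                 n_patches_per_image = as.integer(n_patches_per_image),
                 allow_flip_rotation = isTRUE(allow_flip_rotation)),
            class = "patch_config")
}

rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

#' Extract paired training patches
#'
#' Cuts `n_patches_per_image` random square crops from every (input,
#' target) record, applying identical crop offsets (and, if enabled,
#' identical flips/rotations) to both members of a pair, then shuffles the
#' patch order.
#'
#' @param data A tibble with list-columns `input` and `target`.
#' @param cfg A [patch_config()].
#' @param seed Integer seed for offsets and shuffling.
#' @return A tibble with columns `source`, `offset_i`, `offset_j` and
#'   list-columns `input`, `target` (plus `imaging_rate_ipm` if present in
#'   `data`).
#' @export
extract_patches <- function(data, cfg = patch_config(), seed = 1L) {
  p <- cfg$patch_px
  rows <- with_seed_(seed, {
    out <- vector("list", nrow(data))
    for (r in seq_len(nrow(data))) {
      input <- data$input[[r]]
      target <- data$target[[r]]
      if (nrow(input) < p || ncol(input) < p) {
        abort("patch size exceeds source image size",
              class = "carsdenoise_config_error")
      }
      oi <- sample.int(nrow(input) - p + 1L, cfg$n_patches_per_image,
                       replace = TRUE)
      oj <- sample.int(ncol(input) - p + 1L, cfg$n_patches_per_image,
                       replace = TRUE)
      ins <- vector("list", cfg$n_patches_per_image)
      tgs <- vector("list", cfg$n_patches_per_image)
      for (k in seq_len(cfg$n_patches_per_image)) {
        ii <- oi[k]:(oi[k] + p - 1L)
        jj <- oj[k]:(oj[k] + p - 1L)
        a <- input[ii, jj]
        b <- target[ii, jj]
        if (cfg$allow_flip_rotation) {
          if (runif(1) < 0.5) { a <- a[, rev(seq_len(p))]; b <- b[, rev(seq_len(p))] }
          nrot <- sample(0:3, 1)
          for (q in seq_len(nrot)) { a <- rot90cw(a); b <- rot90cw(b) }
        }
        ins[[k]] <- a
        tgs[[k]] <- b
      }
      row <- tibble::tibble(source = r, offset_i = oi, offset_j = oj,
                            input = ins, target = tgs)
      if ("imaging_rate_ipm" %in% names(data)) {
        row$imaging_rate_ipm <- data$imaging_rate_ipm[[r]]
      }
      out[[r]] <- row
    }
    res <- dplyr::bind_rows(out)
    res[sample.int(nrow(res)), ]
  })
  rows
}

flatten_params <- function(layers) {
  unlist(lapply(layers, function(l) list(l$w, l$b)), recursive = FALSE)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# One Adam step over the layer list; grads is a per-layer list of (w, b).
adam_step <- function(model, grads, state, cfg) {
  t <- state$t + 1L
  lr_t <- cfg$learning_rate * sqrt(1 - cfg$beta2^t) / (1 - cfg$beta1^t)
  for (l in seq_along(model$layers)) {
    for (nm in c("w", "b")) {
      g <- grads[[l]][[nm]]
      state$m[[l]][[nm]] <- cfg$beta1 * state$m[[l]][[nm]] + (1 - cfg$beta1) * g
      state$v[[l]][[nm]] <- cfg$beta2 * state$v[[l]][[nm]] + (1 - cfg$beta2) * g^2
      model$layers[[l]][[nm]] <- model$layers[[l]][[nm]] -
        lr_t * state$m[[l]][[nm]] / (sqrt(state$v[[l]][[nm]]) + cfg$epsilon)
    }
  }
  state$t <- t
  list(model = model, state = state)
}

accumulate_grads <- function(acc, g, scale) {
  if (is.null(acc)) {
    return(lapply(g, function(l) list(w = l$w * scale, b = l$b * scale)))
  }
  for (l in seq_along(g)) {
    acc[[l]]$w <- acc[[l]]$w + g[[l]]$w * scale
    acc[[l]]$b <- acc[[l]]$b + g[[l]]$b * scale
  }
  acc
}

val_mse <- function(model, inputs, targets, scale) {
  tot <- 0
  for (i in seq_along(inputs)) {
    y <- net_forward(model, inputs[[i]] / scale)$y
    tot <- tot + mean((y - targets[[i]] / scale)^2)
  }
  tot / length(inputs)
}

train_engine <- function(model, patches, cfg, val_patches = NULL) {
  scale <- model$norm$scale
  if (is.null(scale)) {
    scale <- as.numeric(quantile(unlist(patches$target), 0.999))
    if (!is.finite(scale) || scale <= 0) scale <- 1
    model$norm$scale <- scale
  }
  if (is.null(val_patches) && cfg$val_fraction > 0 && nrow(patches) >= 5) {
    n_val <- max(1L, floor(cfg$val_fraction * nrow(patches)))
    idx <- with_seed_(substream_seed(cfg$seed, 999L),
                      sample.int(nrow(patches), n_val))
    val_patches <- patches[idx, ]
    patches <- patches[-idx, ]
  }
  tr_in <- patches$input
  tr_tg <- patches$target
  va_in <- val_patches$input
  va_tg <- val_patches$target
  n <- length(tr_in)
  state <- list(t = 0L,
                m = lapply(model$layers, function(l) list(w = l$w * 0, b = l$b * 0)),
                v = lapply(model$layers, function(l) list(w = l$w * 0, b = l$b * 0)))
  best <- list(score = Inf, layers = model$layers)
  history <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed_(substream_seed(cfg$seed, epoch), sample.int(n))
    ep_loss <- 0
    n_batches <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      ids <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      gacc <- NULL
      bloss <- 0
      for (i in ids) {
        x <- tr_in[[i]] / scale
        tg <- tr_tg[[i]] / scale
        fwd <- net_forward(model, x, with_cache = TRUE)
        err <- fwd$y - tg
        bloss <- bloss + mean(err^2)
        dy <- 2 * err / (length(err) * length(ids))
        gacc <- accumulate_grads(gacc, net_backward(model, fwd, dy), 1)
      }
      bloss <- bloss / length(ids)
      if (!is.finite(bloss)) {
        abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
              class = "carsdenoise_training_error")
      }
      st <- adam_step(model, gacc, state, cfg)
      model <- st$model
      state <- st$state
      ep_loss <- ep_loss + bloss
      n_batches <- n_batches + 1L
    }
    vm <- if (length(va_in)) val_mse(model, va_in, va_tg, scale) else NA_real_
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_mse = ep_loss / max(n_batches, 1L), val_mse = vm,
      val_psnr = if (is.na(vm) || vm <= 0) NA_real_ else -10 * log10(vm))
    score <- if (is.na(vm)) -epoch else vm   # no val set: keep last epoch
    if (score < best$score) best <- list(score = score, layers = model$layers)
  }
  model$layers <- best$layers
  model$history <- dplyr::bind_rows(history)
  model$config <- cfg
  model
}

#' Train a denoiser
#'
#' Optimises the MSE between denoised patches and their targets with Adam,
#' and returns the checkpoint with the best validation PSNR. With a
#' clean-target patch set this is ordinary supervised denoising; with a
#' noisy-pair patch set (two independent acquisitions of each scene) it is
#' Noise2Noise-style training, whose expected-MSE minimiser is the same
#' clean signal.
#'
#' @param patches A patch tibble from [extract_patches()] (list-columns
#'   `input`, `target`).
#' @param spec An [arch_spec()].
#' @param config A [train_config()].
#' @param val_patches Optional validation patch tibble; if absent,
#'   `val_fraction` of `patches` is held out.
#' @param mode `"clean-target"` or `"noisy-target"`; recorded as provenance
#'   (the pairing itself is a property of the patch set).
#' @return A trained `denoiser` carrying `history` (per-epoch losses),
#'   `config` and `provenance`.
#' @export
train_denoiser <- function(patches, spec, config = train_config(),
                           val_patches = NULL,
                           mode = c("clean-target", "noisy-target")) {
  mode <- match.arg(mode)
  model <- build_denoiser(spec, seed = config$seed)
  model <- train_engine(model, patches, config, val_patches)
  model$provenance <- list(mode = mode, fine_tuned = FALSE,
                           n_patches = nrow(patches))
  model
}

#' Fine-tune a pre-trained denoiser
#'
#' Continues optimisation from the pre-trained weights (all layers
#' trainable) on a new patch set, returning the best-validation checkpoint.
#' With `config$max_epochs = 0` the weights are returned unchanged.
#'
#' @param model A trained `denoiser`.
#' @param patches,config,val_patches As in [train_denoiser()].
#' @return A fine-tuned `denoiser`; `provenance$fine_tuned` is `TRUE` and
#'   `provenance$pretrained_history` keeps the pre-training record.
#' @export
fine_tune <- function(model, patches, config = train_config(),
                      val_patches = NULL) {
  if (!inherits(model, "denoiser")) {
    abort("`model` must be a trained denoiser",
          class = "carsdenoise_config_error")
  }
  pre_hist <- model$history
  pre_prov <- model$provenance
  if (config$max_epochs == 0L) {
    model$provenance <- list(mode = pre_prov$mode %||% "clean-target",
                             fine_tuned = TRUE, pretrained = pre_prov,
                             pretrained_history = pre_hist)
    return(model)
  }
  out <- train_engine(model, patches, config, val_patches)
  out$provenance <- list(mode = pre_prov$mode %||% "clean-target",
                         fine_tuned = TRUE, pretrained = pre_prov,
                         pretrained_history = pre_hist,
                         n_patches = nrow(patches))
  out
}

#' Combine four fine-tuned models into an ensemble
#'
#' The ensemble prediction is the pixel-wise arithmetic mean of the member
#' outputs. Four members of one architecture is the canonical composition;
#' other counts are allowed only with `strict = FALSE`.
#'
#' @param members A list of `denoiser` objects sharing one architecture.
#' @param strict Require exactly four members (default `TRUE`).
#' @return An object of class `denoiser_ensemble`.
#' @export
ensemble_model <- function(members, strict = TRUE) {
  if (!length(members) || !all(vapply(members, inherits, TRUE, "denoiser"))) {
    abort("`members` must be a list of denoisers",
          class = "carsdenoise_config_error")
  }
  if (strict && length(members) != 4L) {
    abort("an ensemble has exactly 4 members (use strict = FALSE to override)",
          class = "carsdenoise_config_error")
  }
  fams <- vapply(members, function(m) m$spec$family, "")
  if (length(unique(fams)) != 1L) {
    abort("ensemble members must share one architecture",
          class = "carsdenoise_config_error")
  }
  structure(list(members = members), class = "denoiser_ensemble")
}

#' Ensemble prediction
#'
#' @param ensemble A [ensemble_model()].
#' @param image A finite numeric matrix.
#' @return The pixel-wise mean of the member denoised outputs.
#' @export
ensemble_predict <- function(ensemble, image) {
  outs <- lapply(ensemble$members, denoise, image = image)
  Reduce(`+`, outs) / length(outs)
}

#' @export
denoise.denoiser_ensemble <- function(model, image) {
  ensemble_predict(model, image)
}
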