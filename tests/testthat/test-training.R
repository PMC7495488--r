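fake_pairs <- function(n, px = 32, f = function() matrix(runif(px * px), px)) {
  tibble::tibble(input = replicate(n, f(), simplify = FALSE),
                 target = replicate(n, f(), simplify = FALSE))
}

test_that("patch counts multiply out exactly", {
  withr::with_seed(1, src <- fake_pairs(81, 32))
  cfg <- patch_config(patch_px = 16, n_patches_per_image = 50)
  expect_equal(nrow(extract_patches(src, cfg, seed = 1)), 4050L)
  expect_equal(nrow(extract_patches(src[1:5, ], cfg, seed = 1)), 250L)
  expect_equal(nrow(extract_patches(src[1:3, ], cfg, seed = 1)), 150L)
  expect_equal(nrow(extract_patches(src[1, ], cfg, seed = 1)), 50L)
})

test_that("patches are contiguous sub-grids with shared offsets and no flips", {
  withr::with_seed(2, src <- fake_pairs(3, 16))
  pt <- extract_patches(src, patch_config(8, 10), seed = 3)
  for (r in seq_len(nrow(pt))) {
    ii <- pt$offset_i[r]:(pt$offset_i[r] + 7L)
    jj <- pt$offset_j[r]:(pt$offset_j[r] + 7L)
    expect_identical(pt$input[[r]], src$input[[pt$source[r]]][ii, jj])
    expect_identical(pt$target[[r]], src$target[[pt$source[r]]][ii, jj])
  }
})

test_that("flip/rotation augmentation produces dihedral copies when enabled", {
  withr::with_seed(4, src <- fake_pairs(2, 12))
  pt <- extract_patches(src, patch_config(6, 20, allow_flip_rotation = TRUE),
                        seed = 5)
  transformed <- vapply(seq_len(nrow(pt)), function(r) {
    ii <- pt$offset_i[r]:(pt$offset_i[r] + 5L)
    jj <- pt$offset_j[r]:(pt$offset_j[r] + 5L)
    !identical(pt$input[[r]], src$input[[pt$source[r]]][ii, jj])
  }, TRUE)
  expect_gt(sum(transformed), 0L)
})

test_that("oversized patches are rejected", {
  src <- fake_pairs(1, 8)
  expect_error(extract_patches(src, patch_config(16, 2)),
               class = "carsdenoise_config_error")
})

test_that("training on a noiseless dataset keeps the identity solution", {
  withr::with_seed(6, imgs <- replicate(4, matrix(runif(576), 24),
                                        simplify = FALSE))
  src <- tibble::tibble(input = imgs, target = imgs)
  pt <- extract_patches(src, patch_config(16, 10), seed = 1)
  m <- train_denoiser(pt, arch_spec("W5", 4, 3, 1),
                      train_config(max_epochs = 3, seed = 1))
  vm <- tail(m$history$val_mse, 1)
  expect_lt(vm, 1e-4 * var(unlist(src$target)))
})

test_that("noisy-target training converges toward the clean mean", {
  px <- 16
  withr::with_seed(7, {
    noisy <- function() matrix(0.5 + rnorm(px * px, 0, 0.2), px)
    pt <- tibble::tibble(input = replicate(100, noisy(), simplify = FALSE),
                         target = replicate(100, noisy(), simplify = FALSE))
    test_in <- noisy()
  })
  m <- train_denoiser(pt, arch_spec("W5", 4, 3, 1),
                      train_config(max_epochs = 40, seed = 2),
                      mode = "noisy-target")
  out <- denoise(m, test_in)
  # output approaches the constant 0.5, the expected-MSE minimiser
  expect_lt(mean((out - 0.5)^2), 0.5 * mean((test_in - 0.5)^2))
})

test_that("training is reproducible given (seed, config, data)", {
  ds <- tiny_gaussian_dataset(n_positions = 2, px = 48)
  pt <- extract_patches(ds, patch_config(32, 6), seed = 5)
  cfg <- train_config(max_epochs = 2, seed = 9)
  m1 <- train_denoiser(pt, arch_spec("W5", 4, 3, 1), cfg)
  m2 <- train_denoiser(pt, arch_spec("W5", 4, 3, 1), cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
})

test_that("a non-finite loss is reported as a training error", {
  ds <- tiny_gaussian_dataset(n_positions = 2, px = 48)
  pt <- extract_patches(ds, patch_config(32, 6), seed = 5)
  pt$target[[3]][1, 1] <- Inf
  expect_error(
    train_denoiser(pt, arch_spec("W5", 4, 3, 1),
                   train_config(max_epochs = 2, seed = 1, val_fraction = 0)),
    class = "carsdenoise_training_error")
})

test_that("fine-tuning with a zero-epoch budget returns identical weights", {
  ds <- tiny_gaussian_dataset(n_positions = 2, px = 48)
  pt <- extract_patches(ds, patch_config(32, 6), seed = 5)
  m <- train_denoiser(pt, arch_spec("W5", 4, 3, 1),
                      train_config(max_epochs = 2, seed = 1))
  ft <- fine_tune(m, pt, train_config(max_epochs = 0, seed = 2))
  expect_identical(ft$layers, m$layers)
  expect_true(ft$provenance$fine_tuned)
  # and keeps the input/output contract after real fine-tuning
  ft2 <- fine_tune(m, pt, train_config(max_epochs = 1, seed = 2))
  y <- denoise(ft2, ds$input[[1]])
  expect_equal(dim(y), dim(ds$input[[1]]))
  expect_true(all(is.finite(y)))
})

test_that("pre-training transfers to a related domain under a small budget", {
  gn <- gaussian_noise(0.1)
  specA <- phantom_spec(48, 48, n_fibers = 2, fiber_width_px = 3,
                        fiber_wiggle = 1, n_blobs = 1)
  specB <- phantom_spec(48, 48, n_fibers = 4, fiber_width_px = 6,
                        fiber_wiggle = 3, n_blobs = 2)
  wins <- 0L
  for (s in 1:10) {
    dsA <- simulate_dataset(specA, 1, gn, seed = 1000 + s, n_positions = 3)
    dsB <- simulate_dataset(specB, 1, gn, seed = 2000 + s, n_positions = 2)
    teB <- simulate_dataset(specB, 1, gn, seed = 3000 + s, n_positions = 1)
    ptA <- extract_patches(dsA, patch_config(32, 12), seed = s)
    ptB <- extract_patches(dsB, patch_config(32, 12), seed = s + 50)
    spec <- arch_spec("W5", 4, 3, 2)
    pre <- train_denoiser(ptA, spec, train_config(max_epochs = 5, seed = s))
    ft <- fine_tune(pre, ptB, train_config(max_epochs = 2, seed = s + 1))
    scratch <- train_denoiser(ptB, spec,
                              train_config(max_epochs = 2, seed = s + 1))
    p_ft <- psnr(denoise(ft, teB$input[[1]]), teB$target[[1]])
    p_sc <- psnr(denoise(scratch, teB$input[[1]]), teB$target[[1]])
    if (p_ft >= p_sc) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("ensembles average member outputs exactly", {
  base <- build_denoiser(arch_spec("W5", 4, 3, 1), seed = 1)
  base$layers <- lapply(base$layers, function(l) { l$w[] <- 0; l$b[] <- 0; l })
  members <- lapply(c(1, 2, 3, 4), function(cst) {
    m <- base
    m$layers[[3]]$b[] <- cst        # output = input + cst
    m
  })
  ens <- ensemble_model(members)
  x <- matrix(0, 16, 16)
  expect_equal(ensemble_predict(ens, x), matrix(2.5, 16, 16))
  same <- ensemble_model(replicate(4, members[[2]], simplify = FALSE))
  withr::with_seed(2, x2 <- matrix(runif(256), 16))
  expect_equal(ensemble_predict(same, x2), denoise(members[[2]], x2))
})

test_that("the ensemble MSE never exceeds the member-average MSE", {
  withr::with_seed(3, {
    x <- matrix(runif(32 * 32), 32)
    ref <- matrix(runif(32 * 32), 32)
  })
  members <- lapply(1:4, function(s)
    build_denoiser(arch_spec("DN", 3, 3, 2), seed = s))
  ens <- ensemble_model(members)
  m_mse <- sapply(members, function(m) mean((denoise(m, x) - ref)^2))
  e_mse <- mean((ensemble_predict(ens, x) - ref)^2)
  expect_lte(e_mse, mean(m_mse) + 1e-12)
  expect_lte(e_mse, max(m_mse) + 1e-12)
})

test_that("ensemble composition is validated", {
  m <- build_denoiser(arch_spec("W5", 4, 3, 1))
  expect_error(ensemble_model(list(m, m)), class = "carsdenoise_config_error")
  expect_s3_class(ensemble_model(list(m, m), strict = FALSE),
                  "denoiser_ensemble")
  m2 <- build_denoiser(arch_spec("DN", 4, 3, 2))
  expect_error(ensemble_model(list(m, m, m2, m), strict = TRUE),
               class = "carsdenoise_config_error")
})
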