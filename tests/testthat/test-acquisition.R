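test_that("the noiseless limit returns the phantom", {
  ph <- generate_phantom(tiny_phantom_spec(), seed = 3)
  frame <- simulate_frame(ph, noise_spec(photons_per_unit = 1e12,
                                         impulse_prob = 0, read_sigma = 0),
                          seed = 1)
  expect_lt(max(abs(frame - ph$intensity)), 1e-4)
})

test_that("shot noise has Poisson mean and variance", {
  cval <- 0.8
  p <- 50
  img <- matrix(cval, 320, 320)           # ~1e5 pixels
  frame <- simulate_frame(img, noise_spec(photons_per_unit = p,
                                          impulse_prob = 0, read_sigma = 0),
                          seed = 42)
  n <- length(img)
  se <- sqrt(cval / p / n)
  expect_lt(abs(mean(frame) - cval), 3 * se)
  expect_lt(abs(var(as.vector(frame)) - cval / p), 0.1 * cval / p)
})

test_that("impulse counts follow the binomial oracle", {
  pr <- 0.01
  img <- matrix(0.5, 320, 320)
  frame <- simulate_frame(img, noise_spec(photons_per_unit = 1e12,
                                          impulse_prob = pr, impulse_amp = 2,
                                          read_sigma = 0), seed = 9)
  n <- length(img)
  hits <- sum(frame > 0.5 + 1)
  expect_lt(abs(hits - n * pr), 3 * sqrt(n * pr * (1 - pr)))
})

test_that("frame averaging reduces additive variance as 1/n", {
  img <- matrix(0.5, 100, 100)
  sg <- 0.2
  for (n_frames in c(4, 25, 100)) {
    avg <- acquire_image(img, acquisition_spec(1.6, n_frames),
                         gaussian_noise(sg), seed = n_frames)
    v <- var(as.vector(avg))
    expect_lt(abs(v - sg^2 / n_frames), 0.2 * sg^2 / n_frames)
  }
})

test_that("a single-frame acquisition reproduces simulate_frame", {
  ph <- generate_phantom(tiny_phantom_spec(), seed = 2)
  a <- acquire_image(ph, acquisition_spec(1.6, 1), noise_spec(), seed = 8)
  b <- simulate_frame(ph, noise_spec(), substream_seed(8, 1))
  expect_identical(unname(as.vector(a)), as.vector(b))
})

test_that("the mean of many acquisitions converges to phantom plus impulse bias", {
  cval <- 0.5
  ns <- noise_spec(photons_per_unit = 50, impulse_prob = 0.02,
                   impulse_amp = 2, read_sigma = 0.1)
  img <- matrix(cval, 50, 50)
  n_rep <- 200
  acc <- 0
  for (r in seq_len(n_rep)) acc <- acc + simulate_frame(img, ns, seed = r)
  avg <- acc / n_rep
  expected <- cval + ns$impulse_prob * ns$impulse_amp
  # global mean over n_rep * 2500 draws
  per_frame_var <- cval / 50 + 0.1^2 +
    ns$impulse_prob * (1 - ns$impulse_prob) * ns$impulse_amp^2
  se <- sqrt(per_frame_var / (n_rep * length(img)))
  expect_lt(abs(mean(avg) - expected), 3 * se)
})

test_that("rate bookkeeping is exact for every record", {
  acq <- acquisition_spec(1.6, 3)
  expect_equal(acq$imaging_rate_ipm, 12.5)
  expect_identical(acq$imaging_rate_ipm * acq$frame_exposure_s * acq$n_frames,
                   60)
  ds <- simulate_dataset(tiny_phantom_spec(16), c(1, 3, 10),
                         gaussian_noise(), seed = 1, n_positions = 2)
  expect_equal(ds$imaging_rate_ipm * ds$frame_exposure_s * ds$n_frames,
               rep(60, nrow(ds)))
})

test_that("clean-target pairing yields one record per position with a shared ground truth", {
  ds <- simulate_dataset(tiny_phantom_spec(24), 3, gaussian_noise(),
                         seed = 4, pairing = "clean", n_positions = 5,
                         gt_frames = 20)
  expect_equal(nrow(ds), 5L)
  expect_true(all(vapply(ds$target, is.matrix, TRUE)))
  # same position, second level: target must be the same ground truth
  ds2 <- simulate_dataset(tiny_phantom_spec(24), c(3, 10), gaussian_noise(),
                          seed = 4, pairing = "clean", n_positions = 1,
                          gt_frames = 20)
  expect_identical(ds2$target[[1]], ds2$target[[2]])
})

test_that("noisy-pair mode pairs two independent acquisitions of one phantom", {
  ds <- simulate_dataset(tiny_phantom_spec(24), 2,
                         gaussian_noise(0.1), seed = 6, pairing = "noisy",
                         n_positions = 3)
  for (r in seq_len(nrow(ds))) {
    expect_false(identical(ds$input[[r]], ds$target[[r]]))
  }
  # with vanishing noise both members approach the shared phantom
  ds0 <- simulate_dataset(tiny_phantom_spec(24), 2,
                          noise_spec(1e12, 0, 1, 0), seed = 6,
                          pairing = "noisy", n_positions = 2)
  for (r in seq_len(nrow(ds0))) {
    expect_lt(max(abs(ds0$input[[r]] - ds0$target[[r]])), 1e-4)
  }
})

test_that("91 positions at 100 frames store 9100 frames", {
  ds <- simulate_dataset(tiny_phantom_spec(16, n_fibers = 1, n_blobs = 0),
                         acquisition_spec(0.9, 100), noise_spec(), seed = 1,
                         pairing = "clean", n_positions = 91, gt_frames = 2,
                         keep_frames = TRUE)
  expect_equal(sum(vapply(ds$frames, length, integer(1))), 9100L)
})

test_that("identical seeds give bit-identical datasets", {
  a <- simulate_dataset(tiny_phantom_spec(24), c(1, 4), noise_spec(),
                        seed = 31, n_positions = 2)
  b <- simulate_dataset(tiny_phantom_spec(24), c(1, 4), noise_spec(),
                        seed = 31, n_positions = 2)
  expect_identical(a, b)
})

test_that("degenerate inputs are rejected", {
  expect_error(simulate_frame(matrix(c(1, Inf), 2, 2)),
               class = "carsdenoise_data_error")
  expect_error(simulate_dataset(list(), 1), class = "carsdenoise_config_error")
  expect_error(simulate_dataset(tiny_phantom_spec(16), numeric(0)),
               class = "carsdenoise_config_error")
})
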