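# Shared fixtures, all generated in code at test time.

# Additive-Gaussian-only acquisition noise (shot noise suppressed by a very
# large photon count, no impulses).
gaussian_noise <- function(sigma = 0.1) {
  noise_spec(photons_per_unit = 1e12, impulse_prob = 0, read_sigma = sigma)
}

# Deterministic image pairs with graded correlation, used for the SSIM
# cross-implementation check (reference values frozen in
# ssim_reference.csv).
make_ssim_pairs <- function(n = 50, px = 48) {
  withr::with_seed(42, lapply(seq_len(n), function(i) {
    w <- i / (n + 1)
    a <- matrix(runif(px * px), px)
    b <- w * a + (1 - w) * matrix(runif(px * px), px)
    list(a = a, b = b)
  }))
}

# A small flat-ish phantom spec for fast acquisition tests.
tiny_phantom_spec <- function(px = 48, n_fibers = 2, n_blobs = 1) {
  phantom_spec(height_px = px, width_px = px, n_fibers = n_fibers,
               fiber_width_px = 4, fiber_wiggle = 2, n_blobs = n_blobs)
}

# Clean-target dataset with additive Gaussian noise: the standard training
# testbed (denoisable by construction, no impulse/shot confounders).
tiny_gaussian_dataset <- function(n_positions = 4, px = 96, n_frames = 1,
                                  sigma = 0.1, seed = 7, pairing = "clean") {
  simulate_dataset(tiny_phantom_spec(px, n_fibers = 3, n_blobs = 2),
                   acq_levels = n_frames, noise = gaussian_noise(sigma),
                   seed = seed, pairing = pairing, n_positions = n_positions,
                   gt_frames = 100)
}

expect_no_violation <- function(audit) {
  testthat::expect_equal(sum(audit$violation), 0L)
}
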