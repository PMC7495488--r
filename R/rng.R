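# Seed plumbing. Every stochastic operation takes one integer seed and
# derives per-position / per-frame / per-epoch substream seeds from it
# arithmetically, so datasets are reproducible element-wise and independent
# of generation order.

# Derive the i-th substream seed from a parent seed. Multiplicative
# congruential step (Lehmer / MINSTD modulus) keeps everything inside the
# positive 32-bit integer range that set.seed() accepts.
substream_seed <- function(seed, i) {
  m <- 2147483647
  s <- (as.double(seed) %% m + 1)
  ((s * 48271 + as.double(i) * 8191) %% m)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647), code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name,
                  format(lower), format(upper)),
          class = "carsdenoise_config_error")
  }
  invisible(x)
}
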