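test_that("nested splits enumerate every ordered (test, val) choice", {
  s5 <- nested_splits(letters[1:5])
  expect_equal(nrow(s5), 20L)
  s3 <- nested_splits(1:3)
  expect_equal(nrow(s3), 6L)
  for (r in seq_len(nrow(s5))) {
    ids <- c(s5$test_id[r], s5$val_id[r], s5$train_ids[[r]])
    expect_setequal(ids, letters[1:5])
    expect_equal(length(ids), 5L)
    expect_equal(anyDuplicated(ids), 0L)
    expect_equal(length(s5$train_ids[[r]]), 3L)
  }
  expect_error(nested_splits(c("a", "a", "b")),
               class = "carsdenoise_config_error")
})

test_that("grid search returns the single combination of a singleton space", {
  ds <- tiny_gaussian_dataset(n_positions = 2, px = 48)
  pt <- extract_patches(ds, patch_config(32, 8), seed = 1)
  va <- extract_patches(ds, patch_config(32, 4), seed = 2)
  space <- tibble::tibble(family = "W5", n_filters_F = 4L, kernel_K = 3L,
                          n_layers_L = 1L)
  out <- grid_search(space, pt, va, train_config(max_epochs = 1, seed = 1))
  expect_equal(out$best_spec$n_filters_F, 4L)
  expect_equal(nrow(out$results), 1L)
})

test_that("grid-search ties break to the first combination in canonical order", {
  ds <- tiny_gaussian_dataset(n_positions = 2, px = 48)
  pt <- extract_patches(ds, patch_config(32, 8), seed = 1)
  va <- extract_patches(ds, patch_config(32, 4), seed = 2)
  row <- tibble::tibble(family = "W5", n_filters_F = 4L, kernel_K = 3L,
                        n_layers_L = 1L)
  space <- dplyr::bind_rows(dplyr::mutate(row, n_layers_L = 1L), row)
  out <- grid_search(space, pt, va, train_config(max_epochs = 1, seed = 1))
  expect_equal(out$results$score[1], out$results$score[2])
  expect_equal(out$best_spec$n_layers_L, space$n_layers_L[1])
})

test_that("capacity wins a grid search when it strictly helps", {
  wins <- 0L
  space <- tibble::tibble(family = "W5", n_filters_F = c(2L, 8L),
                          kernel_K = 3L, n_layers_L = c(1L, 2L))
  for (s in 1:10) {
    ds <- tiny_gaussian_dataset(n_positions = 3, px = 48, sigma = 0.15,
                                seed = 500 + s)
    pt <- extract_patches(ds, patch_config(32, 15), seed = s)
    va <- extract_patches(ds, patch_config(32, 5), seed = s + 20)
    out <- grid_search(space, pt, va, train_config(max_epochs = 5, seed = s))
    if (out$best_spec$n_filters_F == 8L) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("friedman test handles the null, a worked example, and a clear winner", {
  # identical columns: no evidence of any difference
  m0 <- matrix(rep(c(1, 2, 3, 4, 5), 3), 5, 3)
  r0 <- suppressWarnings(friedman_rank_test(m0))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # textbook 4 subjects x 3 treatments, no ties; per-subject ranks
  # (1,2,3), (1,3,2), (3,1,2), (1,3,2) give column sums R = (6, 9, 9),
  # Q = 12/(4*3*4) * sum(R^2) - 3*4*4 = 1.5
  m1 <- rbind(c(1.0, 2.0, 3.0),
              c(1.5, 2.5, 2.0),
              c(4.0, 1.0, 3.0),
              c(2.0, 6.0, 5.0))
  r1 <- friedman_rank_test(m1)
  expect_equal(r1$statistic, 1.5, tolerance = 1e-10)
  expect_equal(unname(attr(r1, "mean_ranks")),
               c(6, 9, 9) / 4, tolerance = 1e-12)

  # one model dominant by a margin: small p
  withr::with_seed(11, {
    base <- matrix(rnorm(20, 30, 0.3), 5, 4)
    base[, 2] <- base[, 2] + 3
  })
  r2 <- friedman_rank_test(base)
  expect_lt(r2$p_value, 0.05)
})

test_that("the chi-squared statistic matches the internal permutation statistic", {
  withr::with_seed(12, m <- matrix(rnorm(20), 5, 4))
  r <- friedman_rank_test(m)
  expect_equal(carsdenoise:::friedman_stat(m), r$statistic,
               tolerance = 1e-12)
})

test_that("paired t-test matches the t-distribution oracle and is symmetric", {
  b <- c(10, 20, 30, 40, 50)
  a <- b + c(1, 1, 1, 1, 2)
  res <- paired_t(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 4)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-8)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-8)
  expect_equal(paired_t(b, a)$p_value, res$p_value)
  expect_error(paired_t(b, b), class = "carsdenoise_degenerate_error")
  expect_error(paired_t(1, 1:2), class = "carsdenoise_data_error")
})

test_that("Holm correction steps down correctly", {
  out <- holm_adjust(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_equal(out$reject, c(TRUE, FALSE, FALSE))   # 0.03 > 0.05 / 2
  expect_equal(out$p_adjusted, p.adjust(c(0.01, 0.03, 0.04), "holm"))

  # boundary: all p equal to alpha / m are rejected at the first step
  out2 <- holm_adjust(rep(0.05 / 3, 3), alpha = 0.05)
  expect_true(all(out2$reject))

  # single p behaves like the uncorrected test
  out3 <- holm_adjust(0.04, alpha = 0.05)
  expect_true(out3$reject)
  expect_equal(out3$p_adjusted, 0.04)

  expect_error(holm_adjust(c(0.5, 1.2)), class = "carsdenoise_data_error")
})

test_that("Holm rejects a superset of Bonferroni on random p vectors", {
  withr::with_seed(13, {
    for (i in 1:20) {
      p <- runif(8)^2
      holm <- holm_adjust(p, alpha = 0.05)$reject
      bonf <- p <= 0.05 / length(p)
      expect_true(all(holm[bonf]))
    }
  })
})

test_that("the protocol trains one model per split with no leakage", {
  ds <- tiny_gaussian_dataset(n_positions = 5, px = 48)
  pre_pt <- extract_patches(ds, patch_config(32, 4), seed = 1)
  pre <- train_denoiser(pre_pt, arch_spec("W5", 2, 3, 1),
                        train_config(max_epochs = 1, seed = 1))
  out <- run_protocol(ds, arch_spec("W5", 2, 3, 1),
                      train_config(max_epochs = 0, seed = 2),
                      patch_config(32, 2),
                      styles = c("microscopy", "finetune", "ensemble"),
                      pretrained = pre)
  expect_equal(nrow(out$plans), 20L)
  expect_length(grep("^finetune_", names(out$models)), 20L)
  expect_no_violation(out$leakage_audit)
  # every test position is served by exactly 4 plans
  expect_true(all(table(out$plans$test_id) == 4L))
  # tidy results: styles x positions x metrics
  expect_setequal(unique(out$results$style),
                  c("microscopy", "finetune", "ensemble"))
  summ <- summarise_protocol(out$results)
  expect_true(all(is.finite(summ$mean)))
  # pre-training is required for styles that use it
  expect_error(run_protocol(ds, arch_spec("W5", 2, 3, 1),
                            styles = "finetune"),
               class = "carsdenoise_config_error")
})
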