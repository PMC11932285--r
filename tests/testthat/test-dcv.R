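test_that("figures of merit follow the confusion arithmetic exactly", {
  # hand-computed oracle: TP=10, TN=12, FP=1, FN=2
  f <- urinmr:::.figures_from_confusion(10, 12, 1, 2)
  expect_equal(unname(f["sensitivity"]), 100 * 10 / 12, tolerance = 1e-12)
  expect_equal(round(unname(f["sensitivity"]), 1), 83.3)
  expect_equal(round(unname(f["specificity"]), 1), 92.3)
  expect_equal(round(unname(f["accuracy"]), 1), 88.0)
})

test_that("widely separated classes classify perfectly under double CV", {
  d <- shifted_groups(n_ctrl = 13, n_exp = 12, p = 5, shift = 10, seed = 51)
  res <- double_cross_validate(d$X, d$y, dcv_config(seed = 52))
  expect_true(all(res$figures$accuracy == 100))
  expect_true(all(res$figures$sensitivity == 100))
  expect_true(all(res$figures$specificity == 100))
  expect_true(all(res$figures$percent_correct == 100))
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(53)
  X <- matrix(rnorm(25 * 5), 25, 5)
  y <- sample(rep(c(1, -1), c(12, 13)))
  res <- double_cross_validate(X, y, dcv_config(seed = 54))
  m <- mean(res$figures$accuracy)
  expect_gte(m, 35)
  expect_lte(m, 65)
})

test_that("per-repetition accuracy always matches pooled confusion counts", {
  d <- shifted_groups(p = 8, k = 2, shift = 1, seed = 55)
  res <- double_cross_validate(d$X, d$y, dcv_config(seed = 56))
  with(res, {
    expect_equal(figures$accuracy,
                 100 * (confusion$TP + confusion$TN) / n, tolerance = 1e-12)
    expect_true(all(confusion$TP + confusion$TN + confusion$FP +
                      confusion$FN == n))
  })
  expect_true(all(res$figures >= 0 & res$figures <= 100))
})

test_that("double CV is bit-for-bit reproducible under a fixed seed", {
  d <- shifted_groups(p = 6, k = 3, shift = 0.8, seed = 57)
  cfg <- dcv_config(n_repetitions = 5, seed = 58)
  r1 <- double_cross_validate(d$X, d$y, cfg)
  r2 <- double_cross_validate(d$X, d$y, cfg)
  expect_identical(r1, r2)
  r3 <- double_cross_validate(d$X, d$y, dcv_config(n_repetitions = 5,
                                                   seed = 59))
  expect_false(identical(r1$folds, r3$folds))
})

test_that("held-out subjects never contribute to their model's scaling", {
  d <- shifted_groups(p = 6, k = 3, shift = 1, seed = 60)
  cfg <- dcv_config(n_repetitions = 3, seed = 61)
  res <- double_cross_validate(d$X, d$y, cfg)
  for (r in seq_len(cfg$n_repetitions)) {
    fold <- res$folds[r, ]
    for (f in seq_len(cfg$outer_folds)) {
      stored <- res$scaling[[(r - 1) * cfg$outer_folds + f]]
      tr <- which(fold != f)
      expect_equal(stored$means, colMeans(d$X[tr, , drop = FALSE]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(stored$sds, apply(d$X[tr, , drop = FALSE], 2, sd),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("inner latent-variable choice is recorded and capped", {
  d <- shifted_groups(p = 4, k = 2, shift = 1, seed = 62)
  cfg <- dcv_config(n_repetitions = 2, max_lv = 10, seed = 63)
  res <- double_cross_validate(d$X, d$y, cfg)
  expect_true(all(res$chosen_n_lv >= 1 & res$chosen_n_lv <= 4))
})

test_that("degenerate class sizes are rejected", {
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- rep(c(1, -1), c(2, 6))
  expect_error(double_cross_validate(X, y, dcv_config(outer_folds = 5)),
               "at least")
  expect_error(double_cross_validate(X, rep(1, 8), dcv_config()),
               "both classes")
})
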