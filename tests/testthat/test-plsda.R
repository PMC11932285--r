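test_that("first weight vector is the normalized covariance with the class
           code and concentrates on the informative variable", {
  set.seed(41)
  n <- 20
  y <- rep(c(1, -1), each = n / 2)
  X <- cbind(y + rnorm(n, sd = 0.1), matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("V", 1:5)
  Xs <- autoscale(X)$X
  m <- pls_da_fit(Xs, y, n_lv = 2)
  # direct-formula oracle: w1 = X'y / ||X'y|| (columns centred)
  w_oracle <- drop(crossprod(Xs, y - mean(y)))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(m$W[, 1]), abs(w_oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(which.max(abs(m$W[, 1])), 1L, ignore_attr = TRUE)
  # score columns mutually orthogonal
  G <- crossprod(m$T)
  off <- G - diag(diag(G))
  expect_true(max(abs(off)) / max(diag(G)) < 1e-8)
})

test_that("full-complexity PLS reproduces the least-squares fit", {
  set.seed(42)
  n <- 12; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c(1, -1), length.out = n)
  Xs <- autoscale(X)
  m <- pls_da_fit(Xs$X, y, n_lv = p)
  ols <- stats::lm.fit(cbind(1, Xs$X), y)
  pred_pls <- predict(m, Xs$X)
  pred_ols <- drop(cbind(1, Xs$X) %*% ols$coefficients)
  expect_equal(pred_pls, pred_ols, tolerance = 1e-8)
})

test_that("continuous predictions agree with an independent reference PLS
           implementation on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10; p <- 5
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
    y <- rep(c(1, -1), each = 5)
    Xnew <- matrix(rnorm(6 * p), 6, p, dimnames = list(NULL, paste0("V", 1:p)))
    for (A in 1:3) {
      m <- pls_da_fit(X, y, n_lv = A)
      ref <- mixOmics::pls(X, y, ncomp = A, scale = FALSE,
                           mode = "regression")
      pred_ref <- predict(ref, Xnew)$predict[, , A]
      expect_equal(predict(m, Xnew), unname(pred_ref), tolerance = 1e-8)
    }
  }
})

test_that("classification separates well-separated clusters and breaks
           threshold ties toward the exposed class", {
  d <- shifted_groups(shift = 10, seed = 43)
  sc <- autoscale(d$X)
  m <- pls_da_fit(sc$X, d$y, n_lv = 2)
  expect_equal(as.integer(classify(m, sc$X)),
               ifelse(d$y > 0, 2L, 1L))  # levels CTRL=1, Exposed=2
  # a prediction exactly at the threshold goes to Exposed
  m0 <- m
  m0$B[] <- 0; m0$y_mean <- 0
  expect_true(all(classify(m0, sc$X) == "Exposed"))
  expect_error(predict(m, sc$X[, 1:3]), "columns")
})

test_that("degenerate responses are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(pls_da_fit(X, rep(1, 10), 1), "both classes")
  expect_error(pls_da_fit(X, rep(c(1, -1), 5), 5), "n_lv")
})
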