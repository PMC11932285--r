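#' Fit a two-class PLS-DA model
#'
#' PLS1 regression of the class code on the (autoscaled) data matrix by the
#' NIPALS algorithm, used as a classifier. Class coding is +1 = Exposed,
#' -1 = CTRL; the response is mean-centred internally. For every number of
#' components `a <= n_lv` the regression coefficient vector
#' `b_a = W_a (P_a' W_a)^{-1} q_a` is stored, so nested cross-validation can
#' evaluate all model complexities from a single fit.
#'
#' The two-class PLS-DA discriminant subspace is one-dimensional; its
#' canonical representative — the "weights on CV1" — is taken as the
#' coefficient vector `b` at the chosen complexity, normalized to unit
#' length, with sign fixed so that the exposed-class training centroid
#' projects positive (`cv1 = "coefficients"`). The first NIPALS weight
#' vector `w1` is available as an alternative convention.
#'
#' @param X_scaled numeric matrix, subjects x variables, autoscaled
#'   (see [autoscale()]).
#' @param y numeric vector of +1/-1 class codes (both classes present), or
#'   a factor with levels CTRL/Exposed.
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param cv1 convention for the CV1 weight vector: `"coefficients"`
#'   (default) or `"w1"`.
#' @return object of class `plsda_model`: weights `W` (p x A), loadings `P`,
#'   scores `T`, y-loadings `q`, per-complexity coefficients `B` (p x A),
#'   coefficient vector `b` (= `B[, n_lv]`), `cv1_weights`, centring
#'   constants and `class_threshold` (0).
#' @export
pls_da_fit <- function(X_scaled, y, n_lv, cv1 = c("coefficients", "w1")) {
  cv1 <- match.arg(cv1)
  X <- as.matrix(X_scaled)
  if (inherits(X, "scaled_matrix")) X <- X_scaled$X
  if (is.factor(y)) y <- ifelse(y == "Exposed", 1, -1)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop("`y` must contain both classes coded +1/-1", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  n_lv <- as.integer(n_lv)
  if (is.na(n_lv) || n_lv < 1L || n_lv > min(n - 1L, p)) {
    stop(sprintf("`n_lv` must be in 1..min(n-1, p) = %d", min(n - 1L, p)),
         call. = FALSE)
  }
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xd <- sweep(X, 2, x_means)
  yd <- y - y_mean
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop("degenerate deflated matrix: cannot extract component ", a,
           call. = FALSE)
    }
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    pv <- drop(crossprod(Xd, t_)) / tt
    qa <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, pv)
    yd <- yd - t_ * qa
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t_; q[a] <- qa
  }
  # coefficients for every truncation a = 1..n_lv
  B <- matrix(0, p, n_lv)
  for (a in seq_len(n_lv)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  b <- B[, n_lv]
  cv1_w <- if (cv1 == "coefficients") b else W[, 1]
  nb <- sqrt(sum(cv1_w^2))
  if (nb > 0) cv1_w <- cv1_w / nb
  # sign convention: exposed centroid projects positive
  proj <- drop(sweep(X[y > 0, , drop = FALSE], 2, x_means) %*% cv1_w)
  if (mean(proj) < 0) cv1_w <- -cv1_w
  if (!is.null(colnames(X))) {
    rownames(W) <- rownames(P) <- rownames(B) <- colnames(X)
    names(b) <- names(cv1_w) <- colnames(X)
  }
  structure(list(n_lv = n_lv, W = W, P = P, T = Tm, q = q, B = B, b = b,
                 cv1_weights = cv1_w, cv1_convention = cv1,
                 x_means = x_means, y_mean = y_mean,
                 class_threshold = 0),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d latent variable(s), %d variables, CV1 = %s\n",
              x$n_lv, nrow(x$W), x$cv1_convention))
  invisible(x)
}

#' Predict continuous PLS-DA responses
#'
#' @param object a `plsda_model`.
#' @param newdata matrix scaled with the model's training statistics.
#' @param n_lv model complexity to use (default the fitted `n_lv`).
#' @param ... unused.
#' @return numeric vector of continuous predicted class codes.
#' @export
predict.plsda_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$B)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(X), nrow(object$B)), call. = FALSE)
  }
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > object$n_lv) {
    stop("`n_lv` out of fitted range", call. = FALSE)
  }
  drop(sweep(X, 2, object$x_means) %*% object$B[, n_lv]) + object$y_mean
}

#' Classify new observations with a PLS-DA model
#'
#' Labels are the sign of the continuous prediction relative to the class
#' threshold (0 for +1/-1 coding). Predictions exactly at the threshold are
#' deterministically assigned to the positive (Exposed) class.
#'
#' @inheritParams predict.plsda_model
#' @param model a `plsda_model`.
#' @param X_new matrix scaled with the model's training statistics.
#' @return factor of predicted labels with levels CTRL, Exposed.
#' @export
classify <- function(model, X_new, n_lv = model$n_lv) {
  yhat <- predict(model, X_new, n_lv = n_lv)
  factor(ifelse(yhat >= model$class_threshold, "Exposed", "CTRL"),
         levels = .GROUP_LEVELS)
}
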