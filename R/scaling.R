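#' Autoscale a data matrix
#'
#' Unit-variance scaling: each column is centred and divided by its
#' standard deviation. In fit mode the statistics are estimated from `X`
#' itself; in transform mode (test-set contract) reference means and
#' standard deviations from a training set are applied unchanged.
#'
#' @param X numeric matrix, subjects x variables.
#' @param reference_means,reference_sds optional training statistics; both
#'   must be supplied together.
#' @return object of class `scaled_matrix`: list with `X` (scaled matrix),
#'   `column_means`, `column_sds`.
#' @export
#' @examples
#' s <- autoscale(matrix(rnorm(40), 10, 4))
#' colMeans(s$X)  # ~0
autoscale <- function(X, reference_means = NULL, reference_sds = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) {
    stop("`X` must be a finite numeric matrix", call. = FALSE)
  }
  if (xor(is.null(reference_means), is.null(reference_sds))) {
    stop("supply both or neither of reference_means / reference_sds",
         call. = FALSE)
  }
  if (is.null(reference_means)) {
    mu <- colMeans(X)
    sd_ <- apply(X, 2, stats::sd)
    zero <- which(sd_ == 0 | !is.finite(sd_))
    if (length(zero)) {
      nm <- colnames(X)[zero]
      if (is.null(nm)) nm <- as.character(zero)
      stop("zero-variance column(s): ", paste(nm, collapse = ", "),
           call. = FALSE)
    }
  } else {
    if (length(reference_means) != ncol(X) ||
        length(reference_sds) != ncol(X)) {
      stop("reference statistics must match ncol(X)", call. = FALSE)
    }
    if (any(reference_sds <= 0)) {
      stop("reference sds must be > 0", call. = FALSE)
    }
    mu <- reference_means; sd_ <- reference_sds
  }
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
  structure(list(X = Xs, column_means = as.numeric(mu),
                 column_sds = as.numeric(sd_)),
            class = "scaled_matrix")
}

#' Principal component analysis of a scaled matrix
#'
#' Thin wrapper assembling scores, loadings and explained-variance
#' fractions from the singular value decomposition of a column-centred
#' (typically autoscaled) matrix. Fractions are reported over
#' `min(n - 1, p)` components and sum to one.
#'
#' @param X_scaled numeric matrix with centred columns (e.g. `$X` of an
#'   [autoscale()] result).
#' @param n_components number of components to return (default all).
#' @return list with `scores` (n x k), `loadings` (p x k) and
#'   `explained_variance` (length min(n-1, p) fractions).
#' @export
pca <- function(X_scaled, n_components = NULL) {
  X_scaled <- as.matrix(X_scaled)
  if (length(X_scaled) == 0L) stop("empty matrix", call. = FALSE)
  if (max(abs(colMeans(X_scaled))) > 1e-8) {
    stop("`X_scaled` must be column-centred", call. = FALSE)
  }
  n <- nrow(X_scaled); p <- ncol(X_scaled)
  kmax <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- kmax
  n_components <- min(as.integer(n_components), kmax)
  pc <- stats::prcomp(X_scaled, center = FALSE, scale. = FALSE)
  ev <- pc$sdev[seq_len(kmax)]^2
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = ev / sum(ev))
}
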