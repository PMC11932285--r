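#' Configure repeated double cross-validation
#'
#' Defaults follow common chemometrics practice for nested validation of
#' PLS-DA models on small cohorts: 20 repetitions of 5 stratified outer
#' folds, each with 5 stratified inner folds selecting the number of latent
#' variables that minimizes the inner misclassification rate (ties broken
#' toward fewer latent variables).
#'
#' @param n_repetitions repetitions of the whole double-CV scheme.
#' @param outer_folds,inner_folds fold counts (>= 2).
#' @param max_lv maximum latent variables considered; capped per fit at
#'   `min(n_train - 1, p)`.
#' @param seed master seed; all fold shuffles derive from it.
#' @param stratified stratify folds by class (default TRUE).
#' @param global_scaling if TRUE, autoscale once on the full matrix before
#'   splitting (single-block convention); default FALSE refits the scaler
#'   inside every outer-training set so held-out subjects never contribute
#'   to scaling statistics.
#' @param cv1 CV1 weight convention passed to [pls_da_fit()].
#' @return object of class `dcv_config`.
#' @export
dcv_config <- function(n_repetitions = 20L, outer_folds = 5L,
                       inner_folds = 5L, max_lv = 5L, seed = 1L,
                       stratified = TRUE, global_scaling = FALSE,
                       cv1 = c("coefficients", "w1")) {
  cv1 <- match.arg(cv1)
  n_repetitions <- as.integer(n_repetitions)
  outer_folds <- as.integer(outer_folds)
  inner_folds <- as.integer(inner_folds)
  max_lv <- as.integer(max_lv)
  if (n_repetitions < 1L) stop("`n_repetitions` must be >= 1", call. = FALSE)
  if (outer_folds < 2L || inner_folds < 2L) {
    stop("fold counts must be >= 2", call. = FALSE)
  }
  if (max_lv < 1L) stop("`max_lv` must be >= 1", call. = FALSE)
  structure(list(n_repetitions = n_repetitions, outer_folds = outer_folds,
                 inner_folds = inner_folds, max_lv = max_lv,
                 seed = as.integer(seed), stratified = isTRUE(stratified),
                 global_scaling = isTRUE(global_scaling), cv1 = cv1),
            class = "dcv_config")
}

# Fold assignment: stratified splits each class's shuffled indices round-
# robin over k folds so fold sizes differ by at most one per class.
.make_folds <- function(y, k, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        stop(sprintf("class with %d members cannot fill %d folds",
                     length(idx), k), call. = FALSE)
      }
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

# figures of merit (percent) from pooled confusion counts; sensitivity is
# the true-Exposed rate, specificity the true-CTRL rate, percent_correct
# the class-balanced mean of the two
.figures_from_confusion <- function(tp, tn, fp, fn) {
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  c(sensitivity = sens, specificity = spec,
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    percent_correct = (sens + spec) / 2)
}

# misclassification rate of sign predictions for each complexity a
.miscls_by_lv <- function(model, X_test_scaled, y_test, a_max) {
  vapply(seq_len(a_max), function(a) {
    yhat <- predict(model, X_test_scaled, n_lv = a)
    pred <- ifelse(yhat >= 0, 1, -1)
    mean(pred != y_test)
  }, numeric(1))
}

#' Repeated double cross-validation of a PLS-DA classifier
#'
#' Nested (double) cross-validation: for each repetition the subjects are
#' split into stratified outer folds; within each outer-training set an
#' inner cross-validation selects the number of latent variables minimizing
#' the mean inner misclassification rate; the model is refit on the full
#' outer-training set (autoscaling refit there, unless
#' `global_scaling = TRUE`) and applied to the untouched outer fold.
#' Figures of merit — sensitivity, specificity, accuracy and percentage of
#' correct classification — are computed per repetition from the pooled
#' outer predictions and summarized as mean +/- sd across repetitions. The
#' CV1 weight vector of every outer-fold model is collected for
#' stability-based variable selection.
#'
#' Sensitivity is the true-Exposed rate, specificity the true-CTRL rate,
#' accuracy the pooled fraction correct; percentage of correct
#' classification is the class-balanced mean of sensitivity and
#' specificity. All are percentages in [0, 100].
#'
#' @param X a `conc_matrix` data.frame, or a numeric matrix (then `y` is
#'   required).
#' @param y class labels (factor CTRL/Exposed or +1/-1), ignored when `X`
#'   is a `conc_matrix`.
#' @param config a [dcv_config].
#' @return object of class `dcv_result`: `figures` (per-repetition
#'   data.frame), `summary` (mean and sd per figure of merit), `confusion`
#'   (per-repetition pooled TP/TN/FP/FN counts), `cv1_weight_samples`
#'   (one row per outer-fold model), `chosen_n_lv`, `folds` (outer fold
#'   assignments per repetition), `scaling` (per-model means/sds) and the
#'   config echo.
#' @export
double_cross_validate <- function(X, y = NULL, config = dcv_config()) {
  stopifnot(inherits(config, "dcv_config"))
  if (is.data.frame(X) && all(c("subject_id", "group") %in% names(X))) {
    y <- X$group
    X <- conc_values(X)
  }
  X <- as.matrix(X)
  if (is.null(y)) stop("`y` is required when X is a plain matrix",
                       call. = FALSE)
  if (is.factor(y) || is.character(y)) {
    y <- ifelse(as.character(y) == "Exposed", 1, -1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop("labels must contain both classes (CTRL / Exposed)", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (min(table(y)) < config$outer_folds) {
    stop("each class must have at least `outer_folds` members", call. = FALSE)
  }
  rep_seeds <- derive_seeds(config$seed, config$n_repetitions)

  n_models <- config$n_repetitions * config$outer_folds
  weight_samples <- matrix(NA_real_, n_models, p,
                           dimnames = list(NULL, colnames(X)))
  chosen_lv <- matrix(NA_integer_, config$n_repetitions, config$outer_folds)
  folds_all <- matrix(NA_integer_, config$n_repetitions, n)
  scaling <- vector("list", n_models)
  figures <- data.frame(sensitivity = numeric(config$n_repetitions),
                        specificity = numeric(config$n_repetitions),
                        accuracy = numeric(config$n_repetitions),
                        percent_correct = numeric(config$n_repetitions))
  confusion <- data.frame(TP = integer(config$n_repetitions),
                          TN = integer(config$n_repetitions),
                          FP = integer(config$n_repetitions),
                          FN = integer(config$n_repetitions))
  model_names <- character(n_models)

  global_scaler <- if (config$global_scaling) autoscale(X)

  for (r in seq_len(config$n_repetitions)) {
    res_r <- with_seed(rep_seeds[r], {
      outer_fold <- .make_folds(y, config$outer_folds, config$stratified)
      pred <- numeric(n)
      lv_r <- integer(config$outer_folds)
      w_r <- matrix(NA_real_, config$outer_folds, p)
      sc_r <- vector("list", config$outer_folds)
      for (f in seq_len(config$outer_folds)) {
        tr <- which(outer_fold != f)
        te <- which(outer_fold == f)
        X_tr <- X[tr, , drop = FALSE]; y_tr <- y[tr]
        # inner CV over the outer-training set only
        inner_fold <- .make_folds(y_tr, config$inner_folds, config$stratified)
        a_cap <- min(config$max_lv, p)
        err <- matrix(NA_real_, config$inner_folds, a_cap)
        for (g in seq_len(config$inner_folds)) {
          itr <- which(inner_fold != g)
          ite <- which(inner_fold == g)
          a_fit <- min(a_cap, length(itr) - 1L)
          sc <- if (config$global_scaling) {
            list(X = global_scaler$X[tr[itr], , drop = FALSE],
                 column_means = global_scaler$column_means,
                 column_sds = global_scaler$column_sds)
          } else {
            autoscale(X_tr[itr, , drop = FALSE])
          }
          m <- pls_da_fit(sc$X, y_tr[itr], n_lv = a_fit, cv1 = config$cv1)
          Xi_te <- autoscale(X_tr[ite, , drop = FALSE],
                             reference_means = sc$column_means,
                             reference_sds = sc$column_sds)$X
          err[g, seq_len(a_fit)] <- .miscls_by_lv(m, Xi_te, y_tr[ite], a_fit)
        }
        mean_err <- colMeans(err, na.rm = TRUE)
        a_star <- which.min(mean_err)  # which.min takes the first minimum:
                                       # ties resolve to fewer latent variables
        # refit on the full outer-training set
        sc_tr <- if (config$global_scaling) {
          list(X = global_scaler$X[tr, , drop = FALSE],
               column_means = global_scaler$column_means,
               column_sds = global_scaler$column_sds)
        } else {
          autoscale(X_tr)
        }
        a_star <- min(a_star, length(tr) - 1L)
        m_out <- pls_da_fit(sc_tr$X, y_tr, n_lv = a_star, cv1 = config$cv1)
        X_te <- autoscale(X[te, , drop = FALSE],
                          reference_means = sc_tr$column_means,
                          reference_sds = sc_tr$column_sds)$X
        pred[te] <- predict(m_out, X_te)
        lv_r[f] <- a_star
        w_r[f, ] <- m_out$cv1_weights
        sc_r[[f]] <- list(means = sc_tr$column_means, sds = sc_tr$column_sds)
      }
      list(outer_fold = outer_fold, pred = pred, lv = lv_r, w = w_r,
           sc = sc_r)
    })
    pred_lab <- ifelse(res_r$pred >= 0, 1, -1)
    tp <- sum(pred_lab == 1 & y == 1); tn <- sum(pred_lab == -1 & y == -1)
    fp <- sum(pred_lab == 1 & y == -1); fn <- sum(pred_lab == -1 & y == 1)
    figures[r, ] <- .figures_from_confusion(tp, tn, fp, fn)
    confusion[r, ] <- c(tp, tn, fp, fn)
    folds_all[r, ] <- res_r$outer_fold
    chosen_lv[r, ] <- res_r$lv
    rows <- (r - 1L) * config$outer_folds + seq_len(config$outer_folds)
    weight_samples[rows, ] <- res_r$w
    scaling[rows] <- res_r$sc
    model_names[rows] <- sprintf("rep%02d_fold%d", r,
                                 seq_len(config$outer_folds))
  }
  rownames(weight_samples) <- model_names
  names(scaling) <- model_names
  summary_tab <- data.frame(
    figure = names(figures),
    mean = vapply(figures, mean, numeric(1)),
    sd = vapply(figures, stats::sd, numeric(1)),
    row.names = NULL
  )
  structure(list(figures = figures, summary = summary_tab,
                 confusion = confusion,
                 cv1_weight_samples = weight_samples,
                 chosen_n_lv = chosen_lv, folds = folds_all,
                 scaling = scaling, n = n, config = config),
            class = "dcv_result")
}

#' @export
print.dcv_result <- function(x, ...) {
  cat(sprintf("<dcv_result> %d repetition(s) x %d outer fold(s), n = %d\n",
              x$config$n_repetitions, x$config$outer_folds, x$n))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s %5.1f +/- %.1f %%\n", s$figure[i], s$mean[i],
                s$sd[i]))
  }
  invisible(x)
}
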