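#' Stability-based selection of discriminant variables
#'
#' A variable is considered significant for the discrimination when its
#' weight on the first canonical variate (CV1) keeps a consistent sign in
#' every cross-validation model and the percentile confidence interval of
#' those weights does not cross zero. Selected variables are assigned to
#' the group toward which their weight points: positive weights (the
#' Exposed-positive sign convention of [pls_da_fit()]) mark metabolites
#' higher in the exposed class, negative weights metabolites higher in
#' controls.
#'
#' @param result a [double_cross_validate()] result (>= 2 weight samples
#'   per variable), or a numeric matrix of CV1 weight samples
#'   (models x variables).
#' @param ci_level confidence level of the percentile interval
#'   (default 0.95).
#' @return data.frame of class `selection_report`, one row per variable:
#'   `variable`, `median_weight`, `ci_lo`, `ci_hi`, `sign_consistency`
#'   (fraction of samples sharing the majority sign), `selected`, `group`
#'   ("Exposed" or "CTRL" per the sign convention).
#' @export
select_significant_variables <- function(result, ci_level = 0.95) {
  W <- if (inherits(result, "dcv_result")) result$cv1_weight_samples
       else as.matrix(result)
  if (!is.numeric(W) || nrow(W) < 2L) {
    stop("need at least 2 CV1 weight samples per variable", call. = FALSE)
  }
  stopifnot_scalar_number(ci_level, "ci_level")
  if (ci_level <= 0 || ci_level >= 1) {
    stop("`ci_level` must be in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - ci_level
  vars <- colnames(W)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(W)))
  med <- apply(W, 2, stats::median)
  ci <- apply(W, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  pos <- colMeans(W > 0)
  neg <- colMeans(W < 0)
  sign_cons <- pmax(pos, neg)
  all_same_sign <- (pos == 1) | (neg == 1)
  excludes_zero <- (ci[1, ] > 0) | (ci[2, ] < 0)
  selected <- all_same_sign & excludes_zero
  out <- data.frame(
    variable = vars,
    median_weight = as.numeric(med),
    ci_lo = as.numeric(ci[1, ]),
    ci_hi = as.numeric(ci[2, ]),
    sign_consistency = as.numeric(sign_cons),
    selected = selected,
    group = ifelse(med >= 0, "Exposed", "CTRL"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "ci_level") <- ci_level
  class(out) <- c("selection_report", "data.frame")
  out
}
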