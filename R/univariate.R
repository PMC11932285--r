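#' Distribution-routed two-sample test for one metabolite
#'
#' Evaluates normality (Shapiro-Wilk per group) and homoscedasticity
#' (Levene's test, median-centred) at `alpha_assumptions`; when both groups
#' are compatible with normality and the variances with homogeneity, an
#' equal-variance two-sample Student's t-test is applied, otherwise the
#' Wilcoxon rank-sum test. Two-sided p-values throughout. The Wilcoxon
#' branch uses the normal approximation with tie correction and continuity
#' correction except when both groups have n <= 10 and no ties, where the
#' exact distribution is used.
#'
#' Constant data in both groups makes either test undefined: identical
#' constants return a flagged result with p = 1; distinct constants route
#' to the Wilcoxon branch (complete separation).
#'
#' @param x_ctrl,x_exposed numeric vectors (each n >= 3, no missing values).
#' @param alpha_assumptions significance level of the assumption checks
#'   (default 0.05).
#' @param metabolite name recorded in the result.
#' @return one-row data.frame: `metabolite`, `test_used` ("t"/"wilcoxon"),
#'   `statistic`, `p_value`, `direction` ("up_in_exposed"/
#'   "down_in_exposed"), `significant` (p < 0.05), `flagged` (degenerate
#'   input).
#' @export
#' @examples
#' route_and_test(rnorm(13, 10), rnorm(12, 12))
route_and_test <- function(x_ctrl, x_exposed, alpha_assumptions = 0.05,
                           metabolite = "variable") {
  if (anyNA(x_ctrl) || anyNA(x_exposed)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (length(x_ctrl) < 3L || length(x_exposed) < 3L) {
    stop("each group must have n >= 3", call. = FALSE)
  }
  med_c <- stats::median(x_ctrl); med_e <- stats::median(x_exposed)
  direction <- if (med_e > med_c) {
    "up_in_exposed"
  } else if (med_e < med_c) {
    "down_in_exposed"
  } else if (mean(x_exposed) >= mean(x_ctrl)) {
    "up_in_exposed"
  } else {
    "down_in_exposed"
  }
  const_c <- stats::sd(x_ctrl) == 0
  const_e <- stats::sd(x_exposed) == 0
  if (const_c && const_e && x_ctrl[1] == x_exposed[1]) {
    return(data.frame(metabolite = metabolite, test_used = "none",
                      statistic = NA_real_, p_value = 1,
                      direction = direction, significant = FALSE,
                      flagged = TRUE, stringsAsFactors = FALSE))
  }
  normal <- if (const_c || const_e) {
    FALSE  # a constant group is not compatible with a continuous normal
  } else {
    stats::shapiro.test(x_ctrl)$p.value > alpha_assumptions &&
      stats::shapiro.test(x_exposed)$p.value > alpha_assumptions
  }
  homoscedastic <- if (const_c && const_e) {
    TRUE
  } else {
    g <- factor(rep(c("CTRL", "Exposed"),
                    c(length(x_ctrl), length(x_exposed))))
    lev <- car::leveneTest(c(x_ctrl, x_exposed) ~ g, center = stats::median)
    lev[["Pr(>F)"]][1] > alpha_assumptions
  }
  if (normal && homoscedastic) {
    ht <- stats::t.test(x_exposed, x_ctrl, var.equal = TRUE)
    test_used <- "t"
  } else {
    exact_ok <- max(length(x_ctrl), length(x_exposed)) <= 10L &&
      !anyDuplicated(c(x_ctrl, x_exposed))
    ht <- suppressWarnings(
      stats::wilcox.test(x_exposed, x_ctrl, exact = exact_ok, correct = TRUE)
    )
    test_used <- "wilcoxon"
  }
  data.frame(metabolite = metabolite, test_used = test_used,
             statistic = unname(ht$statistic), p_value = ht$p.value,
             direction = direction,
             significant = ht$p.value < 0.05,
             flagged = FALSE, stringsAsFactors = FALSE)
}

#' Univariate analysis of a concentration matrix
#'
#' Applies [route_and_test()] to every metabolite column, preserving input
#' column order. Significance is assessed at the 95% confidence level
#' (p < 0.05) without multiple-testing correction; Benjamini-Hochberg
#' adjusted p-values are reported alongside for transparency.
#'
#' @param matrix a `conc_matrix` data.frame with both groups present.
#' @param alpha_assumptions level for the normality/homoscedasticity checks.
#' @return data.frame of class `univariate_report`, one row per metabolite:
#'   columns of [route_and_test()] plus `adjusted_p`. Attribute `summary`
#'   counts significant-up / significant-down metabolites.
#' @export
run_univariate <- function(matrix, alpha_assumptions = 0.05) {
  stopifnot(is.data.frame(matrix),
            all(c("subject_id", "group") %in% names(matrix)))
  g <- matrix$group
  if (anyNA(g) || length(unique(g)) < 2L) {
    stop("both groups (CTRL, Exposed) must be present", call. = FALSE)
  }
  vals <- conc_values(matrix)
  rows <- lapply(colnames(vals), function(nm) {
    route_and_test(vals[g == "CTRL", nm], vals[g == "Exposed", nm],
                   alpha_assumptions = alpha_assumptions, metabolite = nm)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "summary") <- c(
    significant_up = sum(out$significant & out$direction == "up_in_exposed"),
    significant_down = sum(out$significant &
                             out$direction == "down_in_exposed")
  )
  class(out) <- c("univariate_report", "data.frame")
  out
}
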