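# Shared fixtures and independent oracles used across test files.

# Small disjoint-window library for fast synthetic tests: TSP, creatinine
# and three singlet analytes.
tiny_library <- function() {
  sigs <- list(
    metabolite_signal("TSP", c(-0.02, 0.02), 9L),
    metabolite_signal("A", c(1.98, 2.02), 2L),
    metabolite_signal("B", c(2.98, 3.02), 3L),
    metabolite_signal("C", c(4.98, 5.02), 1L),
    metabolite_signal("Creatinine", c(4.03, 4.07), 3L)
  )
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  attr(sigs, "baselines") <- c(A = 50, B = 20, C = 100)
  attr(sigs, "roles") <- c(TSP = "reference", A = "analyte", B = "analyte",
                           C = "analyte", Creatinine = "reference")
  sigs
}

# coarse grid keeps tiny-library tests fast; window centers on grid points
tiny_spectrum_config <- function(...) {
  spectrum_config(ppm_grid = c(-0.5, 6.0, 65001L), ...)
}

# dense-trapezoid oracle on an explicit function, independent of
# integrate_window's interpolation path
trapz_oracle <- function(f, lo, hi, n = 200001L) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum(diff(x) * (y[-n] + y[-1])) / 2
}

# two-group data matrix with a given mean shift on the first `k` columns
shifted_groups <- function(n_ctrl = 13, n_exp = 12, p = 5, k = p,
                           shift = 10, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n_ctrl + n_exp) * p), n_ctrl + n_exp, p)
  X[(n_ctrl + 1):(n_ctrl + n_exp), seq_len(k)] <-
    X[(n_ctrl + 1):(n_ctrl + n_exp), seq_len(k)] + shift
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, y = rep(c(-1, 1), c(n_ctrl, n_exp)),
       groups = factor(rep(c("CTRL", "Exposed"), c(n_ctrl, n_exp)),
                       levels = c("CTRL", "Exposed")))
}
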