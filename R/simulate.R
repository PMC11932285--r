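#' Specify a group effect on one metabolite
#'
#' An effect multiplies the exposed-group median concentration of one
#' metabolite by `2^log2_fold_change` relative to the control baseline.
#'
#' @param metabolite metabolite name (must exist in the library in use).
#' @param log2_fold_change real; exposed vs control log2 fold change.
#' @param source optional provenance tag: `"ctrl-significant"`,
#'   `"exposed-significant"` or `NULL`.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(metabolite, log2_fold_change, source = NULL) {
  stopifnot(is.character(metabolite), length(metabolite) == 1L)
  stopifnot_scalar_number(log2_fold_change, "log2_fold_change")
  if (!is.null(source)) {
    source <- match.arg(source, c("ctrl-significant", "exposed-significant"))
  }
  structure(list(metabolite = metabolite,
                 log2_fold_change = as.numeric(log2_fold_change),
                 source = source),
            class = "effect_spec")
}

#' Default effect pattern for the simulator
#'
#' Encodes the reported direction-of-change pattern of the study the
#' simulator emulates: 22 metabolites lower in exposed workers
#' (branched-chain amino acids and others, assigned to the control class)
#' and 6 higher in exposed (pyroglutamate, glutamine, glycine,
#' furoylglycine, trigonelline and the unknown compound U03), with
#' furoylglycine carrying a 4-fold increase (log2 fold change +2).
#'
#' Magnitudes other than furoylglycine's are not reported as numbers and
#' default to |log2 FC| = 0.65, about 1.5 pooled standard deviations on the
#' log scale at the default log-normal noise (`sigma_log` = 0.3); see the
#' vignette for the rationale.
#'
#' @param log2_magnitude absolute log2 fold change applied to every effect
#'   except furoylglycine.
#' @param furoylglycine_log2 log2 fold change for furoylglycine (default +2,
#'   i.e. 4x higher in exposed).
#' @return list of [effect_spec] objects.
#' @export
default_effects <- function(log2_magnitude = 0.65, furoylglycine_log2 = 2) {
  ctrl_up <- c("Leu", "Val", "Ile", "3-HIBA", "Threo-2,3-DHBA", "3-H-3MBA",
               "Ala", "AA", "N-AcGln", "CA", "Sar", "MG", "Crt", "TMAO",
               "4-HPAA", "Tyr", "PAG", "Hipp", "PSI", "4-HbzA", "FA", "1-MNA")
  exposed_up <- c("pyro-Glu", "Gln", "Gly", "Furoylglycine", "Trig", "U03")
  eff <- c(
    lapply(ctrl_up, effect_spec, log2_fold_change = -abs(log2_magnitude),
           source = "ctrl-significant"),
    lapply(exposed_up, function(m) {
      effect_spec(m,
                  if (m == "Furoylglycine") furoylglycine_log2
                  else abs(log2_magnitude),
                  source = "exposed-significant")
    })
  )
  eff
}

#' Configure a concentration-table simulation
#'
#' Defaults reproduce the emulated study design: 12 exposed workers vs 13
#' controls, 50 variables (46 named metabolites plus 4 unknowns),
#' multiplicative log-normal concentration noise and the reported
#' direction-of-change effect pattern.
#'
#' @param n_exposed,n_control group sizes (each >= 2).
#' @param noise_sigma_log standard deviation of the log-normal noise on the
#'   natural-log scale (> 0).
#' @param effects list of [effect_spec]; default [default_effects()]. Use
#'   `list()` for a global null.
#' @param seed integer seed; mandatory for reproducibility.
#' @param library signal library; default [default_library()].
#' @param baseline_concentrations named positive vector of per-metabolite
#'   control medians (umol/mmol creatinine); defaults to the library's
#'   baselines.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_exposed = 12L, n_control = 13L,
                       noise_sigma_log = 0.3,
                       effects = default_effects(),
                       seed = 1L,
                       library = default_library(),
                       baseline_concentrations = NULL) {
  n_exposed <- as.integer(n_exposed); n_control <- as.integer(n_control)
  if (is.na(n_exposed) || n_exposed < 2L || is.na(n_control) || n_control < 2L) {
    stop("group sizes must be integers >= 2", call. = FALSE)
  }
  stopifnot_scalar_number(noise_sigma_log, "noise_sigma_log", positive = TRUE)
  validate_library(library)
  analytes <- library_analytes(library)
  if (is.null(baseline_concentrations)) {
    baseline_concentrations <- attr(library, "baselines")[analytes]
  }
  if (is.null(names(baseline_concentrations)) ||
      !setequal(names(baseline_concentrations), analytes)) {
    stop("`baseline_concentrations` must be named for every library analyte",
         call. = FALSE)
  }
  baseline_concentrations <- baseline_concentrations[analytes]
  if (any(!is.finite(baseline_concentrations)) ||
      any(baseline_concentrations <= 0)) {
    stop("all baseline concentrations must be positive", call. = FALSE)
  }
  if (!is.list(effects) ||
      !all(vapply(effects, inherits, logical(1), "effect_spec"))) {
    stop("`effects` must be a list of effect_spec objects", call. = FALSE)
  }
  for (e in effects) {
    if (!e$metabolite %in% analytes) {
      stop(sprintf("effect references unknown metabolite '%s'", e$metabolite),
           call. = FALSE)
    }
  }
  structure(list(n_exposed = n_exposed, n_control = n_control,
                 noise_sigma_log = noise_sigma_log, effects = effects,
                 seed = as.integer(seed), library = library,
                 baseline_concentrations = baseline_concentrations),
            class = "sim_config")
}

#' Simulate a group-structured concentration table
#'
#' Draws per-subject metabolite concentrations log-normally around the
#' control baselines; for every effect the exposed-group median is
#' multiplied by `2^log2_fold_change`. Output is a concentration matrix in
#' umol/mmol creatinine with group labels, the container consumed by the
#' chemometric and univariate branches.
#'
#' @param config a [sim_config].
#' @return data.frame of class `conc_matrix`: columns `subject_id`, `group`
#'   (factor CTRL/Exposed), then one column per metabolite. Attribute
#'   `units` = `"umol/mmol creatinine"`.
#' @export
#' @examples
#' m <- simulate_concentrations(sim_config(seed = 7))
#' dim(m)  # 25 subjects x (2 + 50) columns
simulate_concentrations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  analytes <- library_analytes(config$library)
  p <- length(analytes)
  n_c <- config$n_control; n_e <- config$n_exposed
  n <- n_c + n_e
  medians <- matrix(rep(config$baseline_concentrations, each = n), n, p)
  colnames(medians) <- analytes
  for (e in config$effects) {
    j <- match(e$metabolite, analytes)
    medians[(n_c + 1L):n, j] <- medians[(n_c + 1L):n, j] * 2^e$log2_fold_change
  }
  vals <- with_seed(config$seed, {
    z <- matrix(stats::rnorm(n * p, sd = config$noise_sigma_log), n, p)
    medians * exp(z)
  })
  out <- data.frame(
    subject_id = c(sprintf("CTRL%02d", seq_len(n_c)),
                   sprintf("EXP%02d", seq_len(n_e))),
    group = factor(rep(.GROUP_LEVELS, c(n_c, n_e)), levels = .GROUP_LEVELS),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  attr(out, "units") <- "umol/mmol creatinine"
  class(out) <- c("conc_matrix", "data.frame")
  out
}

#' Extract the numeric block of a concentration matrix
#'
#' @param x a `conc_matrix` data.frame (columns `subject_id`, `group`, then
#'   metabolites).
#' @return numeric matrix, subjects x metabolites, with dimnames.
#' @export
conc_values <- function(x) {
  stopifnot(is.data.frame(x), all(c("subject_id", "group") %in% names(x)))
  meta <- setdiff(names(x), c("subject_id", "group"))
  m <- as.matrix(x[, meta, drop = FALSE])
  if (!is.numeric(m)) stop("metabolite columns must be numeric", call. = FALSE)
  rownames(m) <- x$subject_id
  m
}

#' Write / read a concentration matrix CSV
#'
#' Layout: first column subject ID, second column group label, remaining
#' columns metabolites (umol/mmol creatinine).
#'
#' @param x a `conc_matrix` data.frame.
#' @param path file path.
#' @return `write_conc_matrix`: `path` invisibly. `read_conc_matrix`: a
#'   `conc_matrix` data.frame.
#' @export
write_conc_matrix <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conc_matrix
#' @export
read_conc_matrix <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(x)[1:2])) {
    stop("concentration CSV must start with subject_id, group columns",
         call. = FALSE)
  }
  x$group <- factor(x$group, levels = .GROUP_LEVELS)
  if (anyNA(x$group)) stop("unrecognized group labels in CSV", call. = FALSE)
  attr(x, "units") <- "umol/mmol creatinine"
  class(x) <- c("conc_matrix", "data.frame")
  x
}
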