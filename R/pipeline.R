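#' Configure an end-to-end analysis run
#'
#' Bundles the stage toggles, paths and per-module configurations of the
#' simulate -> quantify -> analyze (DCV + selection) -> univariate chain.
#' All stochastic stages draw their seeds deterministically from the single
#' master seed, so a rerun with the same configuration reproduces every
#' output byte for byte.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed master seed (mandatory; drives simulation and fold shuffles).
#' @param stages character subset of
#'   `c("simulate", "quantify", "analyze", "univariate")`.
#' @param simulation a [sim_config] (its seed is overridden by a stream
#'   derived from `seed`).
#' @param spectrum a [spectrum_config] used when spectra are synthesized.
#' @param quant a [quant_config].
#' @param dcv a [dcv_config] (seed overridden likewise).
#' @param alpha_assumptions level for the univariate assumption checks.
#' @param spectra_dir directory of two-column spectra + manifest.csv. With
#'   the simulate stage enabled, spectra are written here; with only the
#'   quantify stage, they are read from here.
#' @param matrix_csv optional pre-existing concentration CSV used when
#'   neither simulate nor quantify is enabled.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            stages = c("simulate", "quantify", "analyze",
                                       "univariate"),
                            simulation = sim_config(),
                            spectrum = spectrum_config(),
                            quant = quant_config(),
                            dcv = dcv_config(),
                            alpha_assumptions = 0.05,
                            spectra_dir = NULL,
                            matrix_csv = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  stopifnot_scalar_number(seed, "seed")
  stopifnot(inherits(simulation, "sim_config"),
            inherits(spectrum, "spectrum_config"),
            inherits(quant, "quant_config"),
            inherits(dcv, "dcv_config"))
  if (!"simulate" %in% stages) {
    if ("quantify" %in% stages && (is.null(spectra_dir) ||
                                   !dir.exists(spectra_dir))) {
      stop("`spectra_dir` must exist when quantifying without simulating",
           call. = FALSE)
    }
    if (!"quantify" %in% stages &&
        any(c("analyze", "univariate") %in% stages) &&
        (is.null(matrix_csv) || !file.exists(matrix_csv))) {
      stop("`matrix_csv` must exist when analyzing without simulate/quantify",
           call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 simulation = simulation, spectrum = spectrum, quant = quant,
                 dcv = dcv, alpha_assumptions = alpha_assumptions,
                 spectra_dir = spectra_dir, matrix_csv = matrix_csv),
            class = "pipeline_config")
}

# Known YAML keys per block; anything else is a config error.
.pipeline_keys <- list(
  top = c("out_dir", "seed", "stages", "simulation", "spectrum", "quant",
          "dcv", "alpha_assumptions", "spectra_dir", "matrix_csv"),
  simulation = c("n_exposed", "n_control", "noise_sigma_log", "effects",
                 "seed"),
  spectrum = c("ppm_grid", "linewidth_hwhm_ppm", "tsp_center_ppm",
               "creatinine_singlet_ppm", "tsp_conc_mM",
               "creatinine_conc_mmol_per_L", "j_spacing_ppm",
               "tail_cutoff_ppm", "additive_noise_sd"),
  quant = c("tsp_conc_mM", "tsp_protons", "tsp_window_ppm",
            "creatinine_window_ppm", "creatinine_protons"),
  dcv = c("n_repetitions", "outer_folds", "inner_folds", "max_lv", "seed",
          "stratified", "global_scaling", "cv1")
)

.check_keys <- function(x, allowed, block) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s config: %s", block,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys anywhere in the file raise a validation error before any
#' stage runs. A simulation `effects` block is a list of
#' `{metabolite, log2_fold_change}` entries; omit it to use the default
#' effect pattern, or set `effects: []` for a global null.
#'
#' @param path YAML file.
#' @param out_dir,seed optional overrides of the file's values (flags
#'   override the file; the file overrides defaults).
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  raw <- yaml::read_yaml(path)
  .check_keys(raw, .pipeline_keys$top, "top-level")
  for (block in c("simulation", "spectrum", "quant", "dcv")) {
    if (!is.null(raw[[block]])) {
      .check_keys(raw[[block]], .pipeline_keys[[block]], block)
    }
  }
  sim_args <- raw$simulation %||% list()
  if (!is.null(sim_args$effects)) {
    sim_args$effects <- lapply(sim_args$effects, function(e) {
      effect_spec(e$metabolite, e$log2_fold_change)
    })
  }
  sim <- do.call(sim_config, sim_args)
  spec_cfg <- do.call(spectrum_config, raw$spectrum %||% list())
  quant_cfg <- do.call(quant_config, raw$quant %||% list())
  dcv_cfg <- do.call(dcv_config, raw$dcv %||% list())
  pipeline_config(
    out_dir = out_dir %||% raw$out_dir %||% ".",
    seed = seed %||% raw$seed %||%
      stop("`seed` is mandatory", call. = FALSE),
    stages = raw$stages %||% c("simulate", "quantify", "analyze",
                               "univariate"),
    simulation = sim, spectrum = spec_cfg, quant = quant_cfg, dcv = dcv_cfg,
    alpha_assumptions = raw$alpha_assumptions %||% 0.05,
    spectra_dir = raw$spectra_dir, matrix_csv = raw$matrix_csv
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the configured analysis pipeline
#'
#' Executes the enabled stages in order and writes the report bundle into
#' `out_dir`: `concentration_matrix.csv`, `dcv_summary.json` (figures of
#' merit mean +/- sd and chosen latent variables), `selection.csv` (the
#' sign-stability variable selection report), `univariate.csv` and
#' `run_manifest.yaml` (configuration echo, master seed and package
#' version, enabling bit-identical reruns).
#'
#' @param config a [pipeline_config] (or path to a YAML file readable by
#'   [read_pipeline_config()]).
#' @return invisibly, a list with the in-memory stage results (`matrix`,
#'   `dcv`, `selection`, `univariate`) and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  seeds <- derive_seeds(config$seed, 3L)  # simulate / spectra noise / dcv
  paths <- list()
  result <- list()
  conc <- NULL

  if ("simulate" %in% config$stages) {
    sim <- config$simulation
    sim$seed <- seeds[1]
    conc <- simulate_concentrations(sim)
    if (!is.null(config$spectra_dir) || "quantify" %in% config$stages) {
      sdir <- config$spectra_dir %||% file.path(config$out_dir, "spectra")
      spectra <- synthesize_cohort(conc, config = config$spectrum,
                                   library = config$simulation$library,
                                   noise_seed = seeds[2])
      paths$spectra_manifest <- write_spectra(spectra, conc$group, sdir)
    }
  }
  if ("quantify" %in% config$stages) {
    sdir <- config$spectra_dir %||% file.path(config$out_dir, "spectra")
    sp <- read_spectra(sdir)
    conc <- build_matrix(sp$spectra, sp$groups,
                         library = config$simulation$library,
                         config = config$quant)
  }
  if (is.null(conc)) {
    if (is.null(config$matrix_csv)) {
      stop("no concentration matrix: enable simulate/quantify or supply ",
           "`matrix_csv`", call. = FALSE)
    }
    conc <- read_conc_matrix(config$matrix_csv)
  }
  paths$matrix <- file.path(config$out_dir, "concentration_matrix.csv")
  write_conc_matrix(conc, paths$matrix)
  result$matrix <- conc

  if ("analyze" %in% config$stages) {
    dcv_cfg <- config$dcv
    dcv_cfg$seed <- seeds[3]
    dcv <- double_cross_validate(conc, config = dcv_cfg)
    sel <- select_significant_variables(dcv)
    paths$dcv_summary <- file.path(config$out_dir, "dcv_summary.json")
    jsonlite::write_json(
      list(figures_of_merit = dcv$summary,
           chosen_n_lv = as.vector(table(dcv$chosen_n_lv)),
           n_repetitions = dcv$config$n_repetitions,
           outer_folds = dcv$config$outer_folds),
      paths$dcv_summary, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    paths$selection <- file.path(config$out_dir, "selection.csv")
    utils::write.csv(sel, paths$selection, row.names = FALSE)
    result$dcv <- dcv
    result$selection <- sel
  }
  if ("univariate" %in% config$stages) {
    uni <- run_univariate(conc, alpha_assumptions = config$alpha_assumptions)
    paths$univariate <- file.path(config$out_dir, "univariate.csv")
    utils::write.csv(uni, paths$univariate, row.names = FALSE)
    result$univariate <- uni
  }
  manifest <- list(
    package = "urinmr",
    version = as.character(utils::packageVersion("urinmr")),
    seed = config$seed,
    stages = config$stages,
    simulation = list(
      n_exposed = config$simulation$n_exposed,
      n_control = config$simulation$n_control,
      noise_sigma_log = config$simulation$noise_sigma_log,
      n_effects = length(config$simulation$effects)),
    dcv = list(n_repetitions = config$dcv$n_repetitions,
               outer_folds = config$dcv$outer_folds,
               inner_folds = config$dcv$inner_folds,
               max_lv = config$dcv$max_lv)
  )
  paths$manifest <- file.path(config$out_dir, "run_manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)
  result$paths <- paths
  invisible(result)
}
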