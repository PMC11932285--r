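#' Construct an NMR spectrum object
#'
#' A processed 1D spectrum: a strictly monotone ppm axis and an intensity
#' vector of equal length. Decreasing axes (the conventional plotting order)
#' are normalized internally to increasing ppm.
#'
#' @param ppm strictly monotone numeric vector (ppm).
#' @param intensity numeric vector, same length as `ppm`.
#' @param subject_id subject identifier.
#' @return object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, subject_id = "subject") {
  if (!is.numeric(ppm) || !is.numeric(intensity) ||
      length(ppm) != length(intensity) || length(ppm) < 2L) {
    stop("`ppm` and `intensity` must be numeric vectors of equal length >= 2",
         call. = FALSE)
  }
  d <- diff(ppm)
  if (all(d < 0)) {
    ppm <- rev(ppm); intensity <- rev(intensity); d <- -rev(d)
  }
  if (any(d <= 0)) stop("`ppm` must be strictly monotone", call. = FALSE)
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 subject_id = as.character(subject_id)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s: %d points, %.2f to %.2f ppm\n",
              x$subject_id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Configure synthetic spectrum generation
#'
#' @param ppm_grid numeric length-3 `c(min, max, points)`; the default grid
#'   spans -0.5 to 10 ppm at 5e-5 ppm spacing so every default library
#'   window center falls on a grid point.
#' @param linewidth_hwhm_ppm Lorentzian half width at half maximum in ppm
#'   (default 1e-4 ppm, idealized narrow lines keeping cross-window tail
#'   leakage between neighbouring signals well below 1%).
#' @param tsp_center_ppm chemical-shift origin of the TSP reference singlet.
#' @param creatinine_singlet_ppm creatinine reference singlet position.
#' @param tsp_conc_mM internal-standard concentration in the tube
#'   (default 1.82 mM).
#' @param creatinine_conc_mmol_per_L urinary creatinine concentration used
#'   to map umol/mmol inputs to molarities (default 10 mmol/L).
#' @param j_spacing_ppm multiplet line spacing in ppm (default 0.012 ppm,
#'   about 7 Hz at 600 MHz).
#' @param tail_cutoff_ppm Lorentzian tails are truncated beyond this
#'   distance from each line center, emulating locally baseline-corrected
#'   processed spectra (default 0.25 ppm).
#' @param additive_noise_sd standard deviation of additive Gaussian noise
#'   (intensity units; 0 = noiseless).
#' @return object of class `spectrum_config`.
#' @export
spectrum_config <- function(ppm_grid = c(-0.5, 10.0, 210001L),
                            linewidth_hwhm_ppm = 1e-4,
                            tsp_center_ppm = 0.0,
                            creatinine_singlet_ppm = 4.05,
                            tsp_conc_mM = 1.82,
                            creatinine_conc_mmol_per_L = 10,
                            j_spacing_ppm = 0.012,
                            tail_cutoff_ppm = 0.25,
                            additive_noise_sd = 0) {
  if (!is.numeric(ppm_grid) || length(ppm_grid) != 3L ||
      ppm_grid[1] >= ppm_grid[2] || ppm_grid[3] < 16) {
    stop("`ppm_grid` must be c(min, max, points) with min < max, points >= 16",
         call. = FALSE)
  }
  stopifnot_scalar_number(linewidth_hwhm_ppm, "linewidth_hwhm_ppm", TRUE)
  stopifnot_scalar_number(tsp_conc_mM, "tsp_conc_mM", TRUE)
  stopifnot_scalar_number(creatinine_conc_mmol_per_L,
                          "creatinine_conc_mmol_per_L", TRUE)
  stopifnot_scalar_number(j_spacing_ppm, "j_spacing_ppm", TRUE)
  stopifnot_scalar_number(tail_cutoff_ppm, "tail_cutoff_ppm", TRUE)
  if (additive_noise_sd < 0) stop("`additive_noise_sd` must be >= 0",
                                  call. = FALSE)
  structure(list(ppm_grid = c(ppm_grid[1], ppm_grid[2],
                              as.integer(ppm_grid[3])),
                 linewidth_hwhm_ppm = linewidth_hwhm_ppm,
                 tsp_center_ppm = tsp_center_ppm,
                 creatinine_singlet_ppm = creatinine_singlet_ppm,
                 tsp_conc_mM = tsp_conc_mM,
                 creatinine_conc_mmol_per_L = creatinine_conc_mmol_per_L,
                 j_spacing_ppm = j_spacing_ppm,
                 tail_cutoff_ppm = tail_cutoff_ppm,
                 additive_noise_sd = additive_noise_sd),
            class = "spectrum_config")
}

# Add one multiplet to an intensity vector. `area` is the total integral
# (intensity * ppm); lines follow the binomial intensity pattern spaced by
# `j` ppm around `center`. Tails truncated at `cutoff` ppm from each line.
.add_multiplet <- function(intensity, ppm, center, area, multiplicity,
                           gamma, j, cutoff) {
  m <- multiplicity
  w <- choose(m - 1L, 0:(m - 1L)); w <- w / sum(w)
  offsets <- (seq_len(m) - 1 - (m - 1) / 2) * j
  for (k in seq_len(m)) {
    x0 <- center + offsets[k]
    idx <- which(ppm >= x0 - cutoff & ppm <= x0 + cutoff)
    if (length(idx)) {
      dx <- ppm[idx] - x0
      intensity[idx] <- intensity[idx] +
        area * w[k] * (gamma / pi) / (dx^2 + gamma^2)
    }
  }
  intensity
}

#' Synthesize a 1D urine-like NMR spectrum
#'
#' Builds a spectrum as a sum of Lorentzian multiplets: one multiplet per
#' library analyte whose window integral is proportional to concentration
#' times proton count, plus the TSP reference singlet at 0 ppm and the
#' creatinine singlet at 4.05 ppm at their configured concentrations.
#' Analyte concentrations are supplied in umol/mmol creatinine and mapped
#' to molarities through the configured creatinine concentration, so that
#' quantification against TSP followed by creatinine normalization recovers
#' the input values.
#'
#' @param concentrations named non-negative numeric vector, umol/mmol
#'   creatinine, names drawn from the library's analytes. Analytes absent
#'   from the vector are simulated at zero concentration.
#' @param config a [spectrum_config].
#' @param library signal library (default [default_library()]).
#' @param subject_id identifier stored in the spectrum.
#' @param noise_seed optional seed for the additive noise draw (only used
#'   when `additive_noise_sd > 0`).
#' @return an [nmr_spectrum].
#' @export
#' @examples
#' sp <- synthesize_spectrum(c(Gly = 100, Hipp = 60), spectrum_config())
synthesize_spectrum <- function(concentrations, config = spectrum_config(),
                                library = default_library(),
                                subject_id = "subject",
                                noise_seed = NULL) {
  stopifnot(inherits(config, "spectrum_config"))
  validate_library(library)
  analytes <- library_analytes(library)
  if (length(concentrations)) {
    if (is.null(names(concentrations)) ||
        !all(names(concentrations) %in% analytes)) {
      stop("`concentrations` must be named with library analytes",
           call. = FALSE)
    }
    if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
      stop("all concentrations must be finite and >= 0", call. = FALSE)
    }
  }
  g <- config$ppm_grid
  ppm <- seq(g[1], g[2], length.out = g[3])
  win <- t(vapply(library, `[[`, numeric(2), "window_ppm"))
  if (min(win) < g[1] || max(win) > g[2]) {
    stop("library window outside the ppm grid", call. = FALSE)
  }
  intensity <- numeric(length(ppm))
  gamma <- config$linewidth_hwhm_ppm
  creat_mM <- config$creatinine_conc_mmol_per_L

  add_named <- function(intensity, name, conc_mM) {
    sig <- library_signal(library, name)
    center <- mean(sig$window_ppm)
    .add_multiplet(intensity, ppm, center,
                   area = conc_mM * sig$n_protons,
                   multiplicity = sig$multiplicity, gamma = gamma,
                   j = config$j_spacing_ppm, cutoff = config$tail_cutoff_ppm)
  }
  # references: areas proportional to concentration x protons, shared unit
  intensity <- add_named(intensity, "TSP", config$tsp_conc_mM)
  intensity <- add_named(intensity, "Creatinine", creat_mM)
  for (nm in names(concentrations)) {
    conc_mM <- concentrations[[nm]] * creat_mM / 1000  # umol/mmol -> mM
    if (conc_mM > 0) intensity <- add_named(intensity, nm, conc_mM)
  }
  if (config$additive_noise_sd > 0) {
    noise <- if (is.null(noise_seed)) {
      stats::rnorm(length(ppm), sd = config$additive_noise_sd)
    } else {
      with_seed(noise_seed,
                stats::rnorm(length(ppm), sd = config$additive_noise_sd))
    }
    intensity <- intensity + noise
  }
  nmr_spectrum(ppm, intensity, subject_id = subject_id)
}

#' Synthesize one spectrum per subject of a concentration table
#'
#' @param conc a `conc_matrix` data.frame (see [simulate_concentrations()]).
#' @param config a [spectrum_config].
#' @param library signal library.
#' @param noise_seed optional master seed for per-subject noise draws.
#' @return named list of [nmr_spectrum] objects, in row order.
#' @export
synthesize_cohort <- function(conc, config = spectrum_config(),
                              library = default_library(),
                              noise_seed = NULL) {
  stopifnot(is.data.frame(conc))
  vals <- conc_values(conc)
  seeds <- if (!is.null(noise_seed)) derive_seeds(noise_seed, nrow(vals))
  out <- lapply(seq_len(nrow(vals)), function(i) {
    synthesize_spectrum(vals[i, ], config = config, library = library,
                        subject_id = rownames(vals)[i],
                        noise_seed = if (is.null(noise_seed)) NULL
                        else seeds[i])
  })
  names(out) <- rownames(vals)
  out
}

#' Write / read spectra as two-column delimited text
#'
#' One file per subject (`<subject_id>.tsv`, columns ppm and intensity,
#' tab-separated, no header) plus `manifest.csv` mapping file to subject to
#' group label.
#'
#' @param spectra named list of [nmr_spectrum] objects.
#' @param groups character/factor of group labels, one per spectrum.
#' @param dir output directory (created if missing).
#' @return `write_spectra`: the manifest path, invisibly. `read_spectra`: a
#'   list with elements `spectra` (list of [nmr_spectrum]) and `groups`.
#' @export
write_spectra <- function(spectra, groups, dir) {
  stopifnot(is.list(spectra), length(spectra) == length(groups))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(spectra, `[[`, character(1), "subject_id")
  files <- paste0(ids, ".tsv")
  for (i in seq_along(spectra)) {
    utils::write.table(
      data.frame(ppm = spectra[[i]]$ppm, intensity = spectra[[i]]$intensity),
      file.path(dir, files[i]),
      sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(file = files, subject_id = ids,
                         group = as.character(groups),
                         stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_spectra
#' @param path a two-column (ppm, intensity) delimited text file.
#' @param subject_id identifier to attach to the spectrum read.
#' @export
read_spectrum <- function(path, subject_id = NULL) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("ppm", "intensity"))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  nmr_spectrum(tab$ppm, tab$intensity, subject_id = subject_id)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("manifest.csv not found in ", dir,
                                call. = FALSE)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(nrow(manifest)), function(i) {
    read_spectrum(file.path(dir, manifest$file[i]), manifest$subject_id[i])
  })
  names(spectra) <- manifest$subject_id
  list(spectra = spectra,
       groups = factor(manifest$group, levels = .GROUP_LEVELS))
}
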