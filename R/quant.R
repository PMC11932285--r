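#' Configure internal-standard quantification
#'
#' @param tsp_conc_mM TSP internal-standard concentration in the tube
#'   (default 1.82 mM).
#' @param tsp_protons protons generating the TSP singlet (9, three
#'   equivalent methyls).
#' @param tsp_window_ppm half-open integration window around 0 ppm.
#' @param creatinine_window_ppm half-open window around the 4.05 ppm
#'   creatinine singlet.
#' @param creatinine_protons protons assigned to the creatinine reference
#'   singlet (default 3).
#' @return object of class `quant_config`.
#' @export
quant_config <- function(tsp_conc_mM = 1.82,
                         tsp_protons = 9L,
                         tsp_window_ppm = c(-0.02, 0.02),
                         creatinine_window_ppm = c(4.03, 4.07),
                         creatinine_protons = 3L) {
  stopifnot_scalar_number(tsp_conc_mM, "tsp_conc_mM", positive = TRUE)
  stopifnot(length(tsp_window_ppm) == 2L,
            tsp_window_ppm[1] < tsp_window_ppm[2],
            length(creatinine_window_ppm) == 2L,
            creatinine_window_ppm[1] < creatinine_window_ppm[2])
  structure(list(tsp_conc_mM = tsp_conc_mM,
                 tsp_protons = as.integer(tsp_protons),
                 tsp_window_ppm = as.numeric(tsp_window_ppm),
                 creatinine_window_ppm = as.numeric(creatinine_window_ppm),
                 creatinine_protons = as.integer(creatinine_protons)),
            class = "quant_config")
}

#' Integrate a spectrum over a half-open ppm window
#'
#' Trapezoidal integration of intensity over `[lo, hi)`. Intensities at the
#' exact window bounds are obtained by linear interpolation, so the result
#' for a constant intensity `c` is exactly `c * (hi - lo)` regardless of
#' grid alignment.
#'
#' @param spectrum an [nmr_spectrum].
#' @param window numeric length-2 half-open interval `[lo, hi)` in ppm.
#' @return the integral in intensity * ppm units.
#' @export
#' @examples
#' sp <- nmr_spectrum(seq(0, 1, by = 0.01), rep(2, 101))
#' integrate_window(sp, c(0.1, 0.6))  # 2 * 0.5 = 1
integrate_window <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (!is.numeric(window) || length(window) != 2L || window[1] >= window[2]) {
    stop("`window` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  ppm <- spectrum$ppm; y <- spectrum$intensity
  lo <- window[1]; hi <- window[2]
  if (lo < ppm[1] || hi > ppm[length(ppm)]) {
    stop(sprintf("window [%g, %g) outside spectrum range [%g, %g]",
                 lo, hi, ppm[1], ppm[length(ppm)]), call. = FALSE)
  }
  inside <- which(ppm > lo & ppm < hi)
  if (length(inside) < 2L) {
    stop("fewer than 2 grid points inside the window", call. = FALSE)
  }
  y_lo <- stats::approx(ppm, y, xout = lo)$y
  y_hi <- stats::approx(ppm, y, xout = hi)$y
  xs <- c(lo, ppm[inside], hi)
  ys <- c(y_lo, y[inside], y_hi)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1])) / 2
}

#' Quantify metabolites against the TSP internal standard
#'
#' For each library analyte, the window integral is normalized by the
#' number of protons generating the signal and compared with the
#' per-proton integral of the TSP reference:
#' `conc_m = (I_m / n_m) / (I_TSP / n_TSP) * tsp_conc_mM`.
#'
#' Negative window integrals (possible on noisy baselines) are clamped to
#' zero with a warning.
#'
#' @param spectrum an [nmr_spectrum].
#' @param library signal library; analyte windows must lie inside the
#'   spectrum range.
#' @param config a [quant_config].
#' @return named numeric vector of molar concentrations (mM), one per
#'   library analyte, in library order. Attribute `creatinine_mM` holds the
#'   creatinine concentration quantified from its own singlet.
#' @export
quantify <- function(spectrum, library = default_library(),
                     config = quant_config()) {
  stopifnot(inherits(spectrum, "nmr_spectrum"),
            inherits(config, "quant_config"))
  validate_library(library)
  i_tsp <- integrate_window(spectrum, config$tsp_window_ppm)
  if (!is.finite(i_tsp) || i_tsp <= 0) {
    stop("nonpositive TSP reference integral; cannot quantify", call. = FALSE)
  }
  per_proton_tsp <- i_tsp / config$tsp_protons
  analytes <- library_analytes(library)
  conc <- vapply(analytes, function(nm) {
    sig <- library_signal(library, nm)
    I_m <- integrate_window(spectrum, sig$window_ppm)
    (I_m / sig$n_protons) / per_proton_tsp * config$tsp_conc_mM
  }, numeric(1))
  if (any(conc < 0)) {
    warning(sprintf("%d negative window integral(s) clamped to 0 (%s)",
                    sum(conc < 0), spectrum$subject_id), call. = FALSE)
    conc[conc < 0] <- 0
  }
  i_crn <- integrate_window(spectrum, config$creatinine_window_ppm)
  creat_mM <- (i_crn / config$creatinine_protons) / per_proton_tsp *
    config$tsp_conc_mM
  attr(conc, "creatinine_mM") <- creat_mM
  conc
}

#' Normalize molar concentrations to creatinine
#'
#' Converts mM concentrations to umol/mmol creatinine:
#' `out_m = 1000 * conc_m / creatinine_mM` (umol/L over mmol/L).
#'
#' @param molar_concs numeric vector of concentrations in mM.
#' @param creatinine_mM creatinine concentration in mM (> 0).
#' @return numeric vector in umol/mmol creatinine.
#' @export
#' @examples
#' normalize_to_creatinine(c(a = 1, b = 0.5), creatinine_mM = 10)
normalize_to_creatinine <- function(molar_concs, creatinine_mM) {
  stopifnot_scalar_number(creatinine_mM, "creatinine_mM")
  if (creatinine_mM <= 0) {
    stop("`creatinine_mM` must be > 0", call. = FALSE)
  }
  out <- 1000 * molar_concs / creatinine_mM
  attr(out, "creatinine_mM") <- NULL
  out
}

#' Build a concentration matrix from a set of spectra
#'
#' Quantifies every spectrum against TSP, normalizes to the creatinine
#' concentration quantified from each subject's own 4.05 ppm singlet, and
#' assembles the subjects x metabolites table. Row order follows the input
#' order.
#'
#' @param spectra non-empty list of [nmr_spectrum] objects.
#' @param groups group labels ("CTRL"/"Exposed"), one per spectrum.
#' @param library signal library shared by all subjects.
#' @param config a [quant_config].
#' @return a `conc_matrix` data.frame (see [simulate_concentrations()]),
#'   units umol/mmol creatinine.
#' @export
build_matrix <- function(spectra, groups, library = default_library(),
                         config = quant_config()) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("`spectra` must be a non-empty list of nmr_spectrum objects",
         call. = FALSE)
  }
  if (length(groups) != length(spectra)) {
    stop("`groups` must have one label per spectrum", call. = FALSE)
  }
  groups <- factor(as.character(groups), levels = .GROUP_LEVELS)
  if (anyNA(groups)) {
    stop("group labels must be 'CTRL' or 'Exposed'", call. = FALSE)
  }
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    res <- tryCatch({
      conc <- quantify(sp, library = library, config = config)
      normalize_to_creatinine(conc, attr(conc, "creatinine_mM"))
    }, error = function(e) {
      stop(sprintf("subject '%s': %s", sp$subject_id, conditionMessage(e)),
           call. = FALSE)
    })
    res
  })
  vals <- do.call(rbind, rows)
  ids <- vapply(spectra, `[[`, character(1), "subject_id")
  out <- data.frame(subject_id = ids, group = groups,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "units") <- "umol/mmol creatinine"
  class(out) <- c("conc_matrix", "data.frame")
  out
}
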