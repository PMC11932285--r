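#' Define one quantifiable NMR resonance
#'
#' A metabolite signal is a single resonance free from overlap that can be
#' integrated for quantification: a name, a half-open chemical-shift window
#' `[lo, hi)` in ppm, the number of protons generating the signal, and the
#' multiplet line count (intensities follow the binomial pattern).
#'
#' @param name metabolite (or reference compound) name.
#' @param window_ppm numeric length-2, half-open integration window
#'   `[lo, hi)` in ppm with `lo < hi`.
#' @param n_protons positive integer, protons generating the signal.
#' @param multiplicity integer >= 1, number of multiplet lines (1 = singlet,
#'   2 = doublet, ...). Line intensities follow Pascal's triangle.
#' @return an object of class `metabolite_signal`.
#' @export
#' @examples
#' metabolite_signal("alanine", c(1.52, 1.56), n_protons = 3, multiplicity = 2)
metabolite_signal <- function(name, window_ppm, n_protons, multiplicity = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(window_ppm) || length(window_ppm) != 2L ||
      any(is.na(window_ppm)) || window_ppm[1] >= window_ppm[2]) {
    stop("`window_ppm` must be numeric c(lo, hi) with lo < hi", call. = FALSE)
  }
  n_protons <- as.integer(n_protons)
  if (is.na(n_protons) || n_protons < 1L) {
    stop("`n_protons` must be an integer >= 1", call. = FALSE)
  }
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L) {
    stop("`multiplicity` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(name = name, window_ppm = as.numeric(window_ppm),
         n_protons = n_protons, multiplicity = multiplicity),
    class = "metabolite_signal"
  )
}

#' @export
print.metabolite_signal <- function(x, ...) {
  cat(sprintf("<metabolite_signal> %s: [%.3f, %.3f) ppm, %d H, %d line(s)\n",
              x$name, x$window_ppm[1], x$window_ppm[2],
              x$n_protons, x$multiplicity))
  invisible(x)
}

# Fixture table behind default_library(). Chemical shifts are canonical
# literature-style values for urine, nudged where needed so that all
# integration windows are pairwise disjoint (the quantification contract:
# only overlap-free signals are integrated). Baselines are plausible
# urinary excretion levels in umol/mmol creatinine used by the simulator.
# role: "analyte" rows populate concentration tables; "reference" rows are
# the TSP and creatinine quantification anchors.
.library_table <- function() {
  tab <- rbind(
    # name            ppm   H  mult baseline role
    c("TSP",            0.00, 9, 1,   0, "reference"),
    c("Leu",            0.94, 6, 2,   8, "analyte"),
    c("Val",            1.04, 6, 2,   8, "analyte"),
    c("Ile",            1.14, 3, 2,   6, "analyte"),
    c("3-HIBA",         1.24, 3, 2,  12, "analyte"),
    c("Lactate",        1.33, 3, 2,  15, "analyte"),
    c("2-HIB",          1.44, 6, 1,   8, "analyte"),
    c("Ala",            1.54, 3, 2,  25, "analyte"),
    c("Threo-2,3-DHBA", 1.66, 3, 2,   8, "analyte"),
    c("3-H-3MBA",       1.78, 6, 1,   7, "analyte"),
    c("AA",             1.92, 3, 1,  12, "analyte"),
    c("N-AcGln",        2.04, 3, 1,  30, "analyte"),
    c("Acetone",        2.16, 6, 1,   5, "analyte"),
    c("Acetoacetate",   2.27, 3, 1,   6, "analyte"),
    c("Pyruvate",       2.38, 3, 1,   9, "analyte"),
    c("CA",             2.54, 4, 2,  60, "analyte"),
    c("Methylamine",    2.66, 3, 1,  10, "analyte"),
    c("DMA",            2.76, 6, 1,  25, "analyte"),
    c("Sar",            2.86, 3, 1,   6, "analyte"),
    c("TMA",            2.96, 9, 1,   4, "analyte"),
    c("Crt",            3.06, 3, 1,  30, "analyte"),
    c("MG",             3.16, 3, 1,   5, "analyte"),
    c("Choline",        3.26, 9, 1,   5, "analyte"),
    c("TMAO",           3.36, 9, 1,  20, "analyte"),
    c("Taurine",        3.46, 2, 1,  80, "analyte"),
    c("Gly",            3.57, 2, 1, 100, "analyte"),
    c("Gln",            3.68, 1, 1,  40, "analyte"),
    c("Betaine",        3.79, 2, 1,  20, "analyte"),
    c("Creatinine",     4.05, 3, 1,   0, "reference"),
    c("Threonine",      4.31, 1, 1,  15, "analyte"),
    c("pyro-Glu",       4.43, 1, 1,  30, "analyte"),
    c("U01",            4.55, 1, 1,  10, "analyte"),
    c("U02",            5.05, 1, 1,   8, "analyte"),
    c("U03",            5.20, 1, 1,   6, "analyte"),
    c("Allantoin",      5.35, 1, 1,  15, "analyte"),
    c("U04",            5.50, 1, 1,  12, "analyte"),
    c("Uridine",        5.90, 1, 2,   6, "analyte"),
    c("Fumarate",       6.52, 2, 1,   3, "analyte"),
    c("Furoylglycine",  6.66, 1, 2,   5, "analyte"),
    c("4-HPAA",         6.88, 2, 2,  15, "analyte"),
    c("4-HbzA",         7.00, 2, 2,   4, "analyte"),
    c("Tyr",            7.20, 2, 2,  12, "analyte"),
    c("Indoxyl-sulfate",7.32, 1, 2,  12, "analyte"),
    c("PAG",            7.44, 2, 2,  35, "analyte"),
    c("Hipp",           7.56, 2, 2,  60, "analyte"),
    c("PSI",            7.68, 1, 1,  30, "analyte"),
    c("Urocanate",      7.82, 1, 1,   6, "analyte"),
    c("Histidine",      7.94, 1, 1,  40, "analyte"),
    c("Hypoxanthine",   8.20, 1, 1,  10, "analyte"),
    c("FA",             8.46, 1, 1,  25, "analyte"),
    c("Trig",           9.12, 1, 1,  30, "analyte"),
    c("1-MNA",          9.28, 1, 1,   8, "analyte")
  )
  data.frame(
    name = tab[, 1],
    center_ppm = as.numeric(tab[, 2]),
    n_protons = as.integer(tab[, 3]),
    multiplicity = as.integer(tab[, 4]),
    baseline_umol_mmol = as.numeric(tab[, 5]),
    role = tab[, 6],
    stringsAsFactors = FALSE
  )
}

#' Default urinary metabolite signal library
#'
#' Returns the built-in signal library used for simulation and
#' quantification: 46 named urinary metabolites plus four unknown-compound
#' placeholders (`U01`--`U04`), together with the two reference signals —
#' the TSP internal standard (9 equivalent protons, 0 ppm) and the
#' creatinine singlet at 4.05 ppm used for dilution normalization. All
#' integration windows are half-open `[lo, hi)` intervals of equal width
#' centred on the resonance and pairwise disjoint, so every signal is
#' overlap-free by construction.
#'
#' Chemical-shift windows are fixture constants in the style of literature
#' urine assignments (not measured values); see the package vignette.
#'
#' @param window_width_ppm full width of each integration window in ppm.
#' @return a list of [metabolite_signal] objects with attributes
#'   `baselines` (named vector of simulator baseline concentrations,
#'   umol/mmol creatinine, analytes only) and `roles` (named character).
#' @export
#' @examples
#' lib <- default_library()
#' length(lib)
#' lib[[which(vapply(lib, `[[`, "", "name") == "Furoylglycine")]]
default_library <- function(window_width_ppm = 0.04) {
  stopifnot_scalar_number(window_width_ppm, "window_width_ppm", positive = TRUE)
  tab <- .library_table()
  half <- window_width_ppm / 2
  sigs <- lapply(seq_len(nrow(tab)), function(i) {
    metabolite_signal(
      name = tab$name[i],
      window_ppm = c(tab$center_ppm[i] - half, tab$center_ppm[i] + half),
      n_protons = tab$n_protons[i],
      multiplicity = tab$multiplicity[i]
    )
  })
  names(sigs) <- tab$name
  baselines <- tab$baseline_umol_mmol[tab$role == "analyte"]
  names(baselines) <- tab$name[tab$role == "analyte"]
  attr(sigs, "baselines") <- baselines
  attr(sigs, "roles") <- stats::setNames(tab$role, tab$name)
  validate_library(sigs)
  sigs
}

#' Validate a signal library
#'
#' Checks that all entries are `metabolite_signal` objects, names are
#' unique, and all integration windows are pairwise disjoint (the
#' overlap-free quantification contract).
#'
#' @param library list of [metabolite_signal] objects.
#' @return the library, invisibly; errors on violation.
#' @export
validate_library <- function(library) {
  if (!is.list(library) || length(library) == 0L) {
    stop("library must be a non-empty list of metabolite_signal objects",
         call. = FALSE)
  }
  ok <- vapply(library, inherits, logical(1), "metabolite_signal")
  if (!all(ok)) {
    stop("library entries must all be metabolite_signal objects", call. = FALSE)
  }
  nm <- vapply(library, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate signal names in library: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  win <- t(vapply(library, `[[`, numeric(2), "window_ppm"))
  o <- order(win[, 1])
  lo <- win[o, 1]; hi <- win[o, 2]
  # half-open intervals: [a,b) and [b,c) do not overlap
  bad <- which(hi[-length(hi)] > lo[-1] + 1e-12)
  if (length(bad)) {
    stop(sprintf("overlapping windows: %s and %s",
                 nm[o][bad[1]], nm[o][bad[1] + 1L]), call. = FALSE)
  }
  invisible(library)
}

# name -> signal lookup with a clear error
library_signal <- function(library, name) {
  nm <- vapply(library, `[[`, character(1), "name")
  i <- match(name, nm)
  if (is.na(i)) stop(sprintf("signal '%s' not found in library", name),
                     call. = FALSE)
  library[[i]]
}

# analyte names in library order (references excluded)
library_analytes <- function(library) {
  roles <- attr(library, "roles")
  nm <- vapply(library, `[[`, character(1), "name")
  if (is.null(roles)) {
    setdiff(nm, c("TSP", "Creatinine"))
  } else {
    nm[roles[nm] == "analyte"]
  }
}
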