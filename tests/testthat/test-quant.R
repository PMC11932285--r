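test_that("integrate_window matches closed forms and the trapezoid oracle", {
  ppm <- seq(0, 1, by = 1e-3)
  # all-zero spectrum
  expect_equal(integrate_window(nmr_spectrum(ppm, numeric(length(ppm))),
                                c(0.2, 0.8)), 0)
  # constant intensity c over width w -> exactly c * w, any grid alignment
  spc <- nmr_spectrum(ppm, rep(3, length(ppm)))
  expect_equal(integrate_window(spc, c(0.1004, 0.6027)),
               3 * (0.6027 - 0.1004), tolerance = 1e-12)
  # unit-height Lorentzian, HWHM gamma: window +/- K*gamma around the center
  gam <- 0.01
  lor <- function(x) gam^2 / ((x - 0.5)^2 + gam^2)
  sp <- nmr_spectrum(ppm, lor(ppm))
  i40 <- integrate_window(sp, c(0.5 - 40 * gam, 0.5 + 40 * gam))
  expect_equal(i40, pi * gam, tolerance = 0.02)              # near-total area
  expect_equal(i40, 2 * gam * atan(40), tolerance = 1e-3)    # truncated form
  expect_equal(i40, trapz_oracle(lor, 0.5 - 40 * gam, 0.5 + 40 * gam),
               tolerance = 1e-3)
})

test_that("integrate_window rejects invalid windows", {
  sp <- nmr_spectrum(seq(0, 1, by = 0.01), rep(1, 101))
  expect_error(integrate_window(sp, c(0.5, 1.5)), "outside")
  expect_error(integrate_window(sp, c(0.501, 0.509)), "fewer than 2")
  expect_error(integrate_window(sp, c(0.8, 0.2)), "lo < hi")
})

test_that("a 2-proton signal at 2/9 of the TSP integral quantifies to the
           internal-standard concentration", {
  lib <- tiny_library()
  cfg <- tiny_spectrum_config()
  # analyte A (2 protons) at 1.82 mM: 182 umol/mmol at 10 mM creatinine
  sp <- synthesize_spectrum(c(A = 182), cfg, lib)
  qc <- quant_config()
  i_tsp <- integrate_window(sp, qc$tsp_window_ppm)
  i_a <- integrate_window(sp, lib[["A"]]$window_ppm)
  expect_equal(i_a / i_tsp, 2 / 9, tolerance = 1e-10)
  conc <- quantify(sp, lib, qc)
  expect_equal(unname(conc["A"]), 1.82, tolerance = 1e-10)
  expect_equal(unname(conc["B"]), 0)  # absent analyte: zero integral -> 0 mM
})

test_that("a known molar concentration is recovered within 1%", {
  lib <- tiny_library()
  # 3.0 mM of the 2-proton analyte = 300 umol/mmol at 10 mM creatinine
  sp <- synthesize_spectrum(c(A = 300), tiny_spectrum_config(), lib)
  conc <- quantify(sp, lib)
  expect_equal(unname(conc["A"]), 3.0, tolerance = 0.01)
})

test_that("quantification is invariant to global intensity scaling", {
  lib <- tiny_library()
  sp <- synthesize_spectrum(c(A = 40, B = 10, C = 75),
                            tiny_spectrum_config(), lib)
  for (k in c(0.2, 5, 1000)) {
    spk <- nmr_spectrum(sp$ppm, k * sp$intensity, sp$subject_id)
    expect_equal(quantify(spk, lib), quantify(sp, lib), tolerance = 1e-10)
  }
})

test_that("creatinine normalization is plain unit arithmetic", {
  expect_equal(normalize_to_creatinine(1, 1), 1000)
  expect_equal(normalize_to_creatinine(0, 5), 0)
  expect_equal(normalize_to_creatinine(0.5, 10), 50)
  expect_error(normalize_to_creatinine(1, 0), "> 0")
  expect_error(normalize_to_creatinine(1, -2), "> 0")
})

test_that("quantify demands a usable TSP reference and clamps negatives", {
  lib <- tiny_library()
  ppm <- seq(-0.5, 6, by = 1e-3)
  flat <- nmr_spectrum(ppm, numeric(length(ppm)))
  expect_error(quantify(flat, lib), "TSP")
  # negative analyte window on a valid reference: clamped with a warning
  y <- numeric(length(ppm))
  y[abs(ppm) < 0.02] <- 1000
  y[abs(ppm - 2) < 0.02] <- -5
  y[abs(ppm - 4.05) < 0.02] <- 100
  sp <- nmr_spectrum(ppm, y)
  expect_warning(conc <- quantify(sp, lib), "clamped")
  expect_equal(unname(conc["A"]), 0)
})

test_that("build_matrix preserves subject order and validates input", {
  lib <- tiny_library()
  cfg <- tiny_spectrum_config()
  m <- simulate_concentrations(
    sim_config(n_exposed = 2, n_control = 3, library = lib, seed = 8,
               effects = list()))
  spectra <- synthesize_cohort(m, cfg, lib)
  tab <- build_matrix(spectra, m$group, lib)
  expect_equal(dim(conc_values(tab)), c(5L, 3L))
  expect_equal(tab$subject_id, m$subject_id)
  # permuting the input spectra permutes the rows identically
  perm <- c(3, 1, 5, 2, 4)
  tab_p <- build_matrix(spectra[perm], m$group[perm], lib)
  expect_equal(conc_values(tab_p), conc_values(tab)[perm, ],
               tolerance = 1e-12)
  expect_equal(tab_p$subject_id, tab$subject_id[perm])
  expect_error(build_matrix(list(), factor(character())), "non-empty")
  expect_error(build_matrix(spectra, m$group[1:2]), "one label per spectrum")
})
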