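test_that("empty analyte spectrum is nonzero only at the reference signals", {
  lib <- tiny_library()
  cfg <- tiny_spectrum_config()
  sp <- synthesize_spectrum(numeric(0), cfg, lib)
  cutoff <- cfg$tail_cutoff_ppm
  near_ref <- (abs(sp$ppm - 0) <= cutoff) | (abs(sp$ppm - 4.05) <= cutoff)
  expect_true(all(sp$intensity[!near_ref] == 0))
  expect_true(any(sp$intensity[near_ref] > 0))
  for (a in c("A", "B", "C")) {
    expect_equal(integrate_window(sp, lib[[a]]$window_ppm), 0)
  }
})

test_that("window integrals are linear in concentration", {
  lib <- tiny_library()
  cfg <- tiny_spectrum_config()
  s1 <- synthesize_spectrum(c(A = 50, B = 20), cfg, lib)
  s2 <- synthesize_spectrum(c(A = 100, B = 20), cfg, lib)
  iA1 <- integrate_window(s1, lib[["A"]]$window_ppm)
  iA2 <- integrate_window(s2, lib[["A"]]$window_ppm)
  expect_equal(iA2 / iA1, 2, tolerance = 1e-10)
  # untouched metabolite unchanged
  expect_equal(integrate_window(s2, lib[["B"]]$window_ppm),
               integrate_window(s1, lib[["B"]]$window_ppm),
               tolerance = 1e-12)
})

test_that("reference singlets peak at their nominal shifts", {
  sp <- synthesize_spectrum(numeric(0), spectrum_config(), default_library())
  near_tsp <- abs(sp$ppm) < 0.1
  expect_equal(sp$ppm[near_tsp][which.max(sp$intensity[near_tsp])], 0)
  near_cr <- abs(sp$ppm - 4.05) < 0.1
  expect_equal(sp$ppm[near_cr][which.max(sp$intensity[near_cr])], 4.05)
})

test_that("quantification round-trips synthesized concentrations within 1%", {
  lib <- default_library()
  cfg <- spectrum_config()
  # deterministic: library baselines
  base <- attr(lib, "baselines")
  sp <- synthesize_spectrum(base, cfg, lib)
  conc <- quantify(sp, lib)
  rec <- normalize_to_creatinine(conc, attr(conc, "creatinine_mM"))
  expect_true(all(abs(rec - base) / base < 0.01))
  # one simulated subject (log-normal spread), noiseless spectrum
  m <- simulate_concentrations(sim_config(seed = 17))
  truth <- conc_values(m)[1, ]
  sp2 <- synthesize_spectrum(truth, cfg, lib)
  conc2 <- quantify(sp2, lib)
  rec2 <- normalize_to_creatinine(conc2, attr(conc2, "creatinine_mM"))
  expect_true(all(abs(rec2 - truth) / truth < 0.01))
})

test_that("additive noise is reproducible under a seed", {
  lib <- tiny_library()
  cfg <- tiny_spectrum_config(additive_noise_sd = 0.5)
  s1 <- synthesize_spectrum(c(A = 10), cfg, lib, noise_seed = 99)
  s2 <- synthesize_spectrum(c(A = 10), cfg, lib, noise_seed = 99)
  s3 <- synthesize_spectrum(c(A = 10), cfg, lib, noise_seed = 100)
  expect_identical(s1$intensity, s2$intensity)
  expect_false(identical(s1$intensity, s3$intensity))
})

test_that("spectra survive the two-column text round trip", {
  lib <- tiny_library()
  cfg <- tiny_spectrum_config()
  m <- simulate_concentrations(
    sim_config(n_exposed = 2, n_control = 2, library = lib, seed = 4,
               effects = list()))
  spectra <- synthesize_cohort(m, cfg, lib)
  dir <- withr::local_tempdir()
  write_spectra(spectra, m$group, dir)
  back <- read_spectra(dir)
  expect_equal(names(back$spectra), m$subject_id)
  expect_equal(back$groups, m$group)
  expect_equal(back$spectra[[1]]$intensity, spectra[[1]]$intensity,
               tolerance = 1e-12)
})

test_that("synthesis validates its inputs", {
  lib <- tiny_library()
  expect_error(synthesize_spectrum(c(A = -1), tiny_spectrum_config(), lib),
               ">= 0")
  expect_error(synthesize_spectrum(c(Z = 1), tiny_spectrum_config(), lib),
               "named with library analytes")
  # grid not covering a window
  expect_error(
    synthesize_spectrum(c(A = 1), spectrum_config(ppm_grid = c(0.5, 6, 1000)),
                        lib),
    "outside the ppm grid")
})
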