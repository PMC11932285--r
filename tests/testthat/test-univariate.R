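test_that("identical groups yield a flagged non-significant result", {
  x <- rep(3.2, 8)
  r <- route_and_test(x, x)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  expect_true(r$flagged)
  expect_error(route_and_test(c(1, 2), c(1, 2, 3)), "n >= 3")
  expect_error(route_and_test(c(1, NA, 2), c(1, 2, 3)), "missing")
})

test_that("the routing decision always matches the recomputed assumption
           checks, and Gaussian data routes to t at the composed rate", {
  set.seed(81)
  n_t <- 0
  n_rep <- 150
  for (i in seq_len(n_rep)) {
    xc <- rnorm(13); xe <- rnorm(12)
    r <- route_and_test(xc, xe)
    # independent recomputation of the gate
    normal <- stats::shapiro.test(xc)$p.value > 0.05 &&
      stats::shapiro.test(xe)$p.value > 0.05
    g <- factor(rep(c("c", "e"), c(13, 12)))
    homosc <- car::leveneTest(c(xc, xe) ~ g,
                              center = median)[["Pr(>F)"]][1] > 0.05
    expect_equal(r$test_used, if (normal && homosc) "t" else "wilcoxon")
    n_t <- n_t + (r$test_used == "t")
  }
  # gate = two Shapiro tests and one Levene test at alpha 0.05, so the
  # ideal-case t rate is ~0.95^3 = 0.857; allow ~4 Monte-Carlo sds
  expect_gt(n_t / n_rep, 0.74)
  expect_lt(n_t / n_rep, 0.96)
})

test_that("heavy-tailed shifted data routes to Wilcoxon with the expected
           Monte-Carlo power", {
  set.seed(82)
  n_rep <- 150
  used <- character(n_rep); rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    xc <- exp(rnorm(13, sd = 1))
    xe <- exp(rnorm(12, sd = 1) + log(2))  # 2x median shift
    r <- route_and_test(xc, xe)
    used[i] <- r$test_used
    rej[i] <- r$significant
  }
  expect_gt(mean(used == "wilcoxon"), 0.5)
  # frozen Monte-Carlo band for Wilcoxon power at a 0.69-sd log shift
  expect_gt(mean(rej), 0.25)
  expect_lt(mean(rej), 0.50)
})

test_that("rejection rate grows monotonically with the effect size", {
  set.seed(83)
  rate <- vapply(c(0, 0.8, 1.6), function(delta) {
    mean(replicate(120, {
      route_and_test(rnorm(13), rnorm(12, mean = delta))$significant
    }))
  }, numeric(1))
  expect_true(all(diff(rate) > 0))
  expect_lt(rate[1], 0.15)
  expect_gt(rate[3], 0.85)
})

test_that("run_univariate preserves column order, adjusts p-values and
           recovers injected directions", {
  # the reported direction pattern: 13 metabolites down, 2 up in exposed
  down <- c("Leu", "Ile", "Threo-2,3-DHBA", "3-H-3MBA", "AA", "N-AcGln",
            "Sar", "Crt", "Val", "3-HIBA", "4-HPAA", "Tyr", "4-HbzA")
  up <- c("Furoylglycine", "U03")
  effs <- c(lapply(down, effect_spec, log2_fold_change = -0.65),
            lapply(up, effect_spec, log2_fold_change = 0.65))
  m <- simulate_concentrations(sim_config(effects = effs, seed = 84))
  res <- run_univariate(m)
  expect_equal(res$metabolite, colnames(conc_values(m)))
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
  detected <- res[res$significant & res$metabolite %in% c(down, up), ]
  expect_gt(nrow(detected), 0)
  expect_true(all(
    detected$direction[detected$metabolite %in% down] == "down_in_exposed"))
  expect_true(all(
    detected$direction[detected$metabolite %in% up] == "up_in_exposed"))
  s <- attr(res, "summary")
  expect_equal(unname(s["significant_up"] + s["significant_down"]),
               sum(res$significant))
})

test_that("a single-metabolite matrix yields a single result row", {
  m <- simulate_concentrations(sim_config(seed = 85))
  m1 <- m[, c("subject_id", "group", "Gly")]
  class(m1) <- c("conc_matrix", "data.frame")
  res <- run_univariate(m1)
  expect_equal(nrow(res), 1L)
  m0 <- m
  m0$group <- factor(rep("CTRL", 25), levels = c("CTRL", "Exposed"))
  expect_error(run_univariate(m0), "both groups")
})

test_that("the null rejection rate sits near the nominal 5% level", {
  set.seed(86)
  rej <- replicate(400, {
    route_and_test(exp(rnorm(13, sd = 0.3)),
                   exp(rnorm(12, sd = 0.3)))$significant
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
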