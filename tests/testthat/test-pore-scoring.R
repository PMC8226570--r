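pore <- example_pore_model()
coefs <- example_coefficients()

test_that("steric term follows the Gaussian-overlap limits", {
  p <- pore_model(v_pore = -30, e_pore = 30, area_mean = 50, area_sd = 2)
  expect_equal(steric_term(50, 2, p), log(0.5), tolerance = 1e-12)
  # equal sds of zero: regulariser keeps the ratio finite, still log(1/2)
  p0 <- pore_model(v_pore = -30, e_pore = 30, area_mean = 50, area_sd = 0)
  expect_equal(steric_term(50, 0, p0), log(0.5), tolerance = 1e-12)
  # molecule far below the pore size: barrier vanishes
  expect_gt(steric_term(50 - 10 * 2.83, 2, p), -1e-10)
  expect_lte(max(steric_term(seq(10, 120, 5), 1, p)), 0)
  expect_error(steric_term(-3, 1, p), "mpa_mean")
})

test_that("steric term is monotone in size, pore area and flexibility", {
  p <- pore_model(v_pore = -30, e_pore = 30, area_mean = 55, area_sd = 5)
  sizes <- seq(20, 110, 2)
  u <- steric_term(sizes, 2, p)
  expect_true(all(diff(u) <= 0)) # bigger molecule, higher barrier
  areas <- seq(30, 90, 2)
  u2 <- vapply(areas, function(a) {
    steric_term(60, 2, pore_model(v_pore = -30, e_pore = 30,
                                  area_mean = a, area_sd = 5))
  }, numeric(1))
  expect_true(all(diff(u2) >= 0)) # wider pore, lower barrier
  # molecule larger than the pore: flexibility (mpa_sd) helps
  u3 <- steric_term(70, seq(0, 10, 0.5), p)
  expect_true(all(diff(u3) > 0))
})

test_that("score is the exact linear combination of its stored terms", {
  tab <- random_compound_table(40, seed = 1)
  scored <- permeability_score(tab, pore, coefs)
  expect_equal(scored$score,
               scored$steric_term + scored$charge_term +
                 scored$dipole_term + coefs$delta,
               tolerance = 1e-12)
  expect_equal(scored$steric_term, coefs$alpha * scored$u_steric,
               tolerance = 1e-12)
  # degenerate coefficients: every compound collapses to delta
  flat <- permeability_score(tab, pore, scoring_coefficients(0, 0, 0, 2.5))
  expect_true(all(flat$score == 2.5))
  # exact linearity in net charge: slope beta * v_pore per unit charge
  bumped <- permeability_score(dplyr::mutate(tab, net_charge = net_charge + 1L),
                               pore, coefs)
  expect_equal(bumped$score - scored$score,
               rep(coefs$beta * pore$v_pore, nrow(tab)), tolerance = 1e-12)
  # and in transversal dipole: slope gamma * e_pore per Debye
  bumped_d <- permeability_score(
    dplyr::mutate(tab, transversal_dipole = transversal_dipole + 1),
    pore, coefs
  )
  expect_equal(bumped_d$score - scored$score,
               rep(coefs$gamma * pore$e_pore, nrow(tab)), tolerance = 1e-12)
})

test_that("percent of glycine anchors at 100% and exponentiates differences", {
  cal <- calibrate_glycine(pore, coefs)
  g <- cal$glycine_score
  expect_equal(percent_of_glycine(g, cal), 100)
  expect_equal(percent_of_glycine(g + log(2), cal), 200)
  expect_equal(percent_of_glycine(g - 1.109, cal), 33, tolerance = 0.01)
  expect_true(all(percent_of_glycine(rnorm(50, g, 3), cal) > 0))
  expect_error(percent_of_glycine(1, pore), "calibrat")
  # strictly increasing in score
  s <- seq(g - 5, g + 5, 0.25)
  expect_true(all(diff(percent_of_glycine(s, cal)) > 0))
})

test_that("permeability categories respect the 30/50/70 boundaries", {
  expect_equal(as.character(categorize_permeability(c(33, 29.999, 30, 49.999,
                                                      50, 70, 70.001, 71))),
               c("poor", "very_bad", "poor", "poor",
                 "good", "good", "excellent", "excellent"))
  expect_error(categorize_permeability(c(10, -1)), "> 0")
  # category from percent agrees with direct score thresholding at the
  # equivalent log cutoffs
  cal <- calibrate_glycine(pore, coefs)
  g <- cal$glycine_score
  scores <- seq(g - 4, g + 3, length.out = 81)
  pct <- percent_of_glycine(scores, cal)
  via_percent <- categorize_permeability(pct)
  cuts <- g + log(c(30, 50, 70) / 100)
  via_score <- cut(scores, c(-Inf, cuts[1], cuts[2], cuts[3], Inf),
                   labels = c("very_bad", "poor", "good", "excellent"),
                   right = FALSE)
  # boundary convention: good includes both ends, cut() half-open; compare
  # away from exact boundaries
  off <- abs(outer(scores, cuts, "-")) > 1e-9
  keep <- rowSums(off == FALSE) == 0
  expect_equal(as.character(via_percent)[keep], as.character(via_score)[keep])
})

test_that("fit_coefficients inverts the scoring function", {
  planted <- scoring_coefficients(alpha = 0.8, beta = -0.03, gamma = 0.006,
                                  delta = 1.4)
  tab <- random_compound_table(50, seed = 3)
  scored <- permeability_score(tab, pore, planted)
  train <- dplyr::mutate(tab, reference_score = scored$score)
  fit <- fit_coefficients(train, pore)
  expect_equal(fit$coefficients$alpha, planted$alpha, tolerance = 1e-8)
  expect_equal(fit$coefficients$beta, planted$beta, tolerance = 1e-8)
  expect_equal(fit$coefficients$gamma, planted$gamma, tolerance = 1e-8)
  expect_equal(fit$coefficients$delta, planted$delta, tolerance = 1e-8)

  # diagnostics expose the fit quality (summary.lm warns on an exact fit)
  expect_s3_class(suppressWarnings(tidy(fit)), "tbl_df")
  g <- suppressWarnings(glance(fit))
  expect_equal(g$r.squared, 1, tolerance = 1e-10)
  expect_equal(g$n, 50)

  expect_error(fit_coefficients(head(train, 3), pore), "at least 4")
  # all-neutral training set: the charge regressor is identically zero
  flat <- dplyr::mutate(train, net_charge = 0L)
  expect_error(fit_coefficients(flat, pore), "charge_x")
})
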