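test_that("filters apply the 45 nmol and alogP 2.9 cutoffs strictly", {
  toy <- tibble::tibble(
    id = letters[1:5],
    accumulation = c(10, 100, 200, 300, 400),
    alogp = c(1, 3.5, 1, 1, 1)
  )
  f <- filter_dataset(toy)
  expect_equal(nrow(f$records), 3)
  expect_equal(f$audit$low_accumulation, 1)
  expect_equal(f$audit$nonpolar, 1)
  expect_equal(f$audit$overlap, 0)
  # boundary rows survive: the comparisons are strict
  edge <- tibble::tibble(id = c("at45", "at29"),
                         accumulation = c(45, 500), alogp = c(0, 2.9))
  fe <- filter_dataset(edge)
  expect_equal(nrow(fe$records), 2)
  expect_warning(filter_dataset(tibble::tibble(id = "x", accumulation = 1,
                                               alogp = 5)),
                 "no compounds")
})

test_that("filter audit identity holds on randomised tables", {
  for (s in 1:20) {
    tab <- random_compound_table(60, seed = 100 + s)
    cuts <- c(runif(1, 10, 200), runif(1, 0, 3))
    f <- filter_dataset(tab, accumulation_cutoff = cuts[1],
                        alogp_cutoff = cuts[2])
    a <- f$audit
    expect_equal(a$kept,
                 a$total - a$low_accumulation - a$nonpolar + a$overlap)
    expect_equal(a$kept, nrow(f$records))
    # order independence
    f2 <- filter_dataset(tab[sample(nrow(tab)), ],
                         accumulation_cutoff = cuts[1],
                         alogp_cutoff = cuts[2])
    expect_setequal(f2$records$id, f$records$id)
  }
})

test_that("accumulation categories respect the 250/550/1000 boundaries", {
  expect_equal(
    as.character(categorize_accumulation(c(100, 249.99, 250, 550, 550.01,
                                           600, 1000, 1000.01, 1500))),
    c("low", "low", "accumulator", "accumulator", "good",
      "good", "good", "excellent", "excellent")
  )
  expect_error(categorize_accumulation(-5), ">= 0")
})

test_that("log-log regression matches the explicit Pearson formula", {
  # exactly collinear points
  col <- tibble::tibble(id = as.character(1:10), percent = exp(1:10 / 2),
                        accumulation = exp(2 + 0.7 * (1:10 / 2)))
  r1 <- loglog_regression(col)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p_value, 1e-12)
  expect_equal(r1$slope, 0.7, tolerance = 1e-9)
  anti <- dplyr::mutate(col, accumulation = exp(2 - 0.7 * log(percent)))
  expect_equal(loglog_regression(anti)$r, -1, tolerance = 1e-12)

  # planted-noise synthetic set, checked against the textbook formula
  tab <- generate_table(generator_config(n_compounds = 137, seed = 8,
                                         target_r = 0.74,
                                         n_low_accumulation = 0,
                                         n_nonpolar = 0, n_overlap = 0))
  recs <- dplyr::mutate(tab, percent = true_percent)
  res <- loglog_regression(recs)
  expect_equal(res$n, 137)
  expect_equal(res$r,
               oracle_pearson(log(recs$percent), log(recs$accumulation)),
               tolerance = 1e-12)
  expect_equal(res$r, 0.74, tolerance = 0.12) # single-sample draw

  bad <- dplyr::mutate(col, accumulation = replace(accumulation, 2, 0))
  expect_error(loglog_regression(bad), "2")
})

test_that("Pearson r is invariant under positive rescaling of either axis", {
  tab <- generate_table(generator_config(n_compounds = 60, seed = 4,
                                         n_low_accumulation = 0,
                                         n_nonpolar = 0, n_overlap = 0))
  recs <- dplyr::mutate(tab, percent = true_percent)
  r0 <- loglog_regression(recs)$r
  r1 <- loglog_regression(dplyr::mutate(recs, percent = percent * 37))$r
  r2 <- loglog_regression(dplyr::mutate(recs, accumulation = accumulation / 5))$r
  expect_equal(r1, r0, tolerance = 1e-12)
  expect_equal(r2, r0, tolerance = 1e-12)
})

test_that("the default synthetic study reduces 189 compounds to 137 analysed", {
  tab <- generate_table(generator_config(seed = 7, target_r = 0.74))
  expect_equal(nrow(tab), 189)
  rep <- run_pipeline(tab, example_run_config())
  a <- rep$audit
  expect_equal(a$kept, 137)
  expect_equal(a$low_accumulation, 35) # 34 exclusive + 1 overlapping
  expect_equal(a$nonpolar, 18)         # 17 exclusive + 1 overlapping
  expect_equal(a$overlap, 1)
  expect_equal(a$kept, a$total - a$low_accumulation - a$nonpolar + a$overlap)
  expect_equal(rep$regression$n, 137)
  expect_lt(rep$regression$p_value, 0.05)
  # cross-tab conservation
  expect_equal(sum(rep$crosstab), 137)
  expect_equal(as.integer(rowSums(rep$crosstab)),
               as.integer(table(rep$per_compound$category)[rownames(rep$crosstab)]))
})

test_that("pipeline rejects broken inputs with actionable errors", {
  cfg <- example_run_config()
  expect_error(run_pipeline(tibble::tibble(), cfg), "non-empty")
  tab <- generate_table(generator_config(n_compounds = 10, seed = 1,
                                         n_low_accumulation = 0,
                                         n_nonpolar = 0, n_overlap = 0))
  nocoef <- cfg
  nocoef$coefficients <- NULL
  expect_error(run_pipeline(tab, nocoef), "calibration required")
  broken <- dplyr::mutate(tab, accumulation = replace(accumulation, 3, -2))
  expect_error(run_pipeline(broken, cfg), "rows 3")
})
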