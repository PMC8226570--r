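#' Filter a compound/accumulation table for the porin analysis
#'
#' Removes compounds whose measured whole-cell accumulation is below
#' `accumulation_cutoff` (by default 45 nmol per 1e12 CFUs, the level at
#' which covalent binders such as ampicillin escape LC-MS/MS detection)
#' and non-polar compounds with `alogp > alogp_cutoff` (default 2.9),
#' which do not use the porin route. Both comparisons are strict, so a
#' compound at exactly 45 or exactly 2.9 is kept. The result is
#' order-independent; the audit reports how many rows each rule removed
#' and their overlap, satisfying
#' `kept = total - low_accumulation - nonpolar + overlap`.
#'
#' @param records Data frame with at least `accumulation` and `alogp`
#'   columns.
#' @param accumulation_cutoff Accumulation threshold (nmol per 1e12
#'   CFUs).
#' @param alogp_cutoff Hydrophobicity threshold (alogP).
#' @return A list of class `porin_filter` with elements `records` (the
#'   kept tibble) and `audit` (a one-row tibble of counts). A warning is
#'   raised when nothing survives.
#' @export
filter_dataset <- function(records, accumulation_cutoff = 45,
                           alogp_cutoff = 2.9) {
  if (nrow(records) == 0L) abort("records must be non-empty")
  stopifnot(all(c("accumulation", "alogp") %in% names(records)))
  records <- tibble::as_tibble(records)
  low <- records$accumulation < accumulation_cutoff
  nonpolar <- records$alogp > alogp_cutoff
  kept <- records[!low & !nonpolar, , drop = FALSE]
  n_overlap <- sum(low & nonpolar)
  audit <- tibble::tibble(
    total = nrow(records),
    low_accumulation = sum(low),
    nonpolar = sum(nonpolar),
    overlap = n_overlap,
    kept = nrow(kept),
    accumulation_cutoff = accumulation_cutoff,
    alogp_cutoff = alogp_cutoff
  )
  if (nrow(kept) == 0L) warn("no compounds survive the filters")
  structure(list(records = kept, audit = audit), class = "porin_filter")
}

#' @export
print.porin_filter <- function(x, ...) {
  a <- x$audit
  cat(sprintf(
    "<porin_filter> %d/%d kept (%d low accumulation, %d non-polar, %d overlapping)\n",
    a$kept, a$total, a$low_accumulation, a$nonpolar, a$overlap
  ))
  invisible(x)
}

#' Accumulation categories
#'
#' Bins whole-cell accumulation (nmol per 1e12 CFUs) into `low`
#' (< 250), `accumulator` (250 to 550, both ends included), `good`
#' (> 550 to 1000) and `excellent` (> 1000).
#'
#' @param value Non-negative numeric vector.
#' @return Factor with levels `low`, `accumulator`, `good`, `excellent`.
#' @export
categorize_accumulation <- function(value) {
  if (any(!is.finite(value)) || any(value < 0)) {
    abort("accumulation must be finite and >= 0")
  }
  lab <- ifelse(value < 250, "low",
         ifelse(value <= 550, "accumulator",
         ifelse(value <= 1000, "good", "excellent")))
  factor(lab, levels = c("low", "accumulator", "good", "excellent"))
}

#' Log-log regression of accumulation on predicted permeability
#'
#' Ordinary least squares of `ln(accumulation)` on `ln(percent)` (the
#' glycine-relative predicted permeability), with the Pearson
#' correlation coefficient and its two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom. Pearson r on the log
#' scale is invariant under positive rescaling of either variable, so
#' using percent-of-glycine rather than the raw permeability only
#' shifts the intercept.
#'
#' @param records Data frame with strictly positive `accumulation` and
#'   `percent` columns (and typically `id`), normally the kept records
#'   of [filter_dataset()] after scoring.
#' @return An object of class `porin_loglog` with elements `n`, `r`,
#'   `p_value`, `slope`, `intercept`, `fit` (the `lm`) and `data`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
loglog_regression <- function(records) {
  stopifnot(all(c("accumulation", "percent") %in% names(records)))
  n <- nrow(records)
  if (n < 3L) abort(sprintf("need at least 3 records, got %d", n))
  bad <- records$accumulation <= 0 | records$percent <= 0
  if (any(bad)) {
    ids <- if ("id" %in% names(records)) records$id[bad] else which(bad)
    abort(paste0(
      "non-positive accumulation or percent would reach the logarithm ",
      "(should have been filtered) for: ",
      paste(head(ids, 10L), collapse = ", ")
    ))
  }
  df <- tibble::tibble(
    log_percent = log(records$percent),
    log_accumulation = log(records$accumulation)
  )
  fit <- lm(log_accumulation ~ log_percent, data = df)
  ct <- cor.test(df$log_percent, df$log_accumulation,
                 alternative = "two.sided", method = "pearson")
  structure(
    list(
      n = n,
      r = unname(ct$estimate),
      p_value = ct$p.value,
      slope = unname(coef(fit)["log_percent"]),
      intercept = unname(coef(fit)["(Intercept)"]),
      fit = fit,
      data = tibble::as_tibble(records)
    ),
    class = "porin_loglog"
  )
}

#' @export
print.porin_loglog <- function(x, ...) {
  cat(sprintf(
    "<porin_loglog> n = %d, R = %.3f (p = %.3g), ln(acc) = %.3f + %.3f ln(percent)\n",
    x$n, x$r, x$p_value, x$intercept, x$slope
  ))
  invisible(x)
}

#' @rdname loglog_regression
#' @param x A `porin_loglog`.
#' @param ... Unused.
#' @export
tidy.porin_loglog <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname loglog_regression
#' @export
glance.porin_loglog <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    r = x$r,
    r.squared = x$r^2,
    p.value = x$p_value,
    slope = x$slope,
    intercept = x$intercept
  )
}

#' Run the full accumulation analysis pipeline
#'
#' Orchestrates the analysis on a descriptor/accumulation table:
#' validates the table, calibrates the glycine anchor if needed, scores
#' every compound, applies the accumulation and hydrophobicity filters,
#' assigns accumulation and permeability categories, cross-tabulates
#' them, and fits the log-log regression of accumulation on predicted
#' permeability.
#'
#' @param table Compound table with the canonical columns `id`,
#'   `net_charge`, `total_dipole`, `transversal_dipole`, `mpa_mean`,
#'   `mpa_sd`, `alogp`, `accumulation` (see [read_compound_table()]).
#' @param config A run configuration list with elements `pore` (a
#'   [pore_model()]) and `coefficients` (a [scoring_coefficients()]),
#'   optionally `accumulation_cutoff`, `alogp_cutoff`, `epsilon`; see
#'   [read_run_config()] and [example_run_config()].
#' @return An object of class `porin_report`: a list with
#'   `per_compound` (scored, categorised tibble of the analysed
#'   compounds, plus a `kept` flag on the full table under
#'   `all_compounds`), `audit` (filter counts), `crosstab`
#'   (permeability x accumulation categories), `regression` (a
#'   `porin_loglog`), and `config` metadata.
#' @export
run_pipeline <- function(table, config) {
  if (is.null(config$coefficients)) {
    abort(paste("config has no scoring coefficients: calibration required",
                "(fit_coefficients() or supply a coefficients block)"))
  }
  if (is.null(config$pore)) abort("config has no pore model")
  stopifnot(inherits(config$pore, "pore_model"),
            inherits(config$coefficients, "scoring_coefficients"))
  table <- validate_compound_table(table)
  eps <- config$epsilon %||% 0.1
  acc_cut <- config$accumulation_cutoff %||% 45
  alogp_cut <- config$alogp_cutoff %||% 2.9
  pore <- config$pore
  if (is.na(pore$glycine_score)) {
    pore <- calibrate_glycine(pore, config$coefficients, epsilon = eps)
  }
  scored <- permeability_score(table, pore, config$coefficients,
                               epsilon = eps)
  flt <- filter_dataset(scored, accumulation_cutoff = acc_cut,
                        alogp_cutoff = alogp_cut)
  analysed <- dplyr::mutate(
    flt$records,
    accumulation_category = categorize_accumulation(.data$accumulation)
  )
  crosstab <- table(
    permeability = analysed$category,
    accumulation = analysed$accumulation_category
  )
  regression <- if (nrow(analysed) >= 3L) loglog_regression(analysed) else NULL
  structure(
    list(
      per_compound = analysed,
      all_compounds = dplyr::mutate(scored, kept = .data$id %in% analysed$id),
      audit = flt$audit,
      crosstab = crosstab,
      regression = regression,
      config = list(
        pore = pore,
        coefficients = config$coefficients,
        accumulation_cutoff = acc_cut,
        alogp_cutoff = alogp_cut,
        epsilon = eps
      )
    ),
    class = "porin_report"
  )
}

#' @export
print.porin_report <- function(x, ...) {
  a <- x$audit
  cat(sprintf("<porin_report> %d compounds, %d analysed\n", a$total, a$kept))
  cat(sprintf("  removed: %d low accumulation, %d non-polar (%d overlap)\n",
              a$low_accumulation, a$nonpolar, a$overlap))
  if (!is.null(x$regression)) {
    cat(sprintf("  regression: R = %.3f (p = %.3g) on n = %d\n",
                x$regression$r, x$regression$p_value, x$regression$n))
  } else {
    cat("  regression: not fitted (fewer than 3 analysed compounds)\n")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `porin_report`.
#' @param ... Unused.
#' @export
glance.porin_report <- function(x, ...) {
  a <- x$audit
  reg <- x$regression
  tibble::tibble(
    total = a$total,
    low_accumulation = a$low_accumulation,
    nonpolar = a$nonpolar,
    overlap = a$overlap,
    analysed = a$kept,
    r = if (is.null(reg)) NA_real_ else reg$r,
    p.value = if (is.null(reg)) NA_real_ else reg$p_value,
    slope = if (is.null(reg)) NA_real_ else reg$slope,
    intercept = if (is.null(reg)) NA_real_ else reg$intercept
  )
}
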