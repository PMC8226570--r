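#' Pore model for permeability scoring
#'
#' Describes the general porin the score is computed against: its
#' internal electrostatic potential (negative for a cation-selective
#' pore such as OmpF), its characteristic transversal electric field,
#' and the size distribution of its constriction region (mean
#' cross-section and fluctuation). `glycine_score` anchors the
#' percent-of-glycine scale and is set by [calibrate_glycine()].
#'
#' The shipped [example_pore_model()] carries illustrative values for an
#' OmpF-like pore; the trained pore parameters of the original scoring
#' work are not public, so every number here is a configuration input.
#'
#' @param name Pore name (default `"OmpF"`).
#' @param v_pore Pore electrostatic potential (mV).
#' @param e_pore Characteristic transversal electric field (mV/Angstrom).
#' @param area_mean Mean constriction cross-section (Angstrom^2), > 0.
#' @param area_sd Constriction-area fluctuation (Angstrom^2), >= 0.
#' @param glycine_score Reference score of glycine under the active
#'   coefficients (dimensionless); `NA` until calibrated.
#' @return An object of class `pore_model`.
#' @export
pore_model <- function(name = "OmpF", v_pore, e_pore, area_mean, area_sd,
                       glycine_score = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in list(v_pore, e_pore, area_mean, area_sd)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort("pore parameters must be finite scalars")
    }
  }
  if (area_mean <= 0) abort("area_mean must be > 0")
  if (area_sd < 0) abort("area_sd must be >= 0")
  structure(
    list(name = name, v_pore = v_pore, e_pore = e_pore,
         area_mean = area_mean, area_sd = area_sd,
         glycine_score = glycine_score),
    class = "pore_model"
  )
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf(
    "<pore_model> %s: V = %g mV, E = %g mV/A, constriction %g +/- %g A^2, glycine score %s\n",
    x$name, x$v_pore, x$e_pore, x$area_mean, x$area_sd,
    if (is.na(x$glycine_score)) "uncalibrated" else format(x$glycine_score)
  ))
  invisible(x)
}

#' Scoring coefficients
#'
#' The four weights of the interaction-based permeability score:
#' `alpha` (steric term), `beta` (charge-potential term), `gamma`
#' (transversal dipole-field term) and `delta` (offset). The trained
#' values of the original scoring function are not public; coefficients
#' are configuration inputs, obtainable from reference data with
#' [fit_coefficients()]. Units are absorbed by the coefficients so the
#' score is dimensionless.
#'
#' @param alpha,beta,gamma,delta Finite numeric scalars.
#' @return An object of class `scoring_coefficients`.
#' @export
scoring_coefficients <- function(alpha, beta, gamma, delta) {
  v <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (!is.numeric(v) || length(v) != 4L || !all(is.finite(v))) {
    abort("all four coefficients must be finite numbers")
  }
  structure(as.list(v), class = "scoring_coefficients")
}

#' @export
print.scoring_coefficients <- function(x, ...) {
  cat(sprintf("<scoring_coefficients> alpha = %g, beta = %g, gamma = %g, delta = %g\n",
              x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' Steric size-exclusion term
#'
#' Overlap of the molecule's minimal-projection-area distribution with
#' the pore's constriction-size distribution, modelled as the
#' log-probability that a Gaussian with the pooled spread puts the
#' molecule below the pore cross-section:
#' `U = log Phi((area_mean - mpa_mean) / sqrt(area_sd^2 + mpa_sd^2 + epsilon^2))`.
#' Always <= 0; tends to 0 for a molecule much smaller than the pore and
#' to -Inf for one much larger. Because drug-like molecules are on
#' average larger than the constriction, flexibility helps: for a
#' molecule bigger than the pore, increasing `mpa_sd` makes the term
#' less negative.
#'
#' @param mpa_mean Mean minimal projection area (Angstrom^2), > 0.
#'   Vectorised.
#' @param mpa_sd MPA fluctuation (Angstrom^2), >= 0. Vectorised.
#' @param pore A [pore_model()].
#' @param epsilon Regularising width (Angstrom^2) keeping the pooled
#'   spread positive when both fluctuations are zero.
#' @return Numeric vector of non-positive steric terms.
#' @export
steric_term <- function(mpa_mean, mpa_sd, pore, epsilon = 0.1) {
  stopifnot(inherits(pore, "pore_model"))
  if (any(!is.finite(mpa_mean)) || any(mpa_mean <= 0)) {
    abort("mpa_mean must be finite and > 0")
  }
  if (any(mpa_sd < 0)) abort("mpa_sd must be >= 0")
  z <- (pore$area_mean - mpa_mean) /
    sqrt(pore$area_sd^2 + mpa_sd^2 + epsilon^2)
  pnorm(z, log.p = TRUE)
}

#' Interaction-based porin permeability score
#'
#' Scores each compound with the linear interaction model
#' `score = alpha * U_steric + beta * Q * V_pore + gamma * D * E_pore + delta`,
#' where `U_steric` is the size-exclusion term, `Q` the net charge, `D`
#' the transversal dipole and `V_pore`/`E_pore` the pore's potential and
#' transversal field. The score is interpreted as a log-scale
#' permeability coefficient, so the percent-of-glycine scale
#' exponentiates score differences. The three weighted contributions are
#' returned alongside the score so it decomposes exactly as
#' `score = steric_term + charge_term + dipole_term + delta`.
#'
#' @param descriptors Data frame with columns `net_charge`,
#'   `transversal_dipole`, `mpa_mean`, `mpa_sd` (and typically `id`).
#' @param pore A [pore_model()].
#' @param coefficients A [scoring_coefficients()].
#' @param epsilon Passed to [steric_term()].
#' @return The input as a tibble with columns `u_steric` (raw steric
#'   term), `steric_term`, `charge_term`, `dipole_term` (weighted
#'   contributions) and `score` appended; when the pore is calibrated,
#'   also `percent` ([percent_of_glycine()]) and `category`
#'   ([categorize_permeability()]).
#' @export
permeability_score <- function(descriptors, pore, coefficients,
                               epsilon = 0.1) {
  stopifnot(inherits(pore, "pore_model"),
            inherits(coefficients, "scoring_coefficients"))
  need <- c("net_charge", "transversal_dipole", "mpa_mean", "mpa_sd")
  missing <- setdiff(need, names(descriptors))
  if (length(missing) > 0L) {
    abort(paste0("descriptors lack column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(descriptors)
  u <- steric_term(out$mpa_mean, out$mpa_sd, pore, epsilon = epsilon)
  out <- dplyr::mutate(
    out,
    u_steric = u,
    steric_term = coefficients$alpha * u,
    charge_term = coefficients$beta * .data$net_charge * pore$v_pore,
    dipole_term = coefficients$gamma * .data$transversal_dipole * pore$e_pore,
    score = .data$steric_term + .data$charge_term + .data$dipole_term +
      coefficients$delta
  )
  if (!is.na(pore$glycine_score)) {
    out <- dplyr::mutate(
      out,
      percent = percent_of_glycine(.data$score, pore),
      category = categorize_permeability(.data$percent)
    )
  }
  out
}

#' Permeability as a percentage of glycine
#'
#' Converts a log-scale permeability score into a percentage of the
#' glycine reference: `100 * exp(score - glycine_score)`. Glycine maps
#' to 100% and every output is strictly positive.
#'
#' @param score Numeric vector of permeability scores.
#' @param pore A calibrated [pore_model()] (see [calibrate_glycine()]).
#' @return Numeric vector of percentages.
#' @export
percent_of_glycine <- function(score, pore) {
  stopifnot(inherits(pore, "pore_model"))
  if (is.na(pore$glycine_score)) {
    abort(paste("pore model has no glycine reference score;",
                "run calibrate_glycine() with the active coefficients first"))
  }
  100 * exp(score - pore$glycine_score)
}

#' Permeability categories
#'
#' Bins glycine-relative permeability into `very_bad` (< 30%), `poor`
#' (30% to < 50%), `good` (50% to 70%, both ends included) and
#' `excellent` (> 70%).
#'
#' @param percent Strictly positive numeric vector (percent of glycine).
#' @return Factor with levels `very_bad`, `poor`, `good`, `excellent`.
#' @export
categorize_permeability <- function(percent) {
  if (any(!is.finite(percent)) || any(percent <= 0)) {
    abort("percent must be finite and > 0")
  }
  lab <- ifelse(percent < 30, "very_bad",
         ifelse(percent < 50, "poor",
         ifelse(percent <= 70, "good", "excellent")))
  factor(lab, levels = c("very_bad", "poor", "good", "excellent"))
}

#' Calibrate the glycine reference score
#'
#' Scores a glycine descriptor set under the active pore and
#' coefficients and stores the result as the pore's `glycine_score`, so
#' that the 100% anchor always matches the active configuration. By
#' default the bundled synthetic glycine conformer fixture is used (see
#' [glycine_descriptors()]).
#'
#' @param pore A [pore_model()].
#' @param coefficients A [scoring_coefficients()].
#' @param glycine One-row descriptor data frame for glycine; defaults to
#'   the bundled fixture.
#' @param epsilon Passed to [steric_term()].
#' @return The pore model with `glycine_score` set.
#' @export
calibrate_glycine <- function(pore, coefficients,
                              glycine = glycine_descriptors(),
                              epsilon = 0.1) {
  scored <- permeability_score(glycine, pore, coefficients, epsilon = epsilon)
  if (nrow(scored) != 1L) abort("glycine descriptors must be a single row")
  pore$glycine_score <- scored$score[[1L]]
  pore
}

#' Fit scoring coefficients from reference data
#'
#' Ordinary least squares of reference log-permeability values on the
#' three score regressors (raw steric term, `net_charge * v_pore`,
#' `transversal_dipole * e_pore`) plus an intercept. On noise-free data
#' generated by [permeability_score()] this recovers the planted
#' coefficients exactly (linear-system identity).
#'
#' @param training Data frame with the descriptor columns plus a
#'   `reference_score` column of log-scale permeability values.
#' @param pore A [pore_model()].
#' @param epsilon Passed to [steric_term()].
#' @return An object of class `porin_coef_fit` with elements
#'   `coefficients` (a [scoring_coefficients()]), `fit` (the underlying
#'   `lm`), and `n`. Supports [tidy()] and [glance()].
#' @export
fit_coefficients <- function(training, pore, epsilon = 0.1) {
  stopifnot(inherits(pore, "pore_model"))
  need <- c("net_charge", "transversal_dipole", "mpa_mean", "mpa_sd",
            "reference_score")
  missing <- setdiff(need, names(training))
  if (length(missing) > 0L) {
    abort(paste0("training data lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(training) < 4L) {
    abort(sprintf("need at least 4 training rows, got %d", nrow(training)))
  }
  df <- tibble::tibble(
    reference_score = training$reference_score,
    u_steric = steric_term(training$mpa_mean, training$mpa_sd, pore,
                           epsilon = epsilon),
    charge_x = training$net_charge * pore$v_pore,
    dipole_x = training$transversal_dipole * pore$e_pore
  )
  fit <- lm(reference_score ~ u_steric + charge_x + dipole_x, data = df)
  if (fit$rank < 4L) {
    bad <- names(which(is.na(coef(fit))))
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  cf <- coef(fit)
  structure(
    list(
      coefficients = scoring_coefficients(
        alpha = unname(cf["u_steric"]),
        beta = unname(cf["charge_x"]),
        gamma = unname(cf["dipole_x"]),
        delta = unname(cf["(Intercept)"])
      ),
      fit = fit,
      n = nrow(training)
    ),
    class = "porin_coef_fit"
  )
}

#' @export
print.porin_coef_fit <- function(x, ...) {
  cat(sprintf("<porin_coef_fit> n = %d\n", x$n))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_coefficients
#' @param x A `porin_coef_fit`.
#' @param ... Unused.
#' @export
tidy.porin_coef_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  map <- c("(Intercept)" = "delta", u_steric = "alpha",
           charge_x = "beta", dipole_x = "gamma")
  tibble::tibble(
    term = unname(map[rownames(s)]),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_coefficients
#' @export
glance.porin_coef_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    n = x$n,
    df.residual = x$fit$df.residual
  )
}
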