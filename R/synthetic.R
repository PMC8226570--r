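#' Configuration for the synthetic compound-table generator
#'
#' Defines the study conditions emulated by [generate_table()]: a
#' compound set the size of a typical whole-cell accumulation screen
#' (189 compounds by default), net charges between -2 and +2 dominated
#' by neutral and +1 species, minimal projection areas spanning the
#' 40-75 Angstrom^2 range of drug-like molecules, lognormal dipole
#' magnitudes that grow with net charge, and a log-linear
#' permeability-to-accumulation link with Gaussian noise on the log
#' scale. Planted counts force a fixed number of compounds below the
#' accumulation detection cutoff and above the hydrophobicity cutoff
#' (34 failing only the accumulation filter, 17 failing only the alogP
#' filter, and 1 failing both by default, so the default table reduces
#' to 137 analysed compounds).
#'
#' When `target_r` is set, the noise standard deviation is solved per
#' table from the analytic relation
#' `r^2 = var(signal) / (var(signal) + noise_sd^2)` over the compounds
#' that survive both filters, overriding `noise_sd`.
#'
#' @param n_compounds Number of compounds (>= 1).
#' @param seed Integer seed; every draw is reproducible from it.
#' @param charge_probs Named probabilities over net charges -2..+2
#'   (must sum to 1).
#' @param mpa_mean_range,mpa_sd_range Uniform ranges (Angstrom^2).
#' @param dipole_params List with `meanlog`, `sdlog` (lognormal, Debye)
#'   and `charge_shift` (added to `meanlog` per unit |net charge|).
#' @param transversal_beta Length-2 shape parameters of the Beta
#'   fraction linking transversal to total dipole.
#' @param alogp_params List with `mean` and `sd` of the alogP normal.
#' @param pore A [pore_model()] used to compute the true scores.
#' @param true_coefficients A [scoring_coefficients()] generating the
#'   true log-permeability.
#' @param accumulation_link List with `intercept` and `slope` of
#'   `ln(accumulation) = intercept + slope * score + noise`.
#' @param noise_sd Noise standard deviation on `ln(accumulation)`
#'   (>= 0); ignored when `target_r` is given.
#' @param target_r Optional planted Pearson correlation between
#'   `ln(accumulation)` and `ln(percent)` among analysed compounds.
#' @param n_low_accumulation,n_nonpolar,n_overlap Planted counts of
#'   compounds failing only the accumulation filter, only the alogP
#'   filter, or both.
#' @param accumulation_cutoff,alogp_cutoff Filter thresholds the
#'   planting is aimed at.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 189,
                             seed = 1,
                             charge_probs = c(`-2` = 0.04, `-1` = 0.16,
                                              `0` = 0.28, `1` = 0.40,
                                              `2` = 0.12),
                             mpa_mean_range = c(40, 75),
                             mpa_sd_range = c(0.5, 6),
                             dipole_params = list(meanlog = log(8),
                                                  sdlog = 0.45,
                                                  charge_shift = 0.55),
                             transversal_beta = c(5, 2),
                             alogp_params = list(mean = 1.0, sd = 1.1),
                             pore = example_pore_model(),
                             true_coefficients = example_coefficients(),
                             accumulation_link = list(intercept = 4.68,
                                                      slope = 0.45),
                             noise_sd = 0.8,
                             target_r = NULL,
                             n_low_accumulation = 34,
                             n_nonpolar = 17,
                             n_overlap = 1,
                             accumulation_cutoff = 45,
                             alogp_cutoff = 2.9) {
  if (n_compounds < 1) abort("n_compounds must be >= 1")
  if (abs(sum(charge_probs) - 1) > 1e-8) {
    abort("charge_probs must sum to 1")
  }
  if (length(charge_probs) != 5L) {
    abort("charge_probs must cover the five net charges -2..+2")
  }
  if (any(charge_probs < 0)) abort("charge_probs must be non-negative")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (!is.null(target_r) && (target_r <= 0 || target_r > 1)) {
    abort("target_r must lie in (0, 1]")
  }
  stopifnot(inherits(pore, "pore_model"),
            inherits(true_coefficients, "scoring_coefficients"))
  n_planted <- n_low_accumulation + n_nonpolar + n_overlap
  if (n_planted > 0 && n_compounds - n_planted < 3) {
    abort("planted counts leave fewer than 3 analysable compounds")
  }
  if (diff(mpa_mean_range) < 0 || mpa_mean_range[1L] <= 0) {
    abort("mpa_mean_range must be positive and increasing")
  }
  if (any(transversal_beta <= 0)) abort("transversal_beta shapes must be > 0")
  structure(
    list(
      n_compounds = as.integer(n_compounds), seed = as.integer(seed),
      charge_probs = charge_probs, mpa_mean_range = mpa_mean_range,
      mpa_sd_range = mpa_sd_range, dipole_params = dipole_params,
      transversal_beta = transversal_beta, alogp_params = alogp_params,
      pore = pore, true_coefficients = true_coefficients,
      accumulation_link = accumulation_link, noise_sd = noise_sd,
      target_r = target_r,
      n_low_accumulation = as.integer(n_low_accumulation),
      n_nonpolar = as.integer(n_nonpolar),
      n_overlap = as.integer(n_overlap),
      accumulation_cutoff = accumulation_cutoff,
      alogp_cutoff = alogp_cutoff
    ),
    class = "generator_config"
  )
}

#' Generate a synthetic compound/accumulation table
#'
#' Draws descriptors per [generator_config()], computes each compound's
#' true log-permeability score with the configured pore and
#' coefficients, links accumulation to the score on the log scale with
#' Gaussian noise, and plants the configured numbers of
#' detection-limit and non-polar compounds. Planted low-accumulation
#' compounds are the lowest-accumulating draws, squashed below the
#' cutoff; any other row that falls below the cutoff by chance is
#' raised to it (and hence kept by the strict filter), so the analysed
#' count is exact. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A tibble with the canonical descriptor columns plus
#'   `accumulation`, the generator-side `true_score` and `true_percent`
#'   (under the configured pore/coefficients), `noise_sd_used`, and the
#'   planting flags `planted_low` and `planted_nonpolar`.
#' @export
generate_table <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- cfg$n_compounds
  q <- sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE,
              prob = cfg$charge_probs)
  mpa_mean <- runif(n, cfg$mpa_mean_range[1L], cfg$mpa_mean_range[2L])
  mpa_sd <- runif(n, cfg$mpa_sd_range[1L], cfg$mpa_sd_range[2L])
  dp <- cfg$dipole_params
  total_dipole <- rlnorm(n, dp$meanlog + dp$charge_shift * abs(q), dp$sdlog)
  frac <- rbeta(n, cfg$transversal_beta[1L], cfg$transversal_beta[2L])
  transversal_dipole <- total_dipole * frac
  # alogP of analysable compounds stays at or below the cutoff
  alogp <- rnorm(n, cfg$alogp_params$mean, cfg$alogp_params$sd)
  for (i in 1:100) {
    high <- alogp > cfg$alogp_cutoff
    if (!any(high)) break
    alogp[high] <- rnorm(sum(high), cfg$alogp_params$mean,
                         cfg$alogp_params$sd)
  }
  alogp <- pmin(alogp, cfg$alogp_cutoff)

  u <- steric_term(mpa_mean, mpa_sd, cfg$pore)
  cf <- cfg$true_coefficients
  score <- cf$alpha * u + cf$beta * q * cfg$pore$v_pore +
    cf$gamma * transversal_dipole * cfg$pore$e_pore + cf$delta
  pore_cal <- calibrate_glycine(cfg$pore, cf)
  percent <- percent_of_glycine(score, pore_cal)

  n_low_total <- cfg$n_low_accumulation + cfg$n_overlap
  planted_low <- rep(FALSE, n)
  planted_nonpolar <- rep(FALSE, n)

  signal <- cfg$accumulation_link$slope * score
  intercept <- cfg$accumulation_link$intercept
  n_np_total <- cfg$n_nonpolar + cfg$n_overlap
  noise <- rnorm(n)
  perm <- sample(n) # fixed priority order for the non-polar planting
  analysed_rows <- function(ln_acc) {
    # rows surviving both filters once planting is applied: drop the
    # n_low_total lowest accumulators and the first n_nonpolar rows of
    # the priority order among the rest
    low_idx <- if (n_low_total > 0) order(ln_acc)[seq_len(n_low_total)]
               else integer(0)
    rest <- perm[!perm %in% low_idx]
    np_only <- if (cfg$n_nonpolar > 0) rest[seq_len(cfg$n_nonpolar)]
               else integer(0)
    list(low = low_idx, np_only = np_only,
         keep = setdiff(seq_len(n), c(low_idx, np_only)))
  }
  noise_sd <- cfg$noise_sd
  if (!is.null(cfg$target_r)) {
    # sigma from r^2 = var(signal) / (var(signal) + sigma^2); dropping
    # the lowest accumulators restricts the range and attenuates the
    # realised correlation, so with planting active the analytic value
    # seeds a one-dimensional solve of the analysed-subset correlation
    v <- mean((signal - mean(signal))^2)
    noise_sd <- sqrt(v * (1 / cfg$target_r^2 - 1))
    if (n_low_total + n_np_total > 0 && noise_sd > 0) {
      r_at <- function(s) {
        la <- intercept + signal + s * noise
        keep <- analysed_rows(la)$keep
        cor(la[keep], signal[keep])
      }
      f <- function(s) r_at(s) - cfg$target_r
      hi <- noise_sd * 5
      if (f(1e-8) > 0 && f(hi) < 0) {
        noise_sd <- uniroot(f, c(1e-8, hi), tol = 1e-4)$root
      }
    }
  }
  ln_acc <- intercept + signal + noise_sd * noise
  parts <- analysed_rows(ln_acc)
  planted_low[parts$low] <- TRUE
  accumulation <- exp(ln_acc)
  if (n_low_total > 0) {
    # squash the planted rows below the cutoff, preserving their rank
    squashed <- sort(runif(n_low_total, 2, cfg$accumulation_cutoff - 0.5))
    accumulation[parts$low[order(accumulation[parts$low])]] <- squashed
    # chance stragglers are raised to the (kept) boundary
    low_rest <- !planted_low & accumulation < cfg$accumulation_cutoff
    accumulation[low_rest] <- cfg$accumulation_cutoff
  }
  if (n_np_total > 0) {
    overlap_idx <- if (cfg$n_overlap > 0) {
      head(perm[perm %in% parts$low], cfg$n_overlap)
    } else integer(0)
    np_idx <- c(overlap_idx, parts$np_only)
    planted_nonpolar[np_idx] <- TRUE
    alogp[np_idx] <- runif(length(np_idx), cfg$alogp_cutoff + 0.1,
                           cfg$alogp_cutoff + 1.1)
  }

  tibble::tibble(
    id = sprintf("cmpd_%03d", seq_len(n)),
    net_charge = q,
    total_dipole = total_dipole,
    transversal_dipole = transversal_dipole,
    mpa_mean = mpa_mean,
    mpa_sd = mpa_sd,
    alogp = alogp,
    accumulation = accumulation,
    true_score = score,
    true_percent = percent,
    noise_sd_used = noise_sd,
    planted_low = planted_low,
    planted_nonpolar = planted_nonpolar
  )
}

#' Toy molecular geometries with known descriptors
#'
#' Builds small [conformer_ensemble()] fixtures whose descriptors have
#' closed forms: a `diatomic` (dipole `q * d`), a `rod` of collinear
#' overlapping spheres (minimal projection area `pi * r^2`, seen down
#' the rod axis), a planar `ring` (degenerate inertia axes, exercising
#' the deterministic tie-break) and a seed-reproducible `random_cloud`.
#'
#' @param kind One of `"diatomic"`, `"rod"`, `"ring"`, `"random_cloud"`.
#' @param params Named list of overrides. `diatomic`: `charge`,
#'   `separation`, `radius`, `mass`, or explicit `charges`. `rod`:
#'   `n_atoms`, `radius`, `spacing`. `ring`: `n_atoms`, `ring_radius`,
#'   `radius`. `random_cloud`: `n_atoms`, `spread`, `n_conformers`,
#'   `jitter`.
#' @param seed Integer seed (used by `random_cloud`).
#' @return A [conformer_ensemble()].
#' @export
make_toy_molecule <- function(kind = c("diatomic", "rod", "ring",
                                       "random_cloud"),
                              params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- function(name, default) params[[name]] %||% default
  if (kind == "diatomic") {
    d <- p("separation", 2)
    qq <- p("charges", c(p("charge", 0.5), -p("charge", 0.5)))
    pos <- rbind(c(0, 0, -d / 2), c(0, 0, d / 2))
    conformer_ensemble("diatomic", pos, charges = qq,
                       radii = rep(p("radius", 1.5), 2L),
                       masses = rep(p("mass", 12), 2L),
                       source = "toy:diatomic")
  } else if (kind == "rod") {
    n <- p("n_atoms", 5L)
    s <- p("spacing", 1)
    z <- (seq_len(n) - (n + 1) / 2) * s
    pos <- cbind(0, 0, z)
    conformer_ensemble("rod", pos, charges = rep(0, n),
                       radii = rep(p("radius", 1.5), n),
                       masses = rep(12, n), source = "toy:rod")
  } else if (kind == "ring") {
    n <- p("n_atoms", 6L)
    rr <- p("ring_radius", 1.4)
    th <- 2 * pi * (seq_len(n) - 1) / n
    pos <- cbind(rr * cos(th), rr * sin(th), 0)
    conformer_ensemble("ring", pos, charges = rep(0, n),
                       radii = rep(p("radius", 1.5), n),
                       masses = rep(12, n), source = "toy:ring")
  } else {
    n <- p("n_atoms", 12L)
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    base <- matrix(rnorm(n * 3L, sd = p("spread", 2)), ncol = 3L)
    charges <- rnorm(n, 0, 0.15)
    charges <- charges - (sum(charges) - round(sum(charges))) / n
    radii <- sample(c(1.2, 1.52, 1.55, 1.7, 1.8), n, replace = TRUE)
    masses <- sample(c(12.011, 14.007, 15.999, 32.06), n, replace = TRUE)
    k <- p("n_conformers", 1L)
    confs <- lapply(seq_len(k), function(i) {
      if (i == 1L) base
      else base + matrix(rnorm(n * 3L, sd = p("jitter", 0.3)), ncol = 3L)
    })
    conformer_ensemble(sprintf("cloud_seed%d", seed), confs,
                       charges = charges, radii = radii, masses = masses,
                       source = sprintf("toy:random_cloud(seed=%d)", seed))
  }
}
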