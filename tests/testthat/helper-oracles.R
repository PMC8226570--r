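# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the Monte-Carlo estimator checks the
# raster projection area, the dense-direction sweep checks the lattice
# minimisation, the explicit 3x3 tensor checks the inertia axis, and
# the textbook Pearson formula checks the regression.

# hit-or-miss Monte-Carlo estimate of the projected union-of-disks area
mc_projection_area <- function(positions, radii, direction,
                               n_samples = 1e6, seed = 1) {
  set.seed(seed)
  d <- direction / sqrt(sum(direction^2))
  # in-plane basis by Gram-Schmidt on the standard basis
  cand <- diag(3)[, order(abs(d))[1:2]]
  u <- cand[, 1] - sum(cand[, 1] * d) * d
  u <- u / sqrt(sum(u^2))
  v <- cand[, 2] - sum(cand[, 2] * d) * d - sum(cand[, 2] * u) * u
  v <- v / sqrt(sum(v^2))
  px <- positions %*% u
  py <- positions %*% v
  xr <- range(px - radii, px + radii)
  yr <- range(py - radii, py + radii)
  sx <- runif(n_samples, xr[1], xr[2])
  sy <- runif(n_samples, yr[1], yr[2])
  inside <- rep(FALSE, n_samples)
  for (i in seq_along(px)) {
    inside <- inside | ((sx - px[i])^2 + (sy - py[i])^2 <= radii[i]^2)
  }
  mean(inside) * diff(xr) * diff(yr)
}

# exhaustive minimum over a dense, regular (theta, phi) hemisphere grid
brute_force_mpa <- function(positions, radii, n_directions = 10000,
                            resolution = 0.1) {
  k <- floor(sqrt(n_directions))
  z <- seq(0, 1, length.out = k)
  phi <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  g <- expand.grid(z = z, phi = phi)
  s <- sqrt(pmax(0, 1 - g$z^2))
  dirs <- cbind(s * cos(g$phi), s * sin(g$phi), g$z)
  min(porinperm:::cpp_projection_areas(positions, radii, dirs, resolution))
}

# explicit component-wise inertia tensor, independent eigensolve
oracle_inertia_axis <- function(positions, masses) {
  com <- colSums(positions * masses) / sum(masses)
  x <- positions[, 1] - com[1]
  y <- positions[, 2] - com[2]
  z <- positions[, 3] - com[3]
  I <- matrix(c(
    sum(masses * (y^2 + z^2)), -sum(masses * x * y), -sum(masses * x * z),
    -sum(masses * x * y), sum(masses * (x^2 + z^2)), -sum(masses * y * z),
    -sum(masses * x * z), -sum(masses * y * z), sum(masses * (x^2 + y^2))
  ), 3, 3)
  ev <- eigen(I, symmetric = TRUE)
  ev$vectors[, which.min(ev$values)]
}

# textbook Pearson correlation from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# small random descriptor table satisfying the canonical schema
random_compound_table <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    net_charge = sample(-2:2, n, replace = TRUE),
    total_dipole = rlnorm(n, log(10), 0.5),
    transversal_dipole = NA_real_,
    mpa_mean = runif(n, 35, 80),
    mpa_sd = runif(n, 0, 6),
    alogp = rnorm(n, 1.5, 1.5),
    accumulation = exp(rnorm(n, 5, 1.5))
  ) |>
    dplyr::mutate(transversal_dipole = total_dipole * runif(n, 0.3, 1))
}
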