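test_that("net charge rounds near-integer charge sums and rejects the rest", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  mk <- function(q) conformer_ensemble("x", pos, q, c(1.5, 1.5), c(12, 12))
  expect_identical(net_charge(mk(c(0.999, 0))), 1L)
  expect_identical(net_charge(mk(c(1, -1))), 0L) # zwitterion-like pair
  expect_identical(net_charge(mk(c(0, 0))), 0L)
  expect_identical(net_charge(mk(c(-1.005, -0.999))), -2L)
  expect_error(conformer_ensemble("x", pos, c(0.5, 0), c(1.5, 1.5), c(12, 12)),
               "away from an integer")
})

test_that("dipole vector matches the point-charge closed form", {
  pos <- rbind(c(0, 0, -1), c(0, 0, 1))
  mu <- dipole_vector(pos, c(-0.5, 0.5))
  expect_equal(sqrt(sum(mu^2)), 4.80320, tolerance = 1e-10)
  expect_equal(dipole_vector(pos, c(0, 0)), c(0, 0, 0))
  # net-charged diatomic: origin at the centre of mass
  pos2 <- rbind(c(-1, 0, 0), c(1, 0, 0))
  mu2 <- dipole_vector(pos2, c(1, 0), masses = c(12, 12))
  expect_equal(sqrt(sum(mu2^2)), 1 * 4.80320, tolerance = 1e-10)
  expect_error(dipole_vector(matrix(numeric(0), 0, 3), numeric(0)),
               "at least one atom")
})

test_that("main inertia axis is the long axis, with deterministic tie-breaks", {
  pos <- rbind(c(0, 0, -1.2), c(0, 0, 0), c(0, 0, 1.2))
  ax <- main_inertia_axis(pos, c(16, 12, 16))
  expect_equal(abs(ax), c(0, 0, 1), tolerance = 1e-12)
  expect_gte(ax[3], 0) # sign fixed

  ring <- make_toy_molecule("ring")
  axr <- main_inertia_axis(ring$conformers[[1]], ring$masses)
  expect_equal(axr[3], 0, tolerance = 1e-9) # in-plane for a flat ring
  expect_equal(axr, main_inertia_axis(ring$conformers[[1]], ring$masses))

  for (s in 1:10) {
    m <- make_toy_molecule("random_cloud", seed = s)
    pos <- m$conformers[[1]]
    got <- main_inertia_axis(pos, m$masses)
    want <- oracle_inertia_axis(pos, m$masses)
    expect_equal(abs(sum(got * want)), 1, tolerance = 1e-8)
  }
  expect_error(main_inertia_axis(rbind(c(1, 1, 1), c(1, 1, 1)), c(1, 1)),
               "degenerate")
})

test_that("transversal dipole decomposes by Pythagoras", {
  expect_equal(transversal_dipole(c(0, 0, 5), c(0, 0, 1)), 0)
  expect_equal(transversal_dipole(c(5, 0, 0), c(0, 0, 1)), 5)
  expect_equal(transversal_dipole(c(3, 4, 0), c(1, 0, 0)), 4)
  expect_error(transversal_dipole(c(1, 1, 1), c(1, 1, 0)), "unit vector")
  set.seed(7)
  for (i in 1:25) {
    mu <- rnorm(3, sd = 5)
    a <- rnorm(3)
    a <- a / sqrt(sum(a^2))
    perp <- transversal_dipole(mu, a)
    expect_equal(perp^2 + sum(mu * a)^2, sum(mu^2), tolerance = 1e-9)
    expect_lte(perp, sqrt(sum(mu^2)) + 1e-12)
  }
})

test_that("projection area matches disk closed forms and is idempotent", {
  one <- matrix(0, 1, 3)
  expect_equal(projection_area(one, 1.7, c(0, 0, 1)), pi * 1.7^2,
               tolerance = 0.01)
  two_same <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(projection_area(two_same, c(1.7, 1.7), c(0, 0, 1)),
               projection_area(one, 1.7, c(0, 0, 1)))
  apart <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(projection_area(apart, c(1.5, 1.5), c(0, 0, 1)),
               2 * pi * 1.5^2, tolerance = 0.02)
  # converges to the exact union area as the raster is refined
  expect_equal(projection_area(apart, c(1.5, 1.5), c(0, 0, 1),
                               resolution = 0.02),
               2 * pi * 1.5^2, tolerance = 0.005)
  expect_error(projection_area(one, 1.7, c(0, 0, 1), resolution = -1),
               "resolution")
})

test_that("projection area is invariant under rigid co-rotation", {
  set.seed(11)
  m <- make_toy_molecule("random_cloud", seed = 3)
  pos <- m$conformers[[1]]
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    d <- rnorm(3)
    d <- d / sqrt(sum(d^2))
    a0 <- projection_area(pos, m$radii, d)
    a1 <- projection_area(pos %*% t(q), m$radii, as.numeric(q %*% d))
    expect_equal(a1, a0, tolerance = 0.02)
  }
})

test_that("minimal projection area finds the small face", {
  sph <- minimal_projection_area(matrix(0, 1, 3), 1.7, n_directions = 32)
  expect_equal(sph$mpa, pi * 1.7^2, tolerance = 0.01)
  rod <- make_toy_molecule("rod")
  mr <- minimal_projection_area(rod$conformers[[1]], rod$radii)
  expect_equal(mr$mpa, pi * 1.5^2, tolerance = 0.02)
  expect_equal(abs(mr$direction[3]), 1, tolerance = 0.01) # looks down the rod
})

test_that("MPA never exceeds the area along any probed direction and grows with atoms", {
  set.seed(23)
  for (s in 1:5) {
    m <- make_toy_molecule("random_cloud", seed = s, params = list(n_atoms = 8))
    pos <- m$conformers[[1]]
    mpa <- minimal_projection_area(pos, m$radii, n_directions = 128)
    for (i in 1:10) {
      d <- rnorm(3)
      d <- d / sqrt(sum(d^2))
      expect_lte(mpa$mpa, projection_area(pos, m$radii, d) + 1e-9)
    }
    # union grows when an atom is added away from the others
    pos2 <- rbind(pos, pos[1, ] + c(4, 4, 4))
    mpa2 <- minimal_projection_area(pos2, c(m$radii, 1.5),
                                    n_directions = 128)
    expect_gte(mpa2$mpa, mpa$mpa - 0.05 * mpa$mpa)
  }
})

test_that("ensemble descriptors summarise conformers with a population sd", {
  m1 <- make_toy_molecule("random_cloud", seed = 5)
  d1 <- ensemble_descriptors(m1, alogp = 1.2, n_directions = 64)
  expect_identical(d1$mpa_sd, 0)
  expect_identical(d1$alogp, 1.2)
  expect_gte(d1$total_dipole, d1$transversal_dipole)
  expect_gte(d1$transversal_dipole, 0)

  # N identical conformers behave like one
  rep3 <- conformer_ensemble("rep3", rep(m1$conformers, 3), m1$charges,
                             m1$radii, m1$masses)
  d3 <- ensemble_descriptors(rep3, alogp = 1.2, n_directions = 64)
  expect_equal(d3$mpa_sd, 0)
  expect_equal(d3$mpa_mean, d1$mpa_mean)
  expect_equal(d3$total_dipole, d1$total_dipole)

  # mixed ensemble: mean/sd match direct arithmetic and the mean is bracketed
  mix <- make_toy_molecule("random_cloud", seed = 9,
                           params = list(n_conformers = 3, jitter = 0.6))
  per <- vapply(mix$conformers, function(p) {
    minimal_projection_area(p, mix$radii, n_directions = 64)$mpa
  }, numeric(1))
  dm <- ensemble_descriptors(mix, n_directions = 64)
  expect_equal(dm$mpa_mean, mean(per), tolerance = 1e-12)
  expect_equal(dm$mpa_sd, sqrt(mean((per - mean(per))^2)), tolerance = 1e-12)
  expect_gte(dm$mpa_mean, min(per))
  expect_lte(dm$mpa_mean, max(per))
})
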