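test_that("shell convolution conserves kernel mass", {
  geom <- list(origin = c(0, 0, 0), spacing = 0.5, shape = c(24, 24, 24))
  # constant field: eigenfunction of the kernel with eigenvalue M
  u <- makeGridFixture("uniform", geom, value = 1.7)
  out <- shellConvolve(u, distance = 0.9572, multiplicity = 2)
  expect_equal(range(gridValues(out)), rep(2 * 1.7, 2), tolerance = 1e-12)
  # zero field stays zero
  z <- makeGridFixture("uniform", geom, value = 0)
  expect_equal(max(abs(gridValues(shellConvolve(z, 1, 2)))), 0)
  # impulse spreads onto a spherical shell of the kernel radius
  imp <- makeGridFixture("impulse", geom, value = 3)
  L <- 2.0
  sh <- shellConvolve(imp, distance = L, multiplicity = 2)
  expect_equal(gridIntegral(sh), 2 * gridIntegral(imp), tolerance = 0.01)
  # mass concentrated at radius ~ L: the radial mass profile of |values|
  # peaks at the kernel radius (spectral ringing contributes only tails)
  impCenter <- geom$origin + geom$spacing * ((geom$shape + 1) %/% 2 - 1)
  ra <- radialAverage(grid3D(sh@origin, sh@spacing, abs(gridValues(sh))),
                      center = impCenter)
  shellMass <- ra$mean * ra$n
  expect_equal(ra$r[which.max(shellMass)], L, tolerance = 0.3)
  # kernel distance beyond the grid is refused
  expect_error(shellConvolve(imp, distance = 10), "too large")
})

test_that("excluded-volume mask follows the occupancy threshold", {
  g1 <- array(1, c(4, 4, 4))
  expect_false(any(excludedVolumeMask(g1)))
  g0 <- array(0, c(4, 4, 4))
  expect_true(all(excludedVolumeMask(g0)))
  expect_error(excludedVolumeMask(array(-1, c(2, 2, 2))), "non-negative")
  # LJ fixture: the mask is a ball around the solute center
  st <- ljState()
  m <- excludedVolumeMask(st@g[["O"]])
  d <- dim(m)
  ctr <- (d + 1) / 2
  expect_true(m[ctr[1], ctr[2], ctr[3]])
  idx <- which(m, arr.ind = TRUE)
  r <- sqrt(rowSums((sweep(idx, 2, ctr))^2)) * st@spacing
  expect_lt(max(r), 4)   # compact, connected core region
})

test_that("reconstruction limits: single-term and uniform-hydrogen cases", {
  geom <- list(origin = c(0, 0, 0), spacing = 0.5, shape = c(20, 20, 20))
  AO <- gridValues(makeGridFixture("radial_gaussian", geom, value = 2,
                                   width = 1.5))
  ones <- array(1, geom$shape)
  # A_H = 0: reconstruction returns the central-site map
  rec <- reconstructMolecular(AO, 0 * AO, ones, distance = 0.9572,
                              multiplicity = 2, spacing = 0.5)
  expect_equal(rec, AO, tolerance = 1e-12)
  # A_O = 0, uniform A_H = v: two hydrogens contribute 2v
  rec2 <- reconstructMolecular(0 * AO, 0.7 * ones, ones,
                               distance = 0.9572, multiplicity = 2,
                               spacing = 0.5)
  expect_equal(range(rec2), rep(1.4, 2), tolerance = 1e-12)
  # impulse in A_H becomes a shell at the bond distance
  imp <- gridValues(makeGridFixture("impulse", geom, value = 1))
  rec3 <- reconstructMolecular(0 * AO, imp, ones, distance = 0.9572,
                               multiplicity = 2, spacing = 0.5)
  expect_equal(sum(rec3), 2 * sum(imp), tolerance = 0.01)
  expect_error(reconstructMolecular(AO, array(0, c(2, 2, 2)), ones,
                                    distance = 1, multiplicity = 2,
                                    spacing = 0.5), "mismatch")
})

test_that("reconstruction is linear at fixed g_O", {
  geom <- list(origin = c(0, 0, 0), spacing = 0.5, shape = c(16, 16, 16))
  set.seed(9)
  A1 <- array(stats::rnorm(16^3), geom$shape)
  B1 <- array(stats::rnorm(16^3), geom$shape)
  A2 <- array(stats::rnorm(16^3), geom$shape)
  B2 <- array(stats::rnorm(16^3), geom$shape)
  gO <- array(stats::runif(16^3, 0.5, 2), geom$shape)
  rec <- function(a, b) reconstructMolecular(a, b, gO, distance = 1,
                                             multiplicity = 2,
                                             spacing = 0.5)
  lhs <- rec(2 * A1 + 3 * A2, 2 * B1 + 3 * B2)
  rhs <- 2 * rec(A1, B1) + 3 * rec(A2, B2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("bulk-limit integral additivity: total = int A_O + M int A_H", {
  geom <- list(origin = c(0, 0, 0), spacing = 0.5, shape = c(24, 24, 24))
  AO <- gridValues(makeGridFixture("radial_gaussian", geom, value = 1,
                                   width = 2))
  AH <- gridValues(makeGridFixture("radial_gaussian", geom, value = -0.4,
                                   width = 1.5))
  ones <- array(1, geom$shape)
  rec <- reconstructMolecular(AO, AH, ones, distance = 0.9572,
                              multiplicity = 2, spacing = 0.5)
  expect_equal(sum(rec), sum(AO) + 2 * sum(AH), tolerance = 1e-8)
})
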