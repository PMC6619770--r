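test_that("zero potential leaves the solvent at its bulk fixed point", {
  sol0 <- soluteStructure(data.frame(x = 0, y = 0, z = 0, charge = 0,
                                     sigma = 1, epsilon = 0))
  st <- solveRISM3D(sol0, bulkWater(), spacing = 0.5, buffer = 6,
                    closure = "pse3", tol = 1e-8, minBuffer = 4)
  expect_true(isConverged(st))
  expect_equal(max(abs(unlist(st@h))), 0)
  expect_equal(max(abs(unlist(st@c))), 0)
  expect_true(all(unlist(st@g) == 1))
})

test_that("LJ-sphere solve converges with physical structure", {
  st <- ljState()
  expect_true(isConverged(st))
  expect_lte(residual(st), st@tolerance)
  # non-negative pair distributions everywhere (closure guarantee)
  expect_true(all(unlist(st@g) >= 0))
  # excluded core, first shell above bulk, bulk asymptote at the edge
  gO <- grid3D(st@origin, st@spacing, st@g[["O"]])
  ra <- radialAverage(gO, center = c(0, 0, 0))
  expect_lt(ra$mean[ra$r == 0.75], 1e-6)
  expect_gt(max(ra$mean), 1.5)
  expect_equal(ra$mean[nrow(ra)], 1, tolerance = 0.05)
})

test_that("solver is exactly covariant under whole-voxel translations", {
  sol <- ljSolute()
  geom <- geometryAroundSolute(sol, 0.5, 8)
  u1 <- computePotential(sol, waterModel(), geom)
  st1 <- solveRISM3D(sol, bulkWater(), geom = geom, closure = "pse3",
                     tol = 1e-8, uGrids = u1)
  shift <- c(2, -1, 3)
  u2 <- lapply(u1, translateGrid, shift = shift)
  st2 <- solveRISM3D(sol, bulkWater(), geom = geom, closure = "pse3",
                     tol = 1e-8, uGrids = u2)
  for (s in c("O", "H")) {
    expect_lt(max(abs(st2@h[[s]] - translateGrid(st1@h[[s]], shift))), 1e-10)
  }
  # and the potential itself translates exactly with the solute on the
  # overlap region
  solShift <- makeToySolute("lj_sphere", sigma = 3.15, epsilon = 0.15,
                            center = c(1, -0.5, 1.5))
  uS <- computePotential(solShift, waterModel(), geom)
  d <- dim(u1[["O"]])
  expect_equal(uS[["O"]][3:d[1], 1:(d[2] - 1), 4:d[3]],
               u1[["O"]][1:(d[1] - 2), 2:d[2], 1:(d[3] - 3)])
})

test_that("anisotropy of a spherical solute vanishes under refinement", {
  # voxels at identical |r| (across lattice orbits) should agree; the
  # residual scatter is discretisation anisotropy and must shrink with the
  # voxel size
  scatterOf <- function(st, rmin = 2, rmax = 7) {
    g <- st@g[["O"]]
    h <- st@spacing
    cc <- voxelCenters(grid3D(st@origin, h, g))
    r2 <- outer(outer(cc$x^2, cc$y^2, "+"), cc$z^2, "+")
    key <- round(r2 / h^2 * 4)
    keep <- r2 > rmin^2 & r2 < rmax^2
    max(tapply(g[keep], key[keep], function(v) diff(range(v))))
  }
  s1 <- scatterOf(ljState())
  s2 <- scatterOf(ljStateFine())
  expect_lt(s2, 0.5 * s1)
  expect_lt(s2, 0.02)
})

test_that("grid too small for the solute is refused", {
  expect_error(solveRISM3D(ljSolute(), bulkWater(), spacing = 0.5,
                           buffer = 2, minBuffer = 4),
               "grid too small")
})

test_that("temperature-derivative grids vanish in bulk and obey Richardson", {
  # bulk: u = 0 solute has identically zero derivatives
  sol0 <- soluteStructure(data.frame(x = 0, y = 0, z = 0, charge = 0,
                                     sigma = 1, epsilon = 0))
  st0 <- solveRISM3D(sol0, bulkWater(), spacing = 0.5, buffer = 6,
                     closure = "pse3", tol = 1e-8, minBuffer = 4)
  st0 <- solveTemperatureDerivatives(st0, sol0, bulkWater(), mode = "fd")
  expect_equal(max(abs(unlist(st0@dT$h))), 0, tolerance = 1e-10)
  expect_equal(max(abs(unlist(st0@dT$c))), 0, tolerance = 1e-10)
  # step halving: FD error scales as deltaT^2, so successive differences
  # shrink by about 4
  st <- ljState()
  # large steps and tight solves keep the deltaT^2 signal well above the
  # iterative-solver noise floor
  fd <- lapply(c(4, 2, 1), function(dt) {
    solveTemperatureDerivatives(st, ljSolute(), bulkWater(), mode = "fd",
                                deltaT = dt, tol = 1e-11)@dT$h[["O"]]
  })
  d1 <- max(abs(fd[[1]] - fd[[2]]))
  d2 <- max(abs(fd[[2]] - fd[[3]]))
  expect_equal(d1 / d2, 4, tolerance = 0.35)
})
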