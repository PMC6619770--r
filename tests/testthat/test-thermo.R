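# single-voxel synthetic state for hand-evaluated checks
.pointState <- function(h, cc, tstar, n, temperature = 298) {
  arr <- function(x) array(x, c(1, 1, 1))
  new("RismState",
      siteNames = "O",
      h = list(O = arr(h)), c = list(O = arr(cc)),
      tstar = list(O = arr(tstar)),
      g = list(O = arr(h + 1)), u = list(O = arr(0)),
      closure = n, origin = c(0, 0, 0), spacing = 0.5,
      temperature = temperature, residual = 0, tolerance = 1,
      converged = TRUE, dT = list())
}

test_that("excess chemical potential density matches hand evaluation", {
  w <- buildCTIP3P()
  kTrho <- 0.0019872041 * 298 * w@siteDensities[["O"]]
  # negative t*: truncation term off
  st <- .pointState(h = 0.2, cc = 0.1, tstar = -0.3, n = 3)
  dmu <- excessChemicalPotentialDensity(st, w)
  expect_equal(dmu$O[1, 1, 1], kTrho * (0.2^2 / 2 - 0.1 - 0.2 * 0.1 / 2))
  expect_equal(dmu$O[1, 1, 1], kTrho * (0.02 - 0.1 - 0.01))
  # non-negative t*, n = 1: Heaviside term -t*^2/2 switches on
  st2 <- .pointState(h = 0.2, cc = 0.1, tstar = 0.5, n = 1)
  dmu2 <- excessChemicalPotentialDensity(st2, w)
  expect_equal(dmu2$O[1, 1, 1],
               kTrho * (0.02 - 0.1 - 0.01 - 0.5^2 / 2))
  # bulk is exactly zero
  st0 <- .pointState(0, 0, 0, 3)
  expect_equal(excessChemicalPotentialDensity(st0, w)$O[1, 1, 1],
               # t* = 0 sits on the Heaviside branch but contributes 0^4/4!
               0)
  # HNC drops the truncation term entirely
  stH <- .pointState(h = 0.2, cc = 0.1, tstar = 0.5, n = Inf)
  expect_equal(excessChemicalPotentialDensity(stH, w)$O[1, 1, 1],
               kTrho * (0.02 - 0.1 - 0.01))
})

test_that("solute-water energy density is rho g u pointwise", {
  st <- ljStateFD()
  w <- waterModel()
  en <- energyDensities(st, w)
  for (s in c("O", "H")) {
    expect_equal(en$dEsw[[s]],
                 w@siteDensities[[s]] * st@g[[s]] * st@u[[s]])
  }
  # printed-value check: rho = 0.0334, g = 2, u = -1 gives -0.0668
  expect_equal(0.0334 * 2 * -1, -0.0668)
})

test_that("free-energy decomposition identities hold pointwise", {
  maps <- ljThermo()
  for (s in c("O", "H")) {
    expect_lt(max(abs(maps@dmu[[s]] - maps@dE[[s]] - maps@minusTdS[[s]])),
              1e-10)
    expect_lt(max(abs(maps@dE[[s]] - maps@dEsw[[s]] - maps@dEww[[s]])),
              1e-12)
  }
  # and in the totals
  tt <- maps@totals
  expect_equal(tt$dmu, tt$dE + tt$minusTdS, tolerance = 1e-10)
  expect_equal(tt$dE, tt$dEsw + tt$dEww, tolerance = 1e-10)
})

test_that("entropy density agrees with the finite-difference oracle", {
  st <- ljStateFD()
  w <- waterModel()
  mTdS <- entropyDensity(st, w)
  # oracle: central difference of the closure free-energy density over
  # temperature-consistent re-solves
  dT <- 1
  geom <- solvmap:::.stateGeom(st)
  dmuAt <- function(sgn) {
    mT <- solvmap:::.withTemperature(w, 298 + sgn * dT)
    bT <- solveDRISM(mT, bulkWater()@grid, closure = "pse3", tol = 1e-10,
                     csInit = bulkWater()@csShort, ladder = FALSE)
    sT <- solveRISM3D(ljSolute(), bT, geom = geom, closure = "pse3",
                      tol = 1e-8, ladder = FALSE, csInit = st@c,
                      minBuffer = 0)
    excessChemicalPotentialDensity(sT, mT)
  }
  dp <- dmuAt(1); dm <- dmuAt(-1)
  for (s in c("O", "H")) {
    fd <- 298 * (dp[[s]] - dm[[s]]) / (2 * dT)
    expect_lt(max(abs(mTdS[[s]] - fd)) / max(abs(fd)), 1e-3)
  }
})

test_that("bulk state yields identically zero maps", {
  sol0 <- soluteStructure(data.frame(x = 0, y = 0, z = 0, charge = 0,
                                     sigma = 1, epsilon = 0))
  st0 <- solveRISM3D(sol0, bulkWater(), spacing = 0.5, buffer = 6,
                     closure = "pse3", tol = 1e-8, minBuffer = 4)
  st0 <- solveTemperatureDerivatives(st0, sol0, bulkWater(), mode = "fd")
  m0 <- thermoMaps(st0, bulkWater())
  for (s in c("O", "H")) {
    expect_equal(max(abs(m0@dmu[[s]])), 0, tolerance = 1e-12)
    expect_equal(max(abs(m0@minusTdS[[s]])), 0, tolerance = 1e-12)
    expect_equal(max(abs(m0@dE[[s]])), 0, tolerance = 1e-12)
    expect_equal(max(abs(m0@dEsw[[s]])), 0, tolerance = 1e-12)
  }
})

test_that("maps decay to the bulk asymptote at the grid edge", {
  maps <- ljThermo()
  for (f in c("dmu", "minusTdS", "dE")) {
    v <- slot(maps, f)[["O"]] + slot(maps, f)[["H"]]
    d <- dim(v)
    edge <- c(v[1, , ], v[d[1], , ], v[, 1, ], v[, d[2], ],
              v[, , 1], v[, , d[3]])
    expect_lt(max(abs(edge)), 1e-3 * max(abs(v)))
  }
})

test_that("partial molar volume follows the compressibility relation", {
  st <- ljStateFD()
  pm <- partialMolarVolume(st, bulkWater())
  kTchi <- 0.0019872041 * 298 * compressibility(bulkWater())
  # c = 0 limit: the ideal point solute has v = kB T chi_T
  st0 <- st
  for (s in st0@siteNames) st0@c[[s]][] <- 0
  for (s in st0@siteNames) st0@dT$c[[s]][] <- 0
  pm0 <- partialMolarVolume(st0, bulkWater())
  expect_equal(pm0$v, kTchi, tolerance = 1e-9)
  # local map + offset reconstructs the scalar exactly
  expect_equal(sum(pm$map) * st@spacing^3 + pm$offset, pm$v,
               tolerance = 1e-10)
  expect_gt(pm$v, 0)
  # midpoint quadrature is stable under grid refinement for a smooth field
  f <- function(h) {
    n <- round(8 / h)
    geom <- list(origin = c(-4 + h / 2, -4 + h / 2, -4 + h / 2),
                 spacing = h, shape = rep(n, 3))
    g <- makeGridFixture("radial_gaussian", geom, value = 2, width = 1,
                         center = c(0, 0, 0))
    gridIntegral(g)
  }
  expect_equal(f(0.5), f(0.25), tolerance = 0.005)
})

test_that("UCT with zero parameters is the identity", {
  maps <- ljThermo()
  m0 <- uctCorrect(maps, uctParams(0, 0, 0, 0), 298)
  dEsum <- maps@dE[["O"]] + maps@dE[["H"]]
  expect_equal(m0@uct$dE, dEsum)
  expect_equal(m0@uct$totals$dE, sum(dEsum) * maps@spacing^3)
})

test_that("UCT parameters reproduce a = a1 T + a0 from the config file", {
  p <- uctParamsCTIP3P()
  path <- withr::local_tempfile(fileext = ".cfg")
  writeUctConfig(p, path)
  p2 <- readUctConfig(path)
  expect_equal(uctCoefficients(p2, 298)[["a"]],
               0.0327564 * 298 - 0.000507492)
  expect_equal(p2@b1, -3.26166)
})

test_that("UCT preserves the free-energy decomposition", {
  mu <- uctCorrect(ljThermo(), uctParamsCTIP3P(), 298)
  expect_lt(max(abs(mu@uct$dmu - mu@uct$dE - mu@uct$minusTdS)), 1e-10)
  expect_equal(mu@uct$totals$dmu,
               mu@uct$totals$dE + mu@uct$totals$minusTdS, tolerance = 1e-10)
})
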