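# Shared fixtures, built once per test run and cached.  All fixtures are
# generated in code; solver fixtures use reduced grids/buffers for speed
# (production defaults are 16384 x 0.025 A radial and 0.5 A / 24 A in 3D).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

waterModel <- function() fixture("water", function() buildCTIP3P())

# bulk water on a 4096 x 0.05 A grid (204.8 A extent), PSE-3, residual 1e-10
bulkWater <- function() fixture("bulk", function() {
  solveDRISM(waterModel(), radialGrid(4096, 0.05), closure = "pse3",
             tol = 1e-10)
})

ljSolute <- function() makeToySolute("lj_sphere", sigma = 3.15,
                                     epsilon = 0.15)

# neutral LJ sphere, 0.5 A voxels, 10 A buffer, PSE-3
ljState <- function() fixture("ljState", function() {
  solveRISM3D(ljSolute(), bulkWater(), spacing = 0.5, buffer = 10,
              closure = "pse3", tol = 1e-7)
})

# same state with finite-difference temperature derivatives (deltaT = 1 K)
ljStateFD <- function() fixture("ljStateFD", function() {
  solveTemperatureDerivatives(ljState(), ljSolute(), bulkWater(),
                              mode = "fd", deltaT = 1)
})

ljThermo <- function() fixture("ljThermo", function() {
  thermoMaps(ljStateFD(), bulkWater())
})

# finer-grid LJ solve shared by the anisotropy and refinement checks
ljStateFine <- function() fixture("ljStateFine", function() {
  solveRISM3D(ljSolute(), bulkWater(), spacing = 0.25, buffer = 8,
              closure = "pse3", tol = 1e-7)
})

# one rigid water as a (charged, net-neutral) solute, 10 A buffer
watSolute <- function() makeToySolute("water_as_solute",
                                      model = waterModel())

watStateFD <- function() fixture("watStateFD", function() {
  st <- solveRISM3D(watSolute(), bulkWater(), spacing = 0.5, buffer = 10,
                    closure = "pse3", tol = 1e-6)
  solveTemperatureDerivatives(st, watSolute(), bulkWater(), mode = "fd",
                              deltaT = 1)
})

watThermo <- function() fixture("watThermo", function() {
  thermoMaps(watStateFD(), bulkWater())
})

# quadrature oracle for the concentrated-orientation sampler: KL divergence
# of p(theta) ~ exp(kappa cos theta) (1 - cos theta) against the Haar angle
# density (1 - cos theta)/pi
orientationKLOracle <- function(kappa, n = 20000) {
  th <- seq(1e-9, pi, length.out = n)
  dth <- th[2] - th[1]
  dens <- exp(kappa * (cos(th) - 1)) * (1 - cos(th))
  Z <- sum(dens) * dth
  p <- dens / Z
  sum(p * (kappa * (cos(th) - 1) - log(Z / pi))) * dth
}

# hand-evaluated three-site LJ + Coulomb interaction energy of two rigid
# waters (explicit loops; the oracle partner of the vectorised kernel)
waterPairEnergyOracle <- function(w1, w2, model) {
  s <- model@sites
  par <- list(q = c(s$charge[1], s$charge[2], s$charge[2]),
              sig = c(s$sigma[1], s$sigma[2], s$sigma[2]),
              eps = c(s$epsilon[1], s$epsilon[2], s$epsilon[2]))
  p1 <- rbind(w1$O, w1$H1, w1$H2)
  p2 <- rbind(w2$O, w2$H1, w2$H2)
  e <- 0
  for (i in 1:3) for (j in 1:3) {
    r <- sqrt(sum((p1[i, ] - p2[j, ])^2))
    sm <- (par$sig[i] + par$sig[j]) / 2
    em <- sqrt(par$eps[i] * par$eps[j])
    e <- e + 4 * em * ((sm / r)^12 - (sm / r)^6) +
      332.0637 * par$q[i] * par$q[j] / r
  }
  e
}
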