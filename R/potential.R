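# Solute-solvent interaction potentials on the 3D grid: direct sum over all
# atoms (no cutoff), Lorentz-Berthelot mixing, singularities capped.

.potentialCap <- 1e10  # kcal/mol; keeps exp(t*) underflow well-defined

# squared distance array from every voxel center to a point
.dist2Grid <- function(geom, p) {
  cc <- .geomCenters(geom)
  outer(outer((cc$x - p[1])^2, (cc$y - p[2])^2, "+"), (cc$z - p[3])^2, "+")
}

.geomCenters <- function(geom) {
  d <- geom$shape
  list(x = geom$origin[1] + geom$spacing * (seq_len(d[1]) - 1),
       y = geom$origin[2] + geom$spacing * (seq_len(d[2]) - 1),
       z = geom$origin[3] + geom$spacing * (seq_len(d[3]) - 1))
}

#' Solute-site interaction potential grids
#'
#' Computes u_a(r) for each solvent site type a: the sum over all solute
#' atoms of Lennard-Jones (Lorentz-Berthelot mixing) plus Coulomb terms,
#' evaluated at every voxel center by direct summation with no cutoff.
#' Voxels that coincide with an atom position are capped at 1e10 kcal/mol.
#'
#' @param solute a \linkS4class{SoluteStructure}.
#' @param model a \linkS4class{SolventModel}.
#' @param geom grid geometry: list with \code{origin}, \code{spacing},
#'   \code{shape} (see \code{alignGrid}).
#' @return named list of 3D arrays (kcal/mol), one per site type.
#' @export
computePotential <- function(solute, model, geom) {
  atoms <- solute@atoms
  s <- model@sites
  out <- vector("list", nrow(s))
  names(out) <- s$name
  for (a in seq_len(nrow(s))) {
    u <- array(0, geom$shape)
    for (i in seq_len(nrow(atoms))) {
      r2 <- .dist2Grid(geom, c(atoms$x[i], atoms$y[i], atoms$z[i]))
      r2 <- pmax(r2, 1e-12)
      sm <- 0.5 * (atoms$sigma[i] + s$sigma[a])
      em <- sqrt(atoms$epsilon[i] * s$epsilon[a])
      sr6 <- sm^6 / r2^3
      u <- u + 4 * em * (sr6^2 - sr6) +
        model@coulomb * atoms$charge[i] * s$charge[a] / sqrt(r2)
    }
    out[[a]] <- pmin(u, .potentialCap)
  }
  out
}

# erf-smeared electrostatic potential of the solute on the grid,
# phi(r) = C sum_i q_i erf(|r - r_i|/s)/|r - r_i|  (finite at r -> r_i).
.smearedPotential <- function(solute, model, geom, smear) {
  atoms <- solute@atoms
  phi <- array(0, geom$shape)
  if (all(abs(atoms$charge) < 1e-14)) return(phi)
  for (i in seq_len(nrow(atoms))) {
    if (abs(atoms$charge[i]) < 1e-14) next
    r <- sqrt(.dist2Grid(geom, c(atoms$x[i], atoms$y[i], atoms$z[i])))
    v <- ifelse(r < 1e-8, 2 / (sqrt(pi) * smear), .erf(r / smear) / r)
    phi <- phi + model@coulomb * atoms$charge[i] * v
  }
  phi
}
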