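#' @import methods
NULL

#' Rigid multi-site solvent model
#'
#' Describes a rigid multi-site solvent (the built-in model is a three-site
#' TIP3P-like water with a hydrogen Lennard-Jones core).  Sites are site
#' *types*: equivalent positions (the two water hydrogens) are represented by
#' one type with a multiplicity.  The resolved per-position coordinates of one
#' molecule, in a frame with the dipole along +z, are kept alongside so that
#' intramolecular distances and the dielectric bridge can be built exactly.
#'
#' @slot sites data.frame with columns \code{name}, \code{multiplicity},
#'   \code{charge} (e), \code{sigma} (Lennard-Jones diameter, Angstrom) and
#'   \code{epsilon} (well depth, kcal/mol), one row per site type.
#' @slot siteDensities named numeric, number density of each site type in
#'   Angstrom^-3 (multiplicity times the molecular density).
#' @slot molecularDensity molecular number density in Angstrom^-3.
#' @slot temperature temperature in K.
#' @slot targetDielectric dielectric constant imposed through the DRISM
#'   bridge.
#' @slot positions numeric matrix, one row per resolved site position
#'   (columns x, y, z, Angstrom) in the molecular frame; row names repeat the
#'   site type name for multiplicity > 1.
#' @slot positionType integer index mapping each resolved position to its row
#'   in \code{sites}.
#' @slot distanceMatrix symmetric matrix of intramolecular distances between
#'   resolved positions (Angstrom).
#' @slot kB Boltzmann constant in kcal/mol/K (beta = 1/(kB*T)).
#' @slot coulomb Coulomb constant in kcal*Angstrom/mol/e^2.
#' @export
setClass("SolventModel", representation(
  sites = "data.frame",
  siteDensities = "numeric",
  molecularDensity = "numeric",
  temperature = "numeric",
  targetDielectric = "numeric",
  positions = "matrix",
  positionType = "integer",
  distanceMatrix = "matrix",
  kB = "numeric",
  coulomb = "numeric"
))

setValidity("SolventModel", function(object) {
  msg <- character()
  s <- object@sites
  need <- c("name", "multiplicity", "charge", "sigma", "epsilon")
  if (!all(need %in% names(s))) {
    msg <- c(msg, "sites must have name, multiplicity, charge, sigma, epsilon")
  } else {
    if (any(s$multiplicity < 1)) msg <- c(msg, "multiplicity must be >= 1")
    if (any(s$sigma <= 0)) msg <- c(msg, "lj sigma must be > 0")
    if (any(s$epsilon < 0)) msg <- c(msg, "lj epsilon must be >= 0")
    if (abs(sum(s$multiplicity * s$charge)) > 1e-10)
      msg <- c(msg, "molecule must be charge neutral")
    if (!isTRUE(all.equal(unname(object@siteDensities),
                          s$multiplicity * object@molecularDensity,
                          tolerance = 1e-8)))
      msg <- c(msg, "siteDensities must equal multiplicity * molecularDensity")
  }
  d <- object@distanceMatrix
  if (!isTRUE(all.equal(d, t(d)))) msg <- c(msg, "distanceMatrix not symmetric")
  if (nrow(d) > 1 && any(d[upper.tri(d)] <= 0))
    msg <- c(msg, "distinct-position distances must be > 0")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
  if (length(msg)) msg else TRUE
})

#' Logarithmic-free radial grid for 1D RISM
#'
#' A uniform radial grid r_i = i*dr, i = 1..n, paired with the reciprocal
#' grid k_j = j*dk, dk = pi/((n+1)*dr), on which the discrete sine transform
#' (DST-I) is orthogonal.
#'
#' @slot n number of points.
#' @slot dr spacing in Angstrom.
#' @export
setClass("RadialGrid", representation(n = "integer", dr = "numeric"))

setValidity("RadialGrid", function(object) {
  if (object@n < 8) return("n too small")
  if (object@dr <= 0) return("dr must be > 0")
  TRUE
})

#' Converged bulk solvent (DRISM) solution
#'
#' Holds the site-site correlation functions of the bulk solvent and the
#' symmetric site-site structure factor S_ag(k) = rho_a w_ag + rho_a rho_g
#' h_ag(k), from which the 3D-RISM susceptibility chi_ag = S_ag / rho_a is
#' obtained.
#'
#' @slot model the SolventModel that was solved.
#' @slot grid the RadialGrid.
#' @slot S array [nk, nsite, nsite]: symmetric structure factor (with the
#'   DRISM bridge contribution included in h).
#' @slot h array [nk-by-r? no: nr, nsite, nsite] real-space total correlation
#'   functions h_ag(r).
#' @slot csShort array [nr, nsite, nsite] short-range part of the direct
#'   correlation function (the -beta*q*q*erf(r/s)/r asymptotics is carried
#'   analytically).
#' @slot closure closure used ("kh", "pse2", "pse3", ..., "hnc").
#' @slot residual final residual norm.
#' @slot tolerance requested tolerance.
#' @slot converged logical.
#' @slot coulombSmear erf smearing length (Angstrom) of the analytic
#'   long-range direct correlation.
#' @slot bridgeSmear Gaussian envelope parameter a (Angstrom^-1) of the
#'   dielectric bridge.
#' @slot residualHistory numeric, residual per iteration.
#' @export
setClass("BulkSolvent", representation(
  model = "SolventModel",
  grid = "RadialGrid",
  S = "array",
  h = "array",
  csShort = "array",
  closure = "character",
  residual = "numeric",
  tolerance = "numeric",
  converged = "logical",
  coulombSmear = "numeric",
  bridgeSmear = "numeric",
  residualHistory = "numeric"
))

#' Regular cubic-voxel 3D grid
#'
#' @slot origin coordinates of the first voxel center (Angstrom).
#' @slot spacing voxel edge length (Angstrom, cubic voxels).
#' @slot values 3D numeric array.
#' @export
setClass("Grid3D", representation(
  origin = "numeric",
  spacing = "numeric",
  values = "array"
))

setValidity("Grid3D", function(object) {
  if (length(object@origin) != 3) return("origin must have length 3")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(dim(object@values)) != 3) return("values must be a 3D array")
  TRUE
})

#' Rigid solute structure
#'
#' @slot atoms data.frame with columns x, y, z (Angstrom), charge (e),
#'   sigma (Angstrom), epsilon (kcal/mol) and optionally name.
#' @export
setClass("SoluteStructure", representation(atoms = "data.frame"))

setValidity("SoluteStructure", function(object) {
  a <- object@atoms
  need <- c("x", "y", "z", "charge", "sigma", "epsilon")
  if (!all(need %in% names(a))) return("atoms need x,y,z,charge,sigma,epsilon")
  if (nrow(a) == 0) return("no atoms")
  if (!all(is.finite(as.matrix(a[, need])))) return("non-finite atom fields")
  if (any(a$sigma <= 0)) return("sigma must be > 0")
  TRUE
})

#' Converged 3D-RISM state
#'
#' Per-site-type 3D correlation grids around a rigid solute, all on the same
#' cubic-voxel geometry.  The optional slot \code{dT} holds isochoric
#' temperature-derivative grids delta_T h and delta_T c.
#'
#' @slot siteNames character, site type names (e.g. "O", "H").
#' @slot h,c,tstar,g,u named lists of 3D arrays per site type: total and
#'   direct correlation functions, renormalised indirect function
#'   t* = -beta*u + h - c, pair distribution g, and the solute-site
#'   interaction potential (kcal/mol).
#' @slot closure closure order n (Inf for HNC).
#' @slot origin,spacing grid geometry (first voxel center, voxel edge).
#' @slot temperature temperature of the solve (K).
#' @slot residual final residual norm; @slot tolerance requested.
#' @slot converged logical.
#' @slot dT list, either empty or with elements h, c, tstar (named lists of
#'   arrays) and mode ("fd" or "linear").
#' @export
setClass("RismState", representation(
  siteNames = "character",
  h = "list", c = "list", tstar = "list", g = "list", u = "list",
  closure = "numeric",
  origin = "numeric", spacing = "numeric",
  temperature = "numeric",
  residual = "numeric", tolerance = "numeric", converged = "logical",
  dT = "list"
))

#' Thermodynamic density maps from a 3D-RISM state
#'
#' Per-site and summed voxel maps (kcal/mol/Angstrom^3) of the excess
#' chemical potential density, entropy density (-T dS), energy density and
#' its solute-water / water-water split, plus the partial molar volume and
#' its local map, and (optionally) UCT-corrected total maps.
#'
#' @slot siteNames character.
#' @slot dmu,minusTdS,dE,dEsw,dEww named lists of 3D arrays per site.
#' @slot totals data.frame of volume integrals (kcal/mol) per site and summed.
#' @slot pmv partial molar volume (Angstrom^3); @slot dTpmv its isochoric
#'   temperature derivative delta_T v.
#' @slot pmvMap,dTpmvMap local maps v(r), delta_T v(r) excluding the constant
#'   kB*T*chiT offset (carried in @slot pmvOffset).
#' @slot origin,spacing grid geometry.
#' @slot uct list, empty until \code{uctCorrect} is applied; then holds
#'   corrected dE / minusTdS / dmu maps and totals plus the parameters used.
#' @export
setClass("ThermoMaps", representation(
  siteNames = "character",
  dmu = "list", minusTdS = "list", dE = "list", dEsw = "list", dEww = "list",
  totals = "data.frame",
  pmv = "numeric", dTpmv = "numeric",
  pmvMap = "array", dTpmvMap = "array", pmvOffset = "numeric",
  origin = "numeric", spacing = "numeric",
  uct = "list"
))

#' Explicit rigid-water frame set
#'
#' @slot frames list; each element is a list with matrices \code{O},
#'   \code{H1}, \code{H2} (n_waters x 3, Angstrom) for one frame.
#' @slot region numeric(6): xmin,xmax,ymin,ymax,zmin,zmax of the sampling
#'   region.
#' @export
setClass("WaterFrameSet", representation(frames = "list", region = "numeric"))

setValidity("WaterFrameSet", function(object) {
  if (length(object@frames) < 1) return("need at least one frame")
  f <- object@frames[[1]]
  if (!all(c("O", "H1", "H2") %in% names(f))) return("frames need O,H1,H2")
  TRUE
})

#' GIST voxel maps
#'
#' @slot nObs integer array, water-oxygen counts per voxel over all frames.
#' @slot g occupancy relative to bulk.
#' @slot dStrans,dSorient entropy densities (kcal/mol/K/Angstrom^3 times -T
#'   is NOT applied; see accessors) stored as first-order IST densities in
#'   kcal/mol/Angstrom^3 after multiplying by -T.
#' @slot dEsw,dEww energy densities (kcal/mol/Angstrom^3).
#' @slot orientFlagged logical array: voxels with too few orientation samples.
#' @slot bulkDensity rho0 (Angstrom^-3); @slot nFrames frame count.
#' @slot origin,spacing grid geometry.
#' @export
setClass("GistResults", representation(
  nObs = "array", g = "array",
  dStrans = "array", dSorient = "array",
  dEsw = "array", dEww = "array",
  orientFlagged = "array",
  bulkDensity = "numeric", nFrames = "integer",
  origin = "numeric", spacing = "numeric"
))

#' Parameters of the temperature-dependent universal correction (UCT)
#'
#' a = a1*T + a0 and b = b1*T + b0 enter the corrected energy and entropy
#' densities linearly in the partial molar volume.
#'
#' @slot a0,a1,b0,b1 fitted scalars.
#' @export
setClass("UctParams",
         representation(a0 = "numeric", a1 = "numeric",
                        b0 = "numeric", b1 = "numeric"))
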