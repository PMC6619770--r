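# Grid inhomogeneous solvation theory (GIST) voxel maps from explicit
# rigid-water frame sets: occupancy, first-order translational and
# orientational entropy, and solute-water / water-water energies.  Every
# water is assigned to the voxel holding its oxygen; energies include all
# three sites of the assigned waters.

#' Assign waters to voxels by oxygen position
#'
#' Half-open voxel boxes [low, high) with the origin at the first voxel
#' center; waters outside the grid are left unassigned (index NA).
#'
#' @param frames a \linkS4class{WaterFrameSet}.
#' @param geom grid geometry (origin, spacing, shape).
#' @return list with \code{index}: a list (one integer vector per frame) of
#'   linear voxel indices, \code{counts}: integer array of per-voxel
#'   totals, and \code{geom}.
#' @export
assignWaters <- function(frames, geom) {
  d <- geom$shape
  counts <- array(0L, d)
  index <- vector("list", length(frames@frames))
  for (f in seq_along(frames@frames)) {
    o <- frames@frames[[f]]$O
    ijk <- floor(sweep(o, 2, geom$origin, "-") / geom$spacing + 0.5)
    ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
          ijk[, 2] >= 0 & ijk[, 2] < d[2] &
          ijk[, 3] >= 0 & ijk[, 3] < d[3]
    lin <- rep(NA_integer_, nrow(o))
    lin[ok] <- 1L + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])
    index[[f]] <- lin
    tab <- tabulate(lin[ok], nbins = prod(d))
    counts <- counts + array(tab, d)
  }
  list(index = index, counts = counts, geom = geom)
}

#' Voxel occupancy relative to bulk
#'
#' g_k = n_k / (n_frames * V_k * rho0).
#'
#' @param assignment output of \code{assignWaters}.
#' @param nFrames number of frames.
#' @param rho0 bulk number density (Angstrom^-3).
#' @return numeric array of g values.
#' @export
gistOccupancy <- function(assignment, nFrames, rho0) {
  Vk <- assignment$geom$spacing^3
  assignment$counts / (nFrames * Vk * rho0)
}

#' First-order translational entropy density
#'
#' Per voxel -kB rho0 g ln g (kcal/mol/K/Angstrom^3), with empty voxels
#' contributing zero (x ln x -> 0).  Multiply by the voxel volume for the
#' voxel integral and by -T for the -T dS map.
#'
#' @param g occupancy array from \code{gistOccupancy}.
#' @param rho0 bulk density (Angstrom^-3).
#' @return numeric array, same shape as g.
#' @export
translationalEntropy <- function(g, rho0) {
  out <- array(0, dim(g))
  nz <- g > 0
  out[nz] <- -.kBoltzmann * rho0 * g[nz] * log(g[nz])
  out
}

# fraction of SO(3) within geodesic rotation angle d of a point; series
# branch keeps tiny distances away from catastrophic cancellation
.so3BallMeasure <- function(d) {
  out <- (d - sin(d)) / pi
  small <- d < 1e-4
  out[small] <- (d[small]^3 / 6 - d[small]^5 / 120) / pi
  out
}

# Kozachenko-Leonenko k=1 estimate of the relative (KL) entropy of a
# sample of rotations against the uniform distribution:
# D = -H, H = mean(log((n-1) V(d_nn))) + gamma.
.nnOrientationKL <- function(quats) {
  n <- nrow(quats)
  G <- abs(quats %*% t(quats))   # |q_i . q_j| handles the double cover
  diag(G) <- -1
  nn <- apply(G, 1, max)
  d <- 2 * acos(pmin(nn, 1))
  d <- pmax(d, 1e-12)
  H <- mean(log((n - 1) * .so3BallMeasure(d))) + 0.57721566490153286
  -H
}

# Euler-angle histogram estimate of the same KL divergence.
.histOrientationKL <- function(quats, bins = 12) {
  w <- quats[, 1]; x <- quats[, 2]; y <- quats[, 3]; z <- quats[, 4]
  # z-y-z Euler angles of the rotation; uniform measure is
  # d(phi) d(cos theta) d(psi) / (8 pi^2)
  R31 <- 2 * (x * z - w * y); R32 <- 2 * (y * z + w * x)
  R13 <- 2 * (x * z + w * y); R23 <- 2 * (y * z - w * x)
  R33 <- 1 - 2 * (x^2 + y^2)
  ct <- pmin(pmax(R33, -1), 1)
  phi <- atan2(R23, R13)
  psi <- atan2(R32, -R31)
  bi <- function(v, lo, hi) pmin(floor((v - lo) / (hi - lo) * bins), bins - 1)
  idx <- 1 + bi(phi, -pi, pi) + bins * (bi(ct, -1, 1) +
                                          bins * bi(psi, -pi, pi))
  p <- tabulate(idx, nbins = bins^3) / length(w)
  nz <- p > 0
  sum(p[nz] * log(p[nz] * bins^3))
}

#' First-order orientational entropy density
#'
#' Estimates, per voxel, the relative entropy of the orientation
#' distribution of the assigned waters against uniform, by the
#' nearest-neighbour (k = 1, quaternion geodesic distance, double-cover
#' aware) or Euler-angle histogram estimator, and converts it to the
#' first-order IST orientational entropy density
#' dS_orient = -kB rho0 g D (kcal/mol/K/Angstrom^3).
#'
#' @param frames a \linkS4class{WaterFrameSet}.
#' @param assignment output of \code{assignWaters} on the same frames.
#' @param rho0 bulk density.
#' @param method "nn" or "histogram".
#' @param minSamples voxels with fewer orientation samples are flagged and
#'   left at zero.
#' @return list with \code{density} (array), \code{flagged} (logical
#'   array), \code{nFlagged}.
#' @export
orientationalEntropy <- function(frames, assignment, rho0,
                                 method = c("nn", "histogram"),
                                 minSamples = 20) {
  method <- match.arg(method)
  geom <- assignment$geom
  nFrames <- length(frames@frames)
  nvox <- prod(geom$shape)
  # gather quaternions per voxel
  qByVox <- vector("list", nvox)
  for (f in seq_along(frames@frames)) {
    fr <- frames@frames[[f]]
    lin <- assignment$index[[f]]
    for (i in which(!is.na(lin))) {
      q <- waterQuaternion(fr$O[i, ], fr$H1[i, ], fr$H2[i, ])
      v <- lin[i]
      qByVox[[v]][[length(qByVox[[v]]) + 1]] <- q
    }
  }
  dens <- array(0, geom$shape)
  flagged <- array(FALSE, geom$shape)
  Vk <- geom$spacing^3
  for (v in seq_len(nvox)) {
    qs <- qByVox[[v]]
    n <- length(qs)
    if (n == 0) next
    if (n < minSamples) { flagged[v] <- TRUE; next }
    Q <- do.call(rbind, qs)
    D <- if (method == "nn") .nnOrientationKL(Q) else .histOrientationKL(Q)
    gk <- n / (nFrames * Vk * rho0)
    dens[v] <- -.kBoltzmann * rho0 * gk * D
  }
  list(density = dens, flagged = flagged, nFlagged = sum(flagged))
}

# site parameter vectors for the water sites of a frame (O,H,H per water)
.waterSiteParams <- function(nWaters, model) {
  s <- model@sites
  list(q = rep(c(s$charge[1], s$charge[2], s$charge[2]), nWaters),
       sig = rep(c(s$sigma[1], s$sigma[2], s$sigma[2]), nWaters),
       eps = rep(c(s$epsilon[1], s$epsilon[2], s$epsilon[2]), nWaters),
       water = rep(seq_len(nWaters), each = 3))
}

.frameSites <- function(fr) {
  n <- nrow(fr$O)
  m <- matrix(0, 3 * n, 3)
  m[seq(1, 3 * n, 3), ] <- fr$O
  m[seq(2, 3 * n, 3), ] <- fr$H1
  m[seq(3, 3 * n, 3), ] <- fr$H2
  m
}

# full LJ+Coulomb energy between two site sets (matrices of positions and
# parameter vectors); returns the site-pair energy matrix
.sitePairEnergy <- function(p1, par1, p2, par2, coulomb, cap = 1e10) {
  r2 <- outer(rowSums(p1^2), rowSums(p2^2), "+") - 2 * p1 %*% t(p2)
  r2 <- pmax(r2, 1e-12)
  sm <- outer(par1$sig, par2$sig, "+") / 2
  em <- sqrt(outer(par1$eps, par2$eps))
  sr6 <- sm^6 / r2^3
  e <- 4 * em * (sr6^2 - sr6) + coulomb * outer(par1$q, par2$q) / sqrt(r2)
  pmin(e, cap)
}

#' GIST solute-water and water-water energy densities
#'
#' dE_sw per voxel: mean over frames of the full (three-site, LJ +
#' Coulomb, no cutoff) interaction of the voxel's waters with the solute,
#' divided by the voxel volume.  dE_ww: mean of the half-weighted pair
#' sums of the voxel's waters with all other waters, minus the per-water
#' bulk reference \code{Ebulk} per assigned water, divided by the voxel
#' volume.
#'
#' @param frames a \linkS4class{WaterFrameSet}.
#' @param assignment output of \code{assignWaters}.
#' @param model solvent model (water site parameters).
#' @param solute a SoluteStructure or NULL for no solute.
#' @param Ebulk reference per-water bulk water-water energy (kcal/mol);
#'   default 0 reports raw half-pair sums.
#' @return list with arrays \code{dEsw}, \code{dEww}
#'   (kcal/mol/Angstrom^3).
#' @export
gistEnergies <- function(frames, assignment, model, solute = NULL,
                         Ebulk = 0) {
  geom <- assignment$geom
  nFrames <- length(frames@frames)
  Vk <- geom$spacing^3
  nvox <- prod(geom$shape)
  accSW <- numeric(nvox)
  accWW <- numeric(nvox)
  solPar <- if (!is.null(solute)) {
    a <- solute@atoms
    list(q = a$charge, sig = a$sigma, eps = a$epsilon)
  } else NULL
  solPos <- if (!is.null(solute)) {
    as.matrix(solute@atoms[, c("x", "y", "z")])
  } else NULL
  for (f in seq_along(frames@frames)) {
    fr <- frames@frames[[f]]
    n <- nrow(fr$O)
    sites <- .frameSites(fr)
    par <- .waterSiteParams(n, model)
    lin <- assignment$index[[f]]
    inGrid <- which(!is.na(lin))
    if (!length(inGrid)) next
    addAt <- function(acc, idx, w) {
      ag <- rowsum(w, idx)       # aggregate: several waters may share a voxel
      at <- as.integer(rownames(ag))
      acc[at] <- acc[at] + ag[, 1]
      acc
    }
    if (!is.null(solute)) {
      esite <- .sitePairEnergy(sites, par, solPos, solPar, model@coulomb)
      eWat <- rowsum(rowSums(esite), par$water)
      accSW <- addAt(accSW, lin[inGrid], eWat[inGrid])
    }
    if (n > 1) {
      esite <- .sitePairEnergy(sites, par, sites, par, model@coulomb)
      # zero intramolecular site pairs
      same <- outer(par$water, par$water, "==")
      esite[same] <- 0
      eWat <- rowsum(rowSums(esite), par$water) / 2   # half per partner
      accWW <- addAt(accWW, lin[inGrid], eWat[inGrid] - Ebulk)
    } else {
      accWW <- addAt(accWW, lin[inGrid], rep(-Ebulk, length(inGrid)))
    }
  }
  list(dEsw = array(accSW / (nFrames * Vk), geom$shape),
       dEww = array(accWW / (nFrames * Vk), geom$shape))
}

#' Run the full GIST analysis on a frame set
#'
#' @param frames a \linkS4class{WaterFrameSet}.
#' @param geom grid geometry (origin, spacing, shape), e.g. from
#'   \code{alignGrid}.
#' @param model solvent model (water parameters and rigid geometry).
#' @param rho0 bulk number density (Angstrom^-3); defaults to the model's
#'   molecular density.
#' @param solute optional SoluteStructure.
#' @param Ebulk per-water bulk water-water reference energy (kcal/mol).
#' @param orientMethod "nn" or "histogram".
#' @param minOrientSamples minimum orientation samples per voxel.
#' @return a \linkS4class{GistResults}.
#' @export
runGIST <- function(frames, geom, model = buildCTIP3P(),
                    rho0 = model@molecularDensity, solute = NULL,
                    Ebulk = 0, orientMethod = "nn",
                    minOrientSamples = 20) {
  asg <- assignWaters(frames, geom)
  nFrames <- length(frames@frames)
  g <- gistOccupancy(asg, nFrames, rho0)
  dStrans <- translationalEntropy(g, rho0)
  orient <- orientationalEntropy(frames, asg, rho0, orientMethod,
                                 minOrientSamples)
  en <- gistEnergies(frames, asg, model, solute, Ebulk)
  new("GistResults",
      nObs = asg$counts, g = g,
      dStrans = dStrans, dSorient = orient$density,
      dEsw = en$dEsw, dEww = en$dEww,
      orientFlagged = orient$flagged,
      bulkDensity = rho0, nFrames = as.integer(nFrames),
      origin = geom$origin, spacing = geom$spacing)
}

#' -T dS map of a GIST result
#'
#' @param results a GistResults.
#' @param temperature T in K.
#' @param which "total", "trans" or "orient".
#' @return numeric array (kcal/mol/Angstrom^3).
#' @export
gistMinusTdS <- function(results, temperature,
                         which = c("total", "trans", "orient")) {
  which <- match.arg(which)
  s <- switch(which,
              total = results@dStrans + results@dSorient,
              trans = results@dStrans,
              orient = results@dSorient)
  -temperature * s
}
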