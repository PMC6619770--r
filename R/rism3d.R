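# 3D-RISM solver: h_a(r) = sum_g int c_g(r-r') chi_ag(r') dr' closed by the
# PSE-n family, iterated in reciprocal space with MDIIS acceleration.  The
# direct correlation of each site is split into a short-range grid part and
# the analytic -beta q_a phi_erf(r) Coulomb asymptotics, so only the
# short-range part is iterated.

.fft3 <- function(a) stats::fft(a)
.ifft3 <- function(A) Re(stats::fft(A, inverse = TRUE)) / length(A)

#' Grid geometry around a solute
#'
#' Chooses a lattice-aligned cubic-voxel grid that encloses the solute with
#' at least \code{buffer} Angstrom between any atom and every grid face.
#'
#' @param solute a SoluteStructure.
#' @param spacing voxel edge (Angstrom).
#' @param buffer minimum solute-edge distance (Angstrom).
#' @return geometry list (origin, spacing, shape).
#' @export
geometryAroundSolute <- function(solute, spacing = 0.5, buffer = 24) {
  a <- solute@atoms
  lo <- c(min(a$x), min(a$y), min(a$z)) - buffer
  hi <- c(max(a$x), max(a$y), max(a$z)) + buffer
  shape <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  alignGrid((lo + hi) / 2, spacing, shape)
}

.stateGeom <- function(state) {
  list(origin = state@origin, spacing = state@spacing,
       shape = dim(state@h[[1]]))
}

#' Solve 3D-RISM around a rigid solute
#'
#' @param solute a \linkS4class{SoluteStructure}.
#' @param bulk a converged \linkS4class{BulkSolvent} supplying the site-site
#'   susceptibility.
#' @param geom grid geometry from \code{geometryAroundSolute} or
#'   \code{alignGrid}; if NULL it is built from \code{spacing} and
#'   \code{buffer}.
#' @param spacing,buffer used when \code{geom} is NULL.  The production
#'   defaults are 0.5 Angstrom and 24 Angstrom; small test fixtures use
#'   smaller buffers.
#' @param closure "kh", "pse2", "pse3", ... or "hnc".
#' @param tol RMS residual target on the short-range direct correlation.
#' @param maxIter iteration cap per closure rung.
#' @param mdiis MDIIS settings (see \code{solveDRISM}).
#' @param ladder logical, KH -> PSE-2 -> ... warm-start schedule.
#' @param coulombSmear erf smearing length (Angstrom) of the long-range
#'   Coulomb split (only used for charged solutes).
#' @param csInit optional warm start: named list of short-range direct
#'   correlation arrays.
#' @param minBuffer solves are refused when the solute is closer than this
#'   to the grid edge (Angstrom).
#' @param uGrids optional precomputed site potential grids (named list of
#'   3D arrays, kcal/mol) overriding the direct sum over \code{solute};
#'   \code{phiGrid} (erf-smeared electrostatic potential) must accompany it
#'   for charged solutes.
#' @param phiGrid see \code{uGrids}.
#' @param verbose print residuals.
#' @return a \linkS4class{RismState}.
#' @export
solveRISM3D <- function(solute, bulk, geom = NULL, spacing = 0.5,
                        buffer = 24, closure = "pse3", tol = 1e-6,
                        maxIter = 1000,
                        mdiis = list(nvec = 10, step = 0.7, restart = 10),
                        ladder = TRUE, coulombSmear = 1.0, csInit = NULL,
                        minBuffer = 4, uGrids = NULL, phiGrid = NULL,
                        verbose = FALSE) {
  .requireConverged(bulk)
  model <- bulk@model
  if (is.null(geom))
    geom <- geometryAroundSolute(solute, spacing, buffer)
  a <- solute@atoms
  lo <- geom$origin; hi <- geom$origin + geom$spacing * (geom$shape - 1)
  edges <- c(min(a$x) - lo[1], min(a$y) - lo[2], min(a$z) - lo[3],
             hi[1] - max(a$x), hi[2] - max(a$y), hi[3] - max(a$z))
  if (any(edges < minBuffer))
    stop("grid too small: solute within ", round(min(edges), 2),
         " A of the grid edge (minBuffer = ", minBuffer, ")")
  ns <- nrow(model@sites)
  nm <- model@sites$name
  beta <- .beta(model)
  kl <- .kLattice(geom$shape, geom$spacing)
  if (max(kl$kmag) > max(radialAbscissae(bulk@grid)$k))
    stop("bulk radial grid does not cover the 3D reciprocal lattice")
  chi <- susceptibilityOn3DGrid(bulk, kl$kmag)
  u <- if (is.null(uGrids)) computePotential(solute, model, geom) else uGrids
  charged <- any(abs(a$charge) > 1e-14)
  phiLR <- if (!is.null(phiGrid)) phiGrid
           else if (charged) .smearedPotential(solute, model, geom,
                                               coulombSmear)
           else array(0, geom$shape)
  q <- model@sites$charge
  uShort <- cLRK <- vector("list", ns)
  names(uShort) <- names(cLRK) <- nm
  for (s in seq_len(ns)) {
    uShort[[s]] <- u[[s]] - q[s] * phiLR
    cLRK[[s]] <- if (charged) .fft3(-beta * q[s] * phiLR)
                 else array(0 + 0i, geom$shape)
  }
  orderFinal <- .closureOrder(closure)
  orders <- if (!ladder) orderFinal else {
    if (is.infinite(orderFinal)) c(1, 2, 3, Inf) else seq_len(orderFinal)
  }
  cs <- if (is.null(csInit)) {
    stats::setNames(lapply(seq_len(ns), function(i) array(0, geom$shape)), nm)
  } else csInit
  res <- NA_real_
  nvox <- prod(geom$shape)
  for (ord in orders) {
    st <- .mdiisNew(mdiis$nvec, mdiis$step, mdiis$restart)
    ok <- FALSE
    badStreak <- 0
    prevRes <- Inf
    for (it in seq_len(maxIter)) {
      csK <- lapply(cs, .fft3)
      cK <- mapply(function(a, b) a + b, csK, cLRK, SIMPLIFY = FALSE)
      gammaS <- vector("list", ns)
      tstar <- vector("list", ns)
      csNew <- vector("list", ns)
      for (s in seq_len(ns)) {
        hK <- array(0 + 0i, geom$shape)
        for (g in seq_len(ns)) {
          hK <- hK + cK[[g]] * chi[[paste("chi", nm[s], nm[g], sep = ".")]]
        }
        gS <- .ifft3(hK - csK[[s]])
        ts <- gS - beta * uShort[[s]]
        gfun <- closureG(ts, ord)
        gammaS[[s]] <- gS
        tstar[[s]] <- ts
        csNew[[s]] <- gfun - 1 - gS
      }
      resv <- unlist(csNew, use.names = FALSE) - unlist(cs, use.names = FALSE)
      res <- sqrt(mean(resv^2))
      if (!is.finite(res))
        stop("NaN in 3D-RISM iteration (closure ", .closureName(ord), ")")
      if (verbose && it %% 10 == 0)
        message(.closureName(ord), " iter ", it, " residual ",
                format(res, digits = 3))
      if (res <= tol) { ok <- TRUE; break }
      badStreak <- if (res > prevRes) badStreak + 1 else 0
      if (badStreak > 50)
        stop("3D-RISM diverging: residual rose over 50 consecutive ",
             "iterations (last ", format(res, digits = 4), ")")
      prevRes <- res
      xnew <- .mdiisUpdate(st, unlist(cs, use.names = FALSE), resv)
      for (s in seq_len(ns)) {
        cs[[s]] <- array(xnew[((s - 1) * nvox + 1):(s * nvox)], geom$shape)
      }
    }
    if (!ok && ord == orderFinal)
      warning("3D-RISM did not reach tolerance (residual ",
              format(res, digits = 4), ")")
  }
  # final consistent fields at the requested closure
  csK <- lapply(cs, .fft3)
  cK <- mapply(function(a, b) a + b, csK, cLRK, SIMPLIFY = FALSE)
  h <- g <- tstar <- cfull <- vector("list", ns)
  names(h) <- names(g) <- names(tstar) <- names(cfull) <- nm
  for (s in seq_len(ns)) {
    hK <- array(0 + 0i, geom$shape)
    for (gg in seq_len(ns)) {
      hK <- hK + cK[[gg]] * chi[[paste("chi", nm[s], nm[gg], sep = ".")]]
    }
    gS <- .ifft3(hK - csK[[s]])
    ts <- gS - beta * uShort[[s]]
    gv <- closureG(ts, orderFinal)
    h[[s]] <- gv - 1
    g[[s]] <- gv
    tstar[[s]] <- ts
    cfull[[s]] <- cs[[s]] + if (charged) -beta * q[s] * phiLR else 0
  }
  new("RismState",
      siteNames = nm, h = h, c = cfull, tstar = tstar, g = g, u = u,
      closure = orderFinal,
      origin = geom$origin, spacing = geom$spacing,
      temperature = model@temperature,
      residual = res, tolerance = tol, converged = res <= tol,
      dT = list())
}

.withTemperature <- function(model, temp) {
  model@temperature <- temp
  model
}

#' Isochoric temperature-derivative grids of a 3D-RISM state
#'
#' Computes delta_T h = T (dh/dT)_rho and delta_T c on the state's grid,
#' either by central finite differences of full re-solves at T +/- deltaT
#' (mode "fd", the default; bulk susceptibilities are re-solved at the
#' perturbed temperatures so the derivative is temperature-consistent) or
#' by solving the linearised RISM + closure equations for the derivative
#' fields directly (mode "linear"), with the bulk susceptibility derivative
#' still taken by central differences of the 1D solve.
#'
#' Also computes the partial-molar-volume temperature derivative inputs
#' (compressibility and direct-correlation integrals at the perturbed
#' temperatures) needed by the UCT correction.
#'
#' @param state a converged \linkS4class{RismState}.
#' @param solute the solute it was solved for.
#' @param bulk the converged \linkS4class{BulkSolvent} used for the solve.
#' @param mode "fd" or "linear".
#' @param deltaT temperature step in K.
#' @param tol tolerance for the perturbed/linearised solves (default: the
#'   state's tolerance).
#' @param maxIter iteration cap.
#' @param verbose print residuals.
#' @return the state with its \code{dT} slot filled (elements h, c, tstar:
#'   named lists of arrays; scalars chiT, dTchiT; mode, deltaT).
#' @export
solveTemperatureDerivatives <- function(state, solute, bulk,
                                        mode = c("fd", "linear"),
                                        deltaT = 1, tol = NULL,
                                        maxIter = 1000, verbose = FALSE) {
  mode <- match.arg(mode)
  if (!state@converged) stop("state is not converged")
  model <- bulk@model
  if (is.null(tol)) tol <- state@tolerance
  geom <- .stateGeom(state)
  T0 <- state@temperature
  bulkPM <- lapply(c(-1, 1), function(sgn) {
    solveDRISM(.withTemperature(model, T0 + sgn * deltaT), bulk@grid,
               closure = bulk@closure, tol = bulk@tolerance,
               coulombSmear = bulk@coulombSmear,
               bridgeSmear = bulk@bridgeSmear,
               csInit = bulk@csShort, ladder = FALSE)
  })
  chiTm <- compressibility(bulkPM[[1]])
  chiTp <- compressibility(bulkPM[[2]])
  chiT0 <- compressibility(bulk)
  nm <- state@siteNames
  dT <- list(mode = mode, deltaT = deltaT,
             chiT = chiT0,
             dTchiT = T0 * (chiTp - chiTm) / (2 * deltaT))
  if (mode == "fd") {
    statePM <- lapply(1:2, function(i) {
      solveRISM3D(solute, bulkPM[[i]], geom = geom,
                  closure = state@closure, tol = tol, maxIter = maxIter,
                  ladder = FALSE,
                  csInit = .shortRangeC(state, bulkPM[[i]], solute),
                  minBuffer = 0, verbose = verbose)
    })
    fd <- function(field) {
      stats::setNames(lapply(nm, function(s) {
        T0 * (slot(statePM[[2]], field)[[s]] -
                slot(statePM[[1]], field)[[s]]) / (2 * deltaT)
      }), nm)
    }
    dT$h <- fd("h")
    dT$c <- fd("c")
    dT$tstar <- fd("tstar")
  } else {
    dT <- c(dT, .linearTderiv(state, solute, bulk, bulkPM, deltaT, tol,
                              maxIter, verbose))
  }
  state@dT <- dT
  state
}

# Short-range direct correlation of a state for use as a warm start under a
# (possibly temperature-shifted) bulk: c_s = c + beta q phi_erf, with the
# smeared solute potential recomputed and beta taken at the target bulk's
# temperature (warm starts need not be exact).
.shortRangeC <- function(state, bulk, solute, smear = 1.0) {
  model <- bulk@model
  geom <- .stateGeom(state)
  q <- model@sites$charge
  if (all(abs(solute@atoms$charge) < 1e-14)) return(state@c)
  phi <- .smearedPotential(solute, model, geom, smear)
  beta <- .beta(model)
  stats::setNames(lapply(seq_along(q), function(s) {
    state@c[[s]] + beta * q[s] * phi
  }), state@siteNames)
}

.linearTderiv <- function(state, solute, bulk, bulkPM, deltaT, tol,
                          maxIter, verbose) {
  model <- bulk@model
  geom <- .stateGeom(state)
  nm <- state@siteNames
  ns <- length(nm)
  beta <- .beta(model)
  T0 <- state@temperature
  kl <- .kLattice(geom$shape, geom$spacing)
  chi0 <- susceptibilityOn3DGrid(bulk, kl$kmag)
  chiP <- susceptibilityOn3DGrid(bulkPM[[2]], kl$kmag)
  chiM <- susceptibilityOn3DGrid(bulkPM[[1]], kl$kmag)
  dchi <- stats::setNames(lapply(names(chi0), function(nmp) {
    T0 * (chiP[[nmp]] - chiM[[nmp]]) / (2 * deltaT)
  }), names(chi0))
  q <- model@sites$charge
  charged <- any(abs(solute@atoms$charge) > 1e-14)
  phiLR <- if (charged) {
    .smearedPotential(solute, model, geom, 1.0)
  } else array(0, geom$shape)
  # state c is full c; split back into grid + analytic parts
  csState <- stats::setNames(lapply(seq_len(ns), function(s) {
    state@c[[s]] + beta * q[s] * phiLR
  }), nm)
  csKState <- lapply(csState, .fft3)
  cKState <- stats::setNames(lapply(seq_len(ns), function(s) {
    csKState[[s]] + .fft3(-beta * q[s] * phiLR)
  }), nm)
  uShort <- stats::setNames(lapply(seq_len(ns), function(s) {
    state@u[[s]] - q[s] * phiLR
  }), nm)
  gp <- stats::setNames(lapply(seq_len(ns), function(s) {
    closureGPrime(state@tstar[[s]], state@closure)
  }), nm)
  # delta_T of the analytic long-range c is -c_lr = +beta q phi
  dcLRK <- stats::setNames(lapply(seq_len(ns), function(s) {
    .fft3(beta * q[s] * phiLR)
  }), nm)
  dcs <- stats::setNames(lapply(seq_len(ns),
                                function(s) array(0, geom$shape)), nm)
  st <- .mdiisNew(10, 0.7, 10)
  nvox <- prod(geom$shape)
  res <- NA_real_
  for (it in seq_len(maxIter)) {
    dcsK <- lapply(dcs, .fft3)
    dcK <- mapply(function(a, b) a + b, dcsK, dcLRK, SIMPLIFY = FALSE)
    dcsNew <- vector("list", ns)
    for (s in seq_len(ns)) {
      dhK <- array(0 + 0i, geom$shape)
      for (g in seq_len(ns)) {
        key <- paste("chi", nm[s], nm[g], sep = ".")
        dhK <- dhK + dcK[[g]] * chi0[[key]] + cKState[[g]] * dchi[[key]]
      }
      dgammaS <- .ifft3(dhK - dcsK[[s]])
      dts <- beta * uShort[[s]] + dgammaS
      dh <- gp[[s]] * dts
      dcsNew[[s]] <- dh - dgammaS
    }
    resv <- unlist(dcsNew, use.names = FALSE) - unlist(dcs, use.names = FALSE)
    res <- sqrt(mean(resv^2))
    if (!is.finite(res)) stop("NaN in linearised derivative solve")
    if (verbose && it %% 10 == 0)
      message("linear dT iter ", it, " residual ", format(res, digits = 3))
    if (res <= tol) break
    xnew <- .mdiisUpdate(st, unlist(dcs, use.names = FALSE), resv)
    for (s in seq_len(ns)) {
      dcs[[s]] <- array(xnew[((s - 1) * nvox + 1):(s * nvox)], geom$shape)
    }
  }
  if (res > tol)
    warning("linearised derivative solve stalled at residual ",
            format(res, digits = 4))
  # assemble consistent derivative fields
  dcsK <- lapply(dcs, .fft3)
  dcK <- mapply(function(a, b) a + b, dcsK, dcLRK, SIMPLIFY = FALSE)
  dTh <- dTc <- dTt <- stats::setNames(vector("list", ns), nm)
  for (s in seq_len(ns)) {
    dhK <- array(0 + 0i, geom$shape)
    for (g in seq_len(ns)) {
      key <- paste("chi", nm[s], nm[g], sep = ".")
      dhK <- dhK + dcK[[g]] * chi0[[key]] + cKState[[g]] * dchi[[key]]
    }
    dgammaS <- .ifft3(dhK - dcsK[[s]])
    dts <- beta * uShort[[s]] + dgammaS
    dTh[[s]] <- gp[[s]] * dts
    dTt[[s]] <- dts
    dTc[[s]] <- dcs[[s]] + beta * q[s] * phiLR
  }
  list(h = dTh, c = dTc, tstar = dTt)
}
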