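# 1D dielectrically consistent RISM (DRISM) for the bulk solvent.
#
# The site-site Ornstein-Zernike relation is iterated in the symmetric
# structure-factor form S = (I - S_w C)^-1 S_w, where
# S_w,ag(k) = rho_a * omega_ag(k) is the intramolecular structure factor
# (symmetric because omega sums positions of the second index).  Dielectric
# consistency adds a long-range dipolar bridge to S_w,
#   S_w~ = S_w + rho_m^2 h_c(k) D_a(k) D_g(k),
#   D_a(k) = sum over positions of a of j0(k x) j0(k y) j1(k z),
#   h_c(k) = h0 exp(-k^2/(4 a^2)),  h0 = (eps - 1 - 3y)/(y rho_m),
#   y = (4 pi / 9) beta C rho_m d^2,
# with the molecular dipole d along +z of the molecular frame.  A small-k
# expansion of the charge-weighted structure factor then realises exactly
# the imposed dielectric constant eps, independent of the closure.

.sphericalJ1 <- function(x) {
  small <- abs(x) < 1e-4
  out <- numeric(length(x))
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 30
  xl <- x[!small]
  out[!small] <- sin(xl) / xl^2 - cos(xl) / xl
  out
}

# Symmetric 2x2-per-k solve S = (I - Sw C)^-1 Sw, vectorised over k.
# sw, cc: arrays [nk, 2, 2].
.ssoz2 <- function(sw, cc) {
  s11 <- sw[, 1, 1]; s12 <- sw[, 1, 2]; s22 <- sw[, 2, 2]
  c11 <- cc[, 1, 1]; c12 <- cc[, 1, 2]; c22 <- cc[, 2, 2]
  a11 <- 1 - (s11 * c11 + s12 * c12)
  a12 <- -(s11 * c12 + s12 * c22)
  a21 <- -(s12 * c11 + s22 * c12)
  a22 <- 1 - (s12 * c12 + s22 * c22)
  det <- a11 * a22 - a12 * a21
  S <- array(0, dim(sw))
  S[, 1, 1] <- (a22 * s11 - a12 * s12) / det
  S[, 2, 2] <- (-a21 * s12 + a11 * s22) / det
  s12new <- 0.5 * ((a22 * s12 - a12 * s22) + (-a21 * s11 + a11 * s12)) / det
  S[, 1, 2] <- s12new
  S[, 2, 1] <- s12new
  S
}

# general-n fallback (k-point loop)
.ssozN <- function(sw, cc) {
  nk <- dim(sw)[1]; ns <- dim(sw)[2]
  S <- array(0, dim(sw))
  I <- diag(ns)
  for (j in seq_len(nk)) {
    swj <- sw[j, , ]; ccj <- cc[j, , ]
    Sj <- solve(I - swj %*% ccj, swj)
    S[j, , ] <- 0.5 * (Sj + t(Sj))
  }
  S
}

.drismSetup <- function(model, grid, coulombSmear, bridgeSmear) {
  ax <- radialAbscissae(grid)
  ns <- nrow(model@sites)
  q <- model@sites$charge
  rho <- unname(model@siteDensities)
  rhoM <- model@molecularDensity
  beta <- .beta(model)
  omega <- intramolecularOmega(model, ax$k)
  sw <- omega
  for (a in seq_len(ns)) sw[, a, ] <- rho[a] * omega[, a, ]
  # symmetrise against roundoff
  for (a in seq_len(ns)) for (g in seq_len(ns)) {
    if (a < g) {
      m <- 0.5 * (sw[, a, g] + sw[, g, a])
      sw[, a, g] <- m; sw[, g, a] <- m
    }
  }
  # dielectric bridge
  d <- solventDipole(model)
  zeta <- array(0, dim(sw))
  if (d > 1e-12) {
    y <- (4 * pi / 9) * beta * model@coulomb * rhoM * d^2
    h0 <- (model@targetDielectric - 1 - 3 * y) / (y * rhoM)
    hck <- h0 * exp(-ax$k^2 / (4 * bridgeSmear^2))
    D <- matrix(0, length(ax$k), ns)
    for (p in seq_len(nrow(model@positions))) {
      ty <- model@positionType[p]
      xyz <- model@positions[p, ]
      D[, ty] <- D[, ty] + .sinc(ax$k * xyz[1]) * .sinc(ax$k * xyz[2]) *
        .sphericalJ1(ax$k * xyz[3])
    }
    for (a in seq_len(ns)) for (g in seq_len(ns)) {
      zeta[, a, g] <- rhoM^2 * hck * D[, a] * D[, g]
    }
  }
  # pair potentials (short-range part) and analytic long-range c
  uShort <- array(0, c(grid@n, ns, ns))
  clrK <- array(0, c(grid@n, ns, ns))
  sig <- model@sites$sigma; eps <- model@sites$epsilon
  for (a in seq_len(ns)) for (g in seq_len(ns)) {
    sm <- 0.5 * (sig[a] + sig[g]); em <- sqrt(eps[a] * eps[g])
    sr6 <- (sm / ax$r)^6
    u <- 4 * em * (sr6^2 - sr6) +
      model@coulomb * q[a] * q[g] * .erfc(ax$r / coulombSmear) / ax$r
    uShort[, a, g] <- pmin(u, 1e10)
    clrK[, a, g] <- -beta * 4 * pi * model@coulomb * q[a] * q[g] *
      exp(-ax$k^2 * coulombSmear^2 / 4) / ax$k^2
  }
  list(ax = ax, ns = ns, q = q, rho = rho, rhoM = rhoM, beta = beta,
       sw = sw, swTilde = sw + zeta, zeta = zeta,
       uShort = uShort, clrK = clrK)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# One DRISM closure pass: given short-range c (array [nr,ns,ns]), return
# list(csNew, h, S) at fixed closure order.
.drismSweep <- function(cs, setup, grid, order) {
  ns <- setup$ns
  csK <- array(0, dim(cs))
  for (a in seq_len(ns)) for (g in a:ns) {
    ck <- radialFT(cs[, a, g], grid)
    csK[, a, g] <- ck; csK[, g, a] <- ck
  }
  cK <- csK + setup$clrK
  S <- if (ns == 2) .ssoz2(setup$swTilde, cK) else .ssozN(setup$swTilde, cK)
  csNew <- array(0, dim(cs))
  h <- array(0, dim(cs))
  hK <- array(0, dim(cs))
  for (a in seq_len(ns)) for (g in a:ns) {
    rr <- setup$rho[a] * setup$rho[g]
    hk <- (S[, a, g] - setup$swTilde[, a, g]) / rr +
      setup$zeta[, a, g] / rr    # add bridge back: physical h
    gammaSK <- hk - csK[, a, g]
    gammaS <- radialIFT(gammaSK, grid)
    tstar <- gammaS - setup$beta * setup$uShort[, a, g]
    gfun <- closureG(tstar, order)
    cn <- gfun - 1 - gammaS
    csNew[, a, g] <- cn; csNew[, g, a] <- cn
    hr <- gfun - 1
    h[, a, g] <- hr; h[, g, a] <- hr
    hK[, a, g] <- hk; hK[, g, a] <- hk
  }
  list(csNew = csNew, h = h, hK = hK)
}

#' Solve dielectrically consistent 1D RISM for the bulk solvent
#'
#' Iterates the 1D site-site Ornstein-Zernike relation with the PSE-n
#' closure family and a Perkyns-Pettitt-style dielectric bridge that imposes
#' the model's target dielectric constant.  Convergence is accelerated by
#' MDIIS; by default a closure ladder is used (KH first, then increasing
#' PSE order), each rung warm-started from the previous solution.
#'
#' @param model a \linkS4class{SolventModel}.
#' @param grid a \linkS4class{RadialGrid} (e.g. \code{radialGrid(16384,
#'   0.025)}).
#' @param closure "kh", "pse2", "pse3", ..., or "hnc".
#' @param tol target RMS residual of the short-range direct correlation
#'   update.
#' @param maxIter iteration cap per closure rung.
#' @param mdiis list of MDIIS settings: \code{nvec} stored vectors,
#'   \code{step} damping, \code{restart} residual-increase factor triggering
#'   a subspace flush.
#' @param ladder logical; solve easier closures first and warm-start.
#' @param coulombSmear erf smearing length (Angstrom) used to split the
#'   Coulomb direct correlation into grid + analytic parts.
#' @param bridgeSmear Gaussian envelope parameter a (Angstrom^-1) of the
#'   dielectric bridge.
#' @param csInit optional warm-start array for the short-range direct
#'   correlation.
#' @param verbose print residuals.
#' @return a \linkS4class{BulkSolvent}.
#' @export
solveDRISM <- function(model, grid, closure = "pse3", tol = 1e-12,
                       maxIter = 5000,
                       mdiis = list(nvec = 10, step = 0.7, restart = 10),
                       ladder = TRUE, coulombSmear = 1.0, bridgeSmear = 0.5,
                       csInit = NULL, verbose = FALSE) {
  if (tol <= 0) stop("tolerance must be > 0")
  setup <- .drismSetup(model, grid, coulombSmear, bridgeSmear)
  orderFinal <- .closureOrder(closure)
  orders <- if (!ladder) orderFinal else {
    if (is.infinite(orderFinal)) c(1, 2, 3, Inf)
    else seq_len(orderFinal)
  }
  cs <- if (is.null(csInit)) array(0, c(grid@n, setup$ns, setup$ns)) else csInit
  history <- numeric()
  res <- NA_real_
  for (ord in orders) {
    st <- .mdiisNew(mdiis$nvec, mdiis$step, mdiis$restart)
    ok <- FALSE
    for (it in seq_len(maxIter)) {
      sweep <- .drismSweep(cs, setup, grid, ord)
      resv <- sweep$csNew - cs
      res <- sqrt(mean(resv^2))
      history <- c(history, res)
      if (!is.finite(res)) stop("NaN in DRISM iteration (closure ",
                                .closureName(ord), ", iter ", it, ")")
      if (verbose && it %% 25 == 0)
        message(.closureName(ord), " iter ", it, " residual ",
                format(res, digits = 3))
      if (res <= tol) { ok <- TRUE; break }
      cs <- array(.mdiisUpdate(st, as.vector(cs), as.vector(resv)),
                  dim(cs))
    }
    if (!ok && ord == orderFinal) {
      warning("DRISM did not reach tolerance (residual ",
              format(res, digits = 4), ")")
    }
  }
  sweep <- .drismSweep(cs, setup, grid, orderFinal)
  # physical structure factor S_ag = rho_a w_ag + rho_a rho_g h_ag
  ns <- setup$ns
  S <- setup$sw
  for (a in seq_len(ns)) for (g in seq_len(ns)) {
    S[, a, g] <- setup$sw[, a, g] +
      setup$rho[a] * setup$rho[g] * sweep$hK[, a, g]
  }
  # real-space h from the closure branch (g - 1), so g = h + 1 >= 0 holds
  # exactly; the k-space hK (with its transform ringing in the core) only
  # enters through S
  hr <- sweep$h
  dimnames(S) <- dimnames(hr) <- dimnames(cs) <-
    list(NULL, model@sites$name, model@sites$name)
  new("BulkSolvent",
      model = model, grid = grid, S = S, h = hr, csShort = cs,
      closure = .closureName(orderFinal),
      residual = res, tolerance = tol, converged = res <= tol,
      coulombSmear = coulombSmear, bridgeSmear = bridgeSmear,
      residualHistory = history)
}

.requireConverged <- function(bulk) {
  if (!bulk@converged) stop("bulk solvent solution is not converged")
}

#' Dielectric constant realised by a converged bulk solution
#'
#' Recomputed from the correlations, not read from the model: the
#' charge-weighted structure factor obeys
#' sum_ag q_a q_g S_ag(k) -> k^2/(4 pi beta C) (1 - 1/eps) as k -> 0,
#' so eps is recovered by quadratic extrapolation of q'Sq/k^2 in k^2 over
#' the smallest wavenumbers.
#'
#' @param bulk a converged \linkS4class{BulkSolvent}.
#' @param npoints number of small-k points used in the extrapolation.
#' @return the realised dielectric constant.
#' @export
realizedDielectric <- function(bulk, npoints = 8) {
  .requireConverged(bulk)
  model <- bulk@model
  ax <- radialAbscissae(bulk@grid)
  q <- model@sites$charge
  idx <- seq_len(npoints)
  qSq <- numeric(npoints)
  ns <- length(q)
  for (a in seq_len(ns)) for (g in seq_len(ns)) {
    qSq <- qSq + q[a] * q[g] * bulk@S[idx, a, g]
  }
  k2 <- ax$k[idx]^2
  fit <- stats::lm(I(qSq / k2) ~ k2)
  L <- 4 * pi * .beta(model) * model@coulomb * unname(stats::coef(fit)[1])
  1 / (1 - L)
}

#' Isothermal compressibility from a converged bulk solution
#'
#' Uses the k -> 0 compressibility relation
#' rho_m kB T chi_T = 1 / (1 - rho_m sum_ag M_a M_g c_ag(k=0)),
#' where the direct correlation integrals are extrapolated quadratically to
#' k = 0 (the analytic Coulomb parts cancel by charge neutrality).
#'
#' @param bulk a converged \linkS4class{BulkSolvent}.
#' @param npoints small-k points for the extrapolation; \code{npoints = 1}
#'   uses the value at the smallest k instead.
#' @return chi_T in (kcal/mol/Angstrom^3)^-1.
#' @export
compressibility <- function(bulk, npoints = 12) {
  .requireConverged(bulk)
  model <- bulk@model
  ax <- radialAbscissae(bulk@grid)
  M <- model@sites$multiplicity
  ns <- length(M)
  idx <- seq_len(max(npoints, 1))
  acc <- numeric(length(idx))
  for (a in seq_len(ns)) for (g in seq_len(ns)) {
    acc <- acc + M[a] * M[g] * radialFT(bulk@csShort[, a, g], bulk@grid)[idx]
  }
  c0 <- if (npoints == 1) acc[1] else {
    k2 <- ax$k[idx]^2
    unname(stats::coef(stats::lm(acc ~ k2))[1])
  }
  rhoM <- model@molecularDensity
  1 / (rhoM * model@kB * model@temperature * (1 - rhoM * c0))
}

#' Sample the bulk susceptibility on a 3D reciprocal lattice
#'
#' Radially interpolates the (symmetric) structure factor S_ag(k) of a
#' converged bulk solution onto arbitrary |k| values with a natural cubic
#' spline, returning the 3D-RISM susceptibility chi_ag(k) = S_ag(k)/rho_a
#' of each site pair.  The k = 0 value is obtained by quadratic
#' extrapolation in k^2.
#'
#' @param bulk a converged \linkS4class{BulkSolvent}.
#' @param kmag numeric vector (or array) of |k| values; all must lie within
#'   the radial grid's reciprocal range.
#' @return list of numeric objects shaped like \code{kmag}, one per site
#'   pair, named "chi.O.O", "chi.O.H", ... (chi_ag, first index = a).
#' @export
susceptibilityOn3DGrid <- function(bulk, kmag) {
  .requireConverged(bulk)
  ax <- radialAbscissae(bulk@grid)
  if (max(kmag) > max(ax$k))
    stop("requested |k| beyond the radial reciprocal grid")
  model <- bulk@model
  nm <- model@sites$name
  ns <- length(nm)
  rho <- unname(model@siteDensities)
  out <- list()
  for (a in seq_len(ns)) for (g in seq_len(ns)) {
    Sag <- bulk@S[, a, g]
    # S(k) is even in k: mirror the first points through the origin so the
    # spline interpolates smoothly across k = 0 without a boundary kink
    kk <- c(-rev(ax$k[1:8]), ax$k)
    vv <- c(rev(Sag[1:8]), Sag)
    sf <- stats::splinefun(kk, vv, method = "fmm")
    vals <- sf(as.numeric(kmag)) / rho[a]
    attr_dim <- dim(kmag)
    if (!is.null(attr_dim)) dim(vals) <- attr_dim
    out[[paste("chi", nm[a], nm[g], sep = ".")]] <- vals
  }
  out
}
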