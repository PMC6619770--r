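# Thermodynamic density maps from a converged 3D-RISM state: excess
# chemical potential density of the PSE-n closure, its isochoric
# temperature derivative (-T dS), the energy density and its solute-water /
# water-water split, the partial molar volume, and the UCT correction.

.thetaMask <- function(state, site, theta) {
  if (theta == "tstar") state@tstar[[site]] >= 0 else state@h[[site]] >= 0
}

#' Excess chemical potential density maps
#'
#' Per-site closure free-energy density of the PSE-n family,
#' \deqn{\Delta\mu_g(r) = k_B T \rho_g [ h^2/2 - c - hc/2
#'       - t*^{n+1}/(n+1)!\,\Theta ],}
#' in kcal/mol/Angstrom^3.  The Heaviside factor is applied where t* >= 0
#' (the active region of the PSE series branch; on a converged closure
#' manifold this coincides with h >= 0, and \code{theta = "h"} selects that
#' variant explicitly).  For HNC the truncation term vanishes.
#'
#' @param state a converged \linkS4class{RismState}.
#' @param model the \linkS4class{SolventModel}.
#' @param theta "tstar" (default) or "h": argument of the Heaviside factor.
#' @return named list of 3D arrays, one per site type.
#' @export
excessChemicalPotentialDensity <- function(state, model,
                                           theta = c("tstar", "h")) {
  theta <- match.arg(theta)
  kT <- model@kB * state@temperature
  rho <- model@siteDensities
  n <- state@closure
  out <- stats::setNames(vector("list", length(state@siteNames)),
                         state@siteNames)
  for (s in state@siteNames) {
    h <- state@h[[s]]; cc <- state@c[[s]]
    acc <- h^2 / 2 - cc - h * cc / 2
    if (is.finite(n)) {
      mask <- .thetaMask(state, s, theta)
      acc <- acc - mask * state@tstar[[s]]^(n + 1) / factorial(n + 1)
    }
    out[[s]] <- kT * rho[[s]] * acc
  }
  out
}

#' Solvation entropy density maps, -T dS(r)
#'
#' The isochoric temperature derivative delta_T = T (d/dT)_rho of the
#' excess chemical potential density, evaluated by the chain rule from the
#' state's derivative grids (delta_T h, delta_T c, delta_T t*):
#' \deqn{-T\Delta S_g = \Delta\mu_g + k_B T \rho_g [ h\,\delta_T h
#'   - \delta_T c - (c\,\delta_T h + h\,\delta_T c)/2
#'   - t*^{n}/n!\,\delta_T t*\,\Theta ].}
#' Requires \code{solveTemperatureDerivatives} to have been applied; a
#' finite-difference evaluation of Delta-mu at temperature-consistent
#' solutions is the test oracle for this expression.
#'
#' @inheritParams excessChemicalPotentialDensity
#' @param dmu optional precomputed output of
#'   \code{excessChemicalPotentialDensity}.
#' @return named list of 3D arrays (kcal/mol/Angstrom^3).
#' @export
entropyDensity <- function(state, model, theta = c("tstar", "h"),
                           dmu = NULL) {
  theta <- match.arg(theta)
  if (!length(state@dT)) stop("state has no temperature-derivative grids; ",
                              "run solveTemperatureDerivatives first")
  if (is.null(dmu)) dmu <- excessChemicalPotentialDensity(state, model, theta)
  kT <- model@kB * state@temperature
  rho <- model@siteDensities
  n <- state@closure
  out <- stats::setNames(vector("list", length(state@siteNames)),
                         state@siteNames)
  for (s in state@siteNames) {
    h <- state@h[[s]]; cc <- state@c[[s]]
    dh <- state@dT$h[[s]]; dc <- state@dT$c[[s]]
    acc <- h * dh - dc - (dh * cc + h * dc) / 2
    if (is.finite(n)) {
      mask <- .thetaMask(state, s, theta)
      acc <- acc - mask * state@tstar[[s]]^n / factorial(n) *
        state@dT$tstar[[s]]
    }
    out[[s]] <- dmu[[s]] + kT * rho[[s]] * acc
  }
  out
}

#' Solvation energy density maps and their solute-water/water-water split
#'
#' dE = dmu - delta_T dmu (closure-independent), the solute-water part
#' dE_sw,g = rho_g g_g(r) u_g(r), and the water-water remainder
#' dE_ww = dE - dE_sw, all in kcal/mol/Angstrom^3.
#'
#' @inheritParams entropyDensity
#' @param minusTdS optional precomputed output of \code{entropyDensity}.
#' @return list with named-list elements \code{dE}, \code{dEsw},
#'   \code{dEww}.
#' @export
energyDensities <- function(state, model, theta = c("tstar", "h"),
                            dmu = NULL, minusTdS = NULL) {
  theta <- match.arg(theta)
  if (is.null(dmu)) dmu <- excessChemicalPotentialDensity(state, model, theta)
  if (is.null(minusTdS)) minusTdS <- entropyDensity(state, model, theta, dmu)
  rho <- model@siteDensities
  nm <- state@siteNames
  dE <- dEsw <- dEww <- stats::setNames(vector("list", length(nm)), nm)
  for (s in nm) {
    dE[[s]] <- dmu[[s]] - minusTdS[[s]]
    dEsw[[s]] <- rho[[s]] * state@g[[s]] * state@u[[s]]
    dEww[[s]] <- dE[[s]] - dEsw[[s]]
  }
  list(dE = dE, dEsw = dEsw, dEww = dEww)
}

#' Partial molar volume of the solute and its local map
#'
#' v = kB T chi_T (1 - sum_g rho_g int c_g(r) dr) by voxel quadrature.
#' The local map distributes the direct-correlation term,
#' v(r) = -kB T chi_T sum_g rho_g c_g(r), with the constant "1" carried as
#' a scalar offset kB*T*chi_T (the local split is a stated convention: only
#' the c-term has unambiguous spatial structure).  If derivative grids are
#' present, delta_T v and the local delta_T v(r) are returned too.
#'
#' @param state a converged \linkS4class{RismState} (optionally with dT
#'   grids).
#' @param bulk the converged \linkS4class{BulkSolvent}.
#' @return list with \code{v}, \code{map}, \code{offset}, and (when
#'   derivatives are available) \code{dTv}, \code{dTmap}, \code{dToffset}.
#' @export
partialMolarVolume <- function(state, bulk) {
  if (!state@converged) stop("state is not converged")
  model <- bulk@model
  kT <- model@kB * state@temperature
  chiT <- if (length(state@dT)) state@dT$chiT else compressibility(bulk)
  rho <- model@siteDensities
  vol <- state@spacing^3
  P <- 0
  for (s in state@siteNames) P <- P + rho[[s]] * state@c[[s]]
  v <- kT * chiT * (1 - sum(P) * vol)
  out <- list(v = v, map = -kT * chiT * P, offset = kT * chiT)
  if (length(state@dT)) {
    dchi <- state@dT$dTchiT
    dP <- 0
    for (s in state@siteNames) dP <- dP + rho[[s]] * state@dT$c[[s]]
    # delta_T[kT chi (1 - int P)] = v (1 + dchi/chi) - kT chi int delta_T P
    out$dTv <- v * (1 + dchi / chiT) - kT * chiT * sum(dP) * vol
    out$dTmap <- out$map * (1 + dchi / chiT) - kT * chiT * dP
    out$dToffset <- out$offset * (1 + dchi / chiT)
  }
  out
}

#' Assemble all thermodynamic maps of a state
#'
#' Convenience constructor running
#' \code{excessChemicalPotentialDensity}, \code{entropyDensity},
#' \code{energyDensities} and \code{partialMolarVolume} and collecting the
#' results (and their volume integrals) into a \linkS4class{ThermoMaps}.
#'
#' @param state a converged \linkS4class{RismState} with temperature
#'   derivatives.
#' @param bulk the \linkS4class{BulkSolvent} of the solve.
#' @param theta Heaviside convention, see
#'   \code{excessChemicalPotentialDensity}.
#' @return a \linkS4class{ThermoMaps}.
#' @export
thermoMaps <- function(state, bulk, theta = c("tstar", "h")) {
  theta <- match.arg(theta)
  model <- bulk@model
  dmu <- excessChemicalPotentialDensity(state, model, theta)
  mTdS <- entropyDensity(state, model, theta, dmu)
  en <- energyDensities(state, model, theta, dmu, mTdS)
  pmv <- partialMolarVolume(state, bulk)
  vol <- state@spacing^3
  nm <- state@siteNames
  tot <- function(lst) vapply(nm, function(s) sum(lst[[s]]) * vol, 0)
  totals <- data.frame(site = c(nm, "total"),
                       dmu = c(tot(dmu), sum(tot(dmu))),
                       minusTdS = c(tot(mTdS), sum(tot(mTdS))),
                       dE = c(tot(en$dE), sum(tot(en$dE))),
                       dEsw = c(tot(en$dEsw), sum(tot(en$dEsw))),
                       dEww = c(tot(en$dEww), sum(tot(en$dEww))),
                       stringsAsFactors = FALSE)
  new("ThermoMaps",
      siteNames = nm,
      dmu = dmu, minusTdS = mTdS, dE = en$dE, dEsw = en$dEsw,
      dEww = en$dEww, totals = totals,
      pmv = pmv$v,
      dTpmv = if (is.null(pmv$dTv)) NA_real_ else pmv$dTv,
      pmvMap = pmv$map,
      dTpmvMap = if (is.null(pmv$dTmap)) array(NA_real_, dim(pmv$map))
                 else pmv$dTmap,
      pmvOffset = pmv$offset,
      origin = state@origin, spacing = state@spacing,
      uct = list())
}

#' UCT parameter set
#'
#' @param a0,a1,b0,b1 fitted scalars of the temperature-dependent universal
#'   correction; a = a1*T + a0 and b = b1*T + b0.
#' @return an \linkS4class{UctParams}.
#' @export
uctParams <- function(a0, a1, b0, b1) {
  new("UctParams", a0 = a0, a1 = a1, b0 = b0, b1 = b1)
}

#' UCT parameters fitted for the built-in water model
#' @return an \linkS4class{UctParams}.
#' @export
uctParamsCTIP3P <- function() {
  uctParams(a0 = -0.000507492, a1 = 0.0327564,
            b0 = 0.0100166, b1 = -3.26166)
}

#' Evaluate a = a1*T + a0 and b = b1*T + b0
#' @param params an UctParams; @param temperature T in K.
#' @return named numeric c(a =, b =).
#' @export
uctCoefficients <- function(params, temperature) {
  c(a = params@a1 * temperature + params@a0,
    b = params@b1 * temperature + params@b0)
}

#' Write/read UCT parameters as a key-value config file
#' @param params an UctParams; @param path file path.
#' @export
writeUctConfig <- function(params, path) {
  writeLines(sprintf("%s = %.10g", c("a0", "a1", "b0", "b1"),
                     c(params@a0, params@a1, params@b0, params@b1)), path)
  invisible(path)
}

#' @rdname writeUctConfig
#' @export
readUctConfig <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  kv <- regmatches(ln, regexec("^\\s*([ab][01])\\s*=\\s*(\\S+)", ln))
  keys <- vapply(kv, `[`, "", 2)
  vals <- as.numeric(vapply(kv, `[`, "", 3))
  uctParams(a0 = vals[keys == "a0"], a1 = vals[keys == "a1"],
            b0 = vals[keys == "b0"], b1 = vals[keys == "b1"])
}

#' Apply the temperature-dependent universal correction (UCT)
#'
#' Corrects the summed energy and entropy density maps linearly in the
#' local partial-molar-volume map:
#' \deqn{\Delta E^{UCT}(r) = \sum_g \Delta E_g(r) - a(v(r) - \delta_T v(r))
#'       - T a_1 v(r)}
#' \deqn{-T\Delta S^{UCT}(r) = \sum_g -T\Delta S_g(r) + a_1 T v(r)
#'       + a\,\delta_T v(r)}
#' with a = a1*T + a0.  The constants b0 and b1*T, and the contribution of
#' the constant offset in v, carry no spatial structure and are added to
#' the corrected totals only.  The corrected decomposition still satisfies
#' dmu = dE + (-T dS) pointwise and in totals.
#'
#' @param maps a \linkS4class{ThermoMaps} with pmv derivatives available.
#' @param params an \linkS4class{UctParams}.
#' @param temperature temperature (K); default from the maps' solve is not
#'   stored, so pass the model temperature.
#' @return the ThermoMaps with the \code{uct} slot filled: elements
#'   \code{dE}, \code{minusTdS}, \code{dmu} (summed corrected maps),
#'   \code{totals}, \code{a}, \code{b}.
#' @export
uctCorrect <- function(maps, params, temperature) {
  if (!is.finite(maps@dTpmv))
    stop("maps lack the partial-molar-volume temperature derivative; ",
         "solve temperature derivatives first")
  ab <- uctCoefficients(params, temperature)
  a <- ab[["a"]]; b <- ab[["b"]]
  sumMaps <- function(lst) Reduce(`+`, lst)
  dEsum <- sumMaps(maps@dE)
  mTdSsum <- sumMaps(maps@minusTdS)
  vMap <- maps@pmvMap; dTvMap <- maps@dTpmvMap
  dEc <- dEsum - a * (vMap - dTvMap) - temperature * params@a1 * vMap
  mTdSc <- mTdSsum + params@a1 * temperature * vMap + a * dTvMap
  dmuc <- dEc + mTdSc
  vol <- maps@spacing^3
  v <- maps@pmv; dTv <- maps@dTpmv
  totals <- data.frame(
    dE = sum(dEsum) * vol - a * (v - dTv) - temperature * params@a1 * v +
      params@b0,
    minusTdS = sum(mTdSsum) * vol + params@a1 * temperature * v + a * dTv +
      params@b1 * temperature,
    stringsAsFactors = FALSE)
  totals$dmu <- totals$dE + totals$minusTdS
  maps@uct <- list(dE = dEc, minusTdS = mTdSc, dmu = dmuc,
                   totals = totals, a = a, b = b, params = params)
  maps
}
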