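# Project-wide unit conventions: Angstrom, kcal/mol, Kelvin, elementary
# charge.  beta = 1/(kB*T).
.kBoltzmann <- 0.0019872041   # kcal/mol/K
.kCoulomb <- 332.0637         # kcal*Angstrom/mol/e^2
.avogadroPerLiterToA3 <- 6.02214076e-4  # mol/L -> molecules/Angstrom^3

#' Boltzmann and Coulomb constants used throughout
#'
#' @return named numeric vector with elements \code{kB} (kcal/mol/K) and
#'   \code{coulomb} (kcal*Angstrom/mol/e^2).
#' @export
physicalConstants <- function() {
  c(kB = .kBoltzmann, coulomb = .kCoulomb)
}

#' Build the rigid three-site water model with a hydrogen LJ core
#'
#' Constructs the built-in rigid water: TIP3P geometry (L_OH = 0.9572
#' Angstrom, H-O-H angle 104.52 degrees), TIP3P charges and oxygen
#' Lennard-Jones parameters, plus a small LJ core on the hydrogens, which
#' site-site integral-equation theory needs to keep water hydrogens from
#' collapsing onto neighbouring oxygens.  The hydrogen LJ diameter is tied to
#' the geometry, sigma_H = sigma_O - 2*L_OH = 1.2363 Angstrom, which places
#' the hydrogen core surface at the hydrogen-bonding contact distance.  The
#' hydrogen well depth is not fixed by that argument and is exposed as an
#' argument.
#'
#' @param temperature temperature in K.
#' @param density molecular density in mol/L.
#' @param dielectric dielectric constant imposed through the DRISM bridge.
#' @param sigmaO,epsilonO oxygen LJ diameter (Angstrom) and well depth
#'   (kcal/mol).
#' @param epsilonH hydrogen LJ well depth (kcal/mol); implementer-chosen
#'   default 0.0152.
#' @param chargeO oxygen partial charge (e); hydrogens carry -chargeO/2.
#' @return a \linkS4class{SolventModel}.
#' @examples
#' w <- buildCTIP3P()
#' solventSites(w)$sigma[2]        # 1.2363
#' @export
buildCTIP3P <- function(temperature = 298, density = 55.345,
                        dielectric = 78.497,
                        sigmaO = 3.1507, epsilonO = 0.1521,
                        epsilonH = 0.0152, chargeO = -0.834) {
  lOH <- 0.9572
  angle <- 104.52 * pi / 180
  sigmaH <- sigmaO - 2 * lOH
  rhoM <- density * .avogadroPerLiterToA3
  sites <- data.frame(
    name = c("O", "H"),
    multiplicity = c(1L, 2L),
    charge = c(chargeO, -chargeO / 2),
    sigma = c(sigmaO, sigmaH),
    epsilon = c(epsilonO, epsilonH),
    stringsAsFactors = FALSE
  )
  # molecular frame: O at origin, dipole along +z
  zH <- lOH * cos(angle / 2)
  xH <- lOH * sin(angle / 2)
  pos <- rbind(O = c(0, 0, 0),
               H = c(xH, 0, zH),
               H = c(-xH, 0, zH))
  colnames(pos) <- c("x", "y", "z")
  dmat <- as.matrix(stats::dist(pos))
  dimnames(dmat) <- list(rownames(pos), rownames(pos))
  new("SolventModel",
      sites = sites,
      siteDensities = stats::setNames(sites$multiplicity * rhoM, sites$name),
      molecularDensity = rhoM,
      temperature = temperature,
      targetDielectric = dielectric,
      positions = pos,
      positionType = c(1L, 2L, 2L),
      distanceMatrix = dmat,
      kB = .kBoltzmann,
      coulomb = .kCoulomb)
}

#' Molecular dipole moment of a rigid solvent model
#'
#' @param model a SolventModel.
#' @return dipole moment magnitude in e*Angstrom.
#' @export
solventDipole <- function(model) {
  q <- model@sites$charge[model@positionType]
  sqrt(sum(colSums(q * model@positions)^2))
}

.beta <- function(model, temperature = model@temperature) {
  1 / (model@kB * temperature)
}

#' Intramolecular correlation functions omega_ag(k)
#'
#' For a rigid molecule the intramolecular pair correlation between site
#' types a and g is a sum of delta shells over the positions of g as seen
#' from one position of a: in reciprocal space
#' omega_ag(k) = delta_ag + sum over non-self positions of sin(kL)/(kL).
#' For water, omega_OH(k) = 2 j0(k L_OH) and omega_HH(k) = 1 + j0(k L_HH),
#' so omega_ag(0) equals the multiplicity M_g.
#'
#' @param model a SolventModel.
#' @param k numeric vector of non-negative wavenumbers (Angstrom^-1).
#' @return array [length(k), nsite, nsite] with dimnames of site names.
#'   Note omega_ag != omega_ga when multiplicities differ (the sum runs over
#'   positions of the second index).
#' @export
intramolecularOmega <- function(model, k) {
  if (any(k < 0)) stop("k must be non-negative")
  ns <- nrow(model@sites)
  nm <- model@sites$name
  w <- array(0, c(length(k), ns, ns), dimnames = list(NULL, nm, nm))
  ptype <- model@positionType
  for (a in seq_len(ns)) {
    # fixed representative position of type a
    ia <- which(ptype == a)[1]
    for (g in seq_len(ns)) {
      jg <- which(ptype == g)
      acc <- numeric(length(k))
      for (j in jg) {
        if (j == ia) acc <- acc + 1
        else acc <- acc + .sinc(k * model@distanceMatrix[ia, j])
      }
      w[, a, g] <- acc
    }
  }
  w
}

# sin(x)/x with the continuous limit at 0
.sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Write a solvent model to a key-value config file
#'
#' Plain-text serialization (names, charges, sigma, epsilon, geometry,
#' density, temperature, dielectric) that \code{readSolventConfig} restores.
#'
#' @param model a SolventModel.
#' @param path output file.
#' @export
writeSolventConfig <- function(model, path) {
  s <- model@sites
  lines <- c(
    "# solvmap solvent model",
    sprintf("temperature = %.10g", model@temperature),
    sprintf("density_M = %.10g", model@molecularDensity / .avogadroPerLiterToA3),
    sprintf("dielectric = %.10g", model@targetDielectric),
    sprintf("nsites = %d", nrow(s))
  )
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "site = %s %d %.10g %.10g %.10g",
      s$name[i], s$multiplicity[i], s$charge[i], s$sigma[i], s$epsilon[i]))
  }
  for (i in seq_len(nrow(model@positions))) {
    lines <- c(lines, sprintf(
      "position = %s %.10g %.10g %.10g", rownames(model@positions)[i],
      model@positions[i, 1], model@positions[i, 2], model@positions[i, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a solvent model from a key-value config file
#'
#' @param path file written by \code{writeSolventConfig}.
#' @return a \linkS4class{SolventModel}.
#' @export
readSolventConfig <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  kv <- regmatches(ln, regexec("^\\s*([a-zA-Z_]+)\\s*=\\s*(.*)$", ln))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  getScalar <- function(key) as.numeric(vals[keys == key][1])
  siteLines <- strsplit(trimws(vals[keys == "site"]), "\\s+")
  sites <- do.call(rbind, lapply(siteLines, function(x) {
    data.frame(name = x[1], multiplicity = as.integer(x[2]),
               charge = as.numeric(x[3]), sigma = as.numeric(x[4]),
               epsilon = as.numeric(x[5]), stringsAsFactors = FALSE)
  }))
  posLines <- strsplit(trimws(vals[keys == "position"]), "\\s+")
  pos <- do.call(rbind, lapply(posLines, function(x) as.numeric(x[2:4])))
  rownames(pos) <- vapply(posLines, `[`, "", 1)
  colnames(pos) <- c("x", "y", "z")
  ptype <- match(rownames(pos), sites$name)
  rhoM <- getScalar("density_M") * .avogadroPerLiterToA3
  dmat <- as.matrix(stats::dist(pos))
  dimnames(dmat) <- list(rownames(pos), rownames(pos))
  new("SolventModel",
      sites = sites,
      siteDensities = stats::setNames(sites$multiplicity * rhoM, sites$name),
      molecularDensity = rhoM,
      temperature = getScalar("temperature"),
      targetDielectric = getScalar("dielectric"),
      positions = pos,
      positionType = as.integer(ptype),
      distanceMatrix = dmat,
      kB = .kBoltzmann,
      coulomb = .kCoulomb)
}
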