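# Synthetic fixtures: toy solutes, rigid-water frame sets with known
# statistical structure, and analytic grid fields.  Every generator is a
# pure function of its arguments and seed.

#' Toy solutes for testing and benchmarking
#'
#' \code{lj_sphere}: one neutral Lennard-Jones atom; \code{point_ion}: one
#' charged LJ atom; \code{water_as_solute}: one rigid water (the model's
#' own geometry and parameters) treated as a 3-atom solute.
#'
#' @param kind "lj_sphere", "point_ion" or "water_as_solute".
#' @param sigma,epsilon LJ parameters of the single atom kinds.
#' @param charge ion charge (point_ion).
#' @param center position of the solute (Angstrom).
#' @param model solvent model supplying geometry/parameters for
#'   water_as_solute.
#' @return a \linkS4class{SoluteStructure}.
#' @export
makeToySolute <- function(kind = c("lj_sphere", "point_ion",
                                   "water_as_solute"),
                          sigma = 3.15, epsilon = 0.15, charge = 1,
                          center = c(0, 0, 0), model = buildCTIP3P()) {
  kind <- match.arg(kind)
  if (kind == "lj_sphere") {
    return(soluteStructure(data.frame(
      name = "LJ", x = center[1], y = center[2], z = center[3],
      charge = 0, sigma = sigma, epsilon = epsilon)))
  }
  if (kind == "point_ion") {
    return(soluteStructure(data.frame(
      name = "ION", x = center[1], y = center[2], z = center[3],
      charge = charge, sigma = sigma, epsilon = epsilon)))
  }
  s <- model@sites
  ty <- model@positionType
  pos <- sweep(model@positions, 2, center, "+")
  soluteStructure(data.frame(
    name = rownames(model@positions),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = s$charge[ty], sigma = s$sigma[ty], epsilon = s$epsilon[ty]))
}

# --- quaternion helpers ---------------------------------------------------

#' Uniform random unit quaternions
#'
#' Shoemake's 3-uniform-variate construction: exactly uniform on S^3, hence
#' uniform over SO(3) under the double cover.
#'
#' @param n number of quaternions.
#' @return n x 4 matrix (w, x, y, z rows normalised).
#' @export
quatUniform <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

#' Concentrated random rotations about a reference
#'
#' Samples rotations whose angle theta relative to the reference follows
#' p(theta) proportional to exp(kappa cos(theta)) (1 - cos(theta)) on
#' [0, pi] (the Haar angle measure times a von Mises-Fisher-like
#' concentration), with a uniform rotation axis; sampled by numeric
#' inverse-CDF so the density is known exactly for quadrature oracles.
#'
#' @param n number of rotations.
#' @param kappa concentration (0 = uniform over SO(3)).
#' @param reference unit quaternion (length 4) of the central rotation.
#' @return n x 4 matrix of unit quaternions.
#' @export
quatConcentrated <- function(n, kappa, reference = c(1, 0, 0, 0)) {
  if (kappa <= 0) return(quatUniform(n))
  thGrid <- seq(0, pi, length.out = 4096)
  dens <- exp(kappa * (cos(thGrid) - 1)) * (1 - cos(thGrid))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  theta <- stats::approx(cdf, thGrid, xout = stats::runif(n),
                         yleft = 0, yright = pi, ties = "ordered")$y
  # uniform axes
  z <- stats::runif(n, -1, 1); phi <- stats::runif(n, 0, 2 * pi)
  sz <- sqrt(1 - z^2)
  ax <- cbind(sz * cos(phi), sz * sin(phi), z)
  dq <- cbind(cos(theta / 2), sin(theta / 2) * ax)
  t(apply(dq, 1, function(d) quatMultiply(reference, d)))
}

#' Quaternion product r = a * b
#' @param a,b unit quaternions (w, x, y, z).
#' @export
quatMultiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix.
#' @export
quatToRotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Quaternion of the rigid-body frame of one water
#'
#' Builds the rotation taking the model's canonical water frame (dipole
#' along +z, H-H axis along x) to the lab frame of an (O, H1, H2) triple.
#'
#' @param O,H1,H2 numeric(3) site positions.
#' @return unit quaternion (w, x, y, z) with w >= 0.
#' @export
waterQuaternion <- function(O, H1, H2) {
  b1 <- H1 - O; b2 <- H2 - O
  zax <- b1 + b2; zax <- zax / sqrt(sum(zax^2))
  xax <- b1 - b2; xax <- xax - sum(xax * zax) * zax
  xax <- xax / sqrt(sum(xax^2))
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  R <- cbind(xax, yax, zax)
  # rotation-matrix -> quaternion (Shepperd)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# site positions of waters with O positions `o` (n x 3) and orientation
# quaternions `q` (n x 4), rigid geometry from the model
.buildWaters <- function(o, q, model) {
  n <- nrow(o)
  hpos <- which(model@positionType == 2L)
  p1 <- model@positions[hpos[1], ]
  p2 <- model@positions[hpos[2], ]
  H1 <- H2 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- quatToRotation(q[i, ])
    H1[i, ] <- o[i, ] + as.vector(R %*% p1)
    H2[i, ] <- o[i, ] + as.vector(R %*% p2)
  }
  list(O = o, H1 = H1, H2 = H2)
}

#' Generate synthetic rigid-water frame sets
#'
#' \code{ideal_gas}: oxygen positions uniform in the region, orientations
#' uniform over SO(3) -- no correlations, the null model for GIST
#' estimators.  \code{localized}: oxygens Gaussian about \code{center}
#' (s.d. \code{sigmaPos}), orientations concentrated about
#' \code{referenceQuat} with concentration \code{kappa}.
#' \code{half_box}: oxygens uniform over the lower-x half of the region,
#' orientations uniform.  Water geometry is rigid and exact.
#'
#' @param kind "ideal_gas", "localized" or "half_box".
#' @param nFrames,nWaters frame and per-frame water counts.
#' @param region numeric(6) xmin,xmax,ymin,ymax,zmin,zmax (Angstrom).
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @param model solvent model (rigid geometry source).
#' @param sigmaPos,center,kappa,referenceQuat localized-kind parameters.
#' @return a \linkS4class{WaterFrameSet}.
#' @export
makeFrames <- function(kind = c("ideal_gas", "localized", "half_box"),
                       nFrames, nWaters, region, seed = 1,
                       model = buildCTIP3P(),
                       sigmaPos = 0.3, center = NULL, kappa = 10,
                       referenceQuat = c(1, 0, 0, 0)) {
  kind <- match.arg(kind)
  if (nFrames < 1 || nWaters < 1) stop("need at least one frame and water")
  region <- as.numeric(region)
  wid <- region[c(2, 4, 6)] - region[c(1, 3, 5)]
  if (any(wid <= 0)) stop("degenerate region")
  if (is.null(center)) center <- region[c(1, 3, 5)] + wid / 2
  set.seed(seed)
  frames <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    o <- switch(kind,
      ideal_gas = cbind(stats::runif(nWaters, region[1], region[2]),
                        stats::runif(nWaters, region[3], region[4]),
                        stats::runif(nWaters, region[5], region[6])),
      half_box = cbind(stats::runif(nWaters, region[1],
                                    region[1] + wid[1] / 2),
                       stats::runif(nWaters, region[3], region[4]),
                       stats::runif(nWaters, region[5], region[6])),
      localized = cbind(stats::rnorm(nWaters, center[1], sigmaPos),
                        stats::rnorm(nWaters, center[2], sigmaPos),
                        stats::rnorm(nWaters, center[3], sigmaPos)))
    q <- if (kind == "localized") {
      quatConcentrated(nWaters, kappa, referenceQuat)
    } else quatUniform(nWaters)
    frames[[f]] <- .buildWaters(o, q, model)
  }
  new("WaterFrameSet", frames = frames, region = region)
}

#' Analytic 3D grid fixtures
#'
#' \code{impulse}: a single non-zero voxel; \code{uniform}: a constant
#' field; \code{radial_gaussian}: value * exp(-|r-center|^2/(2 width^2))
#' sampled at voxel centers.
#'
#' @param kind "impulse", "uniform" or "radial_gaussian".
#' @param geom geometry list (origin, spacing, shape).
#' @param value field amplitude.
#' @param index voxel index of the impulse (defaults to the center voxel).
#' @param center,width radial-gaussian parameters.
#' @return a \linkS4class{Grid3D}.
#' @export
makeGridFixture <- function(kind = c("impulse", "uniform",
                                     "radial_gaussian"),
                            geom, value = 1, index = NULL,
                            center = NULL, width = 1) {
  kind <- match.arg(kind)
  v <- array(0, geom$shape)
  if (kind == "uniform") {
    v[] <- value
  } else if (kind == "impulse") {
    if (is.null(index)) index <- (geom$shape + 1) %/% 2
    v[index[1], index[2], index[3]] <- value
  } else {
    cc <- .geomCenters(geom)
    if (is.null(center))
      center <- geom$origin + geom$spacing * (geom$shape - 1) / 2
    r2 <- outer(outer((cc$x - center[1])^2, (cc$y - center[2])^2, "+"),
                (cc$z - center[3])^2, "+")
    v <- value * exp(-r2 / (2 * width^2))
  }
  grid3D(geom$origin, geom$spacing, v)
}

#' Write / read a water frame set as extended-XYZ-like text
#'
#' One block per frame: a count line, a comment line, then one line per
#' water with the nine O/H1/H2 coordinates.
#'
#' @param frames a WaterFrameSet; @param path file path.
#' @export
writeFrames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# region %s",
                     paste(sprintf("%.6g", frames@region), collapse = " ")),
             con)
  for (f in frames@frames) {
    n <- nrow(f$O)
    writeLines(sprintf("%d", n), con)
    writeLines("# O H1 H2 xyz", con)
    m <- cbind(f$O, f$H1, f$H2)
    writeLines(apply(m, 1, function(r)
      paste(sprintf("%.8f", r), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname writeFrames
#' @export
readFrames <- function(path) {
  ln <- readLines(path)
  region <- as.numeric(strsplit(sub("^# region ", "", ln[1]), "\\s+")[[1]])
  i <- 2
  frames <- list()
  while (i <= length(ln)) {
    n <- as.integer(ln[i]); i <- i + 2
    m <- do.call(rbind, lapply(ln[i:(i + n - 1)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    frames[[length(frames) + 1]] <-
      list(O = m[, 1:3, drop = FALSE], H1 = m[, 4:6, drop = FALSE],
           H2 = m[, 7:9, drop = FALSE])
    i <- i + n
  }
  new("WaterFrameSet", frames = frames, region = region)
}
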