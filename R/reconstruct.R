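# Molecular reconstruction: collapse hydrogen-site thermodynamic densities
# onto the oxygen distribution through the intramolecular shell kernel,
# A(r) ~ A_O(r) + g_O(r) * (omega_OH(r) * A_H(r)), with excluded-volume
# masking.

#' Convolve a field with an intramolecular shell kernel
#'
#' The kernel is the normalised delta shell of radius L with total mass M
#' (the site multiplicity): convolution spreads each voxel's content over a
#' sphere of radius L and multiplies the total by exactly M.  Evaluated
#' analytically in reciprocal space as M * sin(kL)/(kL), which avoids the
#' anisotropy of a rasterised real-space shell.
#'
#' @param field a \linkS4class{Grid3D} or 3D array.
#' @param distance shell radius L (Angstrom).
#' @param multiplicity kernel mass M.
#' @param spacing voxel edge, required when \code{field} is a plain array.
#' @return same type as \code{field}.
#' @export
shellConvolve <- function(field, distance, multiplicity = 1,
                          spacing = NULL) {
  isGrid <- is(field, "Grid3D")
  v <- if (isGrid) field@values else field
  h <- if (isGrid) field@spacing else spacing
  if (is.null(h)) stop("spacing required for plain arrays")
  d <- dim(v)
  if (distance >= min(d * h) / 2)
    stop("kernel distance ", distance, " A too large for grid extent")
  kern <- multiplicity * .sinc(.kLattice(d, h)$kmag * distance)
  out <- Re(stats::fft(stats::fft(v) * kern, inverse = TRUE)) / length(v)
  if (isGrid) grid3D(field@origin, h, out) else out
}

#' Excluded-volume mask from the oxygen distribution
#'
#' TRUE where g_O falls below \code{threshold} (default 1e-3): the solute
#' core where the reconstruction sets all contributions to zero.
#'
#' @param gO oxygen pair-distribution values (Grid3D or array).
#' @param threshold occupancy threshold.
#' @return logical array.
#' @export
excludedVolumeMask <- function(gO, threshold = 1e-3) {
  v <- if (is(gO, "Grid3D")) gO@values else gO
  if (any(v < 0)) stop("g_O must be non-negative")
  v < threshold
}

#' Molecular reconstruction of a site-decomposed thermodynamic map
#'
#' A(r) = A_O(r) + g_O(r) * (omega_OH * A_H)(r), with both terms zeroed
#' inside the excluded volume (g_O < threshold).  The kernel distance and
#' multiplicity default to the O-H bond length and hydrogen multiplicity of
#' \code{model}, but any central site can be supplied explicitly.
#'
#' @param AO central-site map (Grid3D or array).
#' @param AH satellite-site map on the same geometry.
#' @param gO central-site pair distribution on the same geometry.
#' @param model a SolventModel supplying L_OH and M_H (optional if
#'   \code{distance}/\code{multiplicity} given).
#' @param distance,multiplicity shell kernel parameters.
#' @param threshold excluded-volume occupancy threshold.
#' @param spacing voxel edge for plain arrays.
#' @return reconstructed map, same type as \code{AO}.
#' @export
reconstructMolecular <- function(AO, AH, gO, model = NULL,
                                 distance = NULL, multiplicity = NULL,
                                 threshold = 1e-3, spacing = NULL) {
  if (is.null(distance)) {
    if (is.null(model)) stop("give either model or distance/multiplicity")
    hpos <- which(model@positionType == 2L)[1]
    distance <- model@distanceMatrix[1, hpos]
    multiplicity <- model@sites$multiplicity[2]
  }
  isGrid <- is(AO, "Grid3D")
  vO <- if (isGrid) AO@values else AO
  vH <- if (is(AH, "Grid3D")) AH@values else AH
  vG <- if (is(gO, "Grid3D")) gO@values else gO
  h <- if (isGrid) AO@spacing else spacing
  if (!identical(dim(vO), dim(vH)) || !identical(dim(vO), dim(vG)))
    stop("grid geometry mismatch between AO, AH and gO")
  conv <- shellConvolve(vH, distance, multiplicity, spacing = h)
  out <- vO + vG * conv
  out[excludedVolumeMask(vG, threshold)] <- 0
  if (isGrid) grid3D(AO@origin, h, out) else out
}
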