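#' Voxelwise comparison of two maps on a shared lattice
#'
#' Truncates both grids to their exact overlap window (index slicing after
#' lattice alignment, never interpolation) and reports voxelwise agreement
#' statistics and region integrals.
#'
#' @param g1,g2 \linkS4class{Grid3D} objects with equal spacing and
#'   lattice-aligned origins.
#' @param mask optional logical array on the overlap window restricting the
#'   comparison (e.g. outside an excluded volume).
#' @return list with \code{n}, \code{correlation}, \code{rmsd},
#'   \code{integral1}, \code{integral2}, \code{maxAbsDiff}.
#' @export
compareMaps <- function(g1, g2, mask = NULL) {
  if (abs(g1@spacing - g2@spacing) > 1e-9)
    stop("maps must share a voxel spacing")
  off <- (g2@origin - g1@origin) / g1@spacing
  if (max(abs(off - round(off))) > 1e-6)
    stop("maps are not lattice-aligned")
  d1 <- dim(g1@values); d2 <- dim(g2@values)
  lo <- pmax(g1@origin, g2@origin)
  hi <- pmin(g1@origin + g1@spacing * (d1 - 1),
             g2@origin + g2@spacing * (d2 - 1))
  if (any(hi < lo)) stop("maps do not overlap")
  shape <- as.integer(round((hi - lo) / g1@spacing)) + 1L
  win <- list(origin = lo, spacing = g1@spacing, shape = shape)
  v1 <- truncateGrid(g1, win)@values
  v2 <- truncateGrid(g2, win)@values
  if (!is.null(mask)) { v1 <- v1[mask]; v2 <- v2[mask] }
  dv <- v1 - v2
  list(n = length(v1),
       correlation = if (stats::sd(v1) > 0 && stats::sd(v2) > 0)
         stats::cor(as.vector(v1), as.vector(v2)) else NA_real_,
       rmsd = sqrt(mean(dv^2)),
       integral1 = sum(v1) * g1@spacing^3,
       integral2 = sum(v2) * g1@spacing^3,
       maxAbsDiff = max(abs(dv)))
}
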