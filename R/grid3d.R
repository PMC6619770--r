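#' Construct a 3D grid of cubic voxels
#'
#' @param origin coordinates of the first voxel center (Angstrom).
#' @param spacing voxel edge length (Angstrom).
#' @param values 3D array, or a dim vector to create a zero grid.
#' @return a \linkS4class{Grid3D}.
#' @export
grid3D <- function(origin, spacing, values) {
  if (is.null(dim(values))) values <- array(0, as.integer(values))
  new("Grid3D", origin = as.numeric(origin), spacing = spacing,
      values = values)
}

#' Voxel-center coordinates along each axis
#' @param grid a Grid3D (or anything with origin/spacing/dim).
#' @return list of numeric vectors x, y, z.
#' @export
voxelCenters <- function(grid) {
  d <- dim(grid@values)
  o <- grid@origin; h <- grid@spacing
  list(x = o[1] + h * (seq_len(d[1]) - 1),
       y = o[2] + h * (seq_len(d[2]) - 1),
       z = o[3] + h * (seq_len(d[3]) - 1))
}

#' Volume integral of a voxel field (midpoint rule)
#'
#' @param x a Grid3D or a plain 3D array.
#' @param spacing required when \code{x} is a plain array.
#' @return sum(values) * voxel volume.
#' @export
gridIntegral <- function(x, spacing = NULL) {
  if (is(x, "Grid3D")) return(sum(x@values) * x@spacing^3)
  sum(x) * spacing^3
}

#' Align a grid so voxel centers sit on a common lattice
#'
#' Chooses the origin of a \code{shape}-sized grid so that every voxel
#' center lies on the lattice \{n * spacing\} of the reference frame, with
#' the grid centered as close as possible to \code{center}.  Two grids
#' aligned this way at equal spacing have exactly coincident voxel centers
#' on their overlap, so maps from different producers can be compared
#' voxel-by-voxel (and a larger map can be truncated to a smaller one by
#' pure index slicing).  Rounding of the requested center to the lattice is
#' round-half-down (ties toward -Inf).
#'
#' @param center numeric(3), requested grid center (Angstrom).
#' @param spacing voxel edge (Angstrom).
#' @param shape integer(3), voxel counts per axis.
#' @return list with \code{origin}, \code{spacing}, \code{shape}.
#' @export
alignGrid <- function(center, spacing, shape) {
  if (spacing <= 0) stop("spacing must be > 0")
  shape <- as.integer(shape)
  # lattice index of the center voxel (or of the lower of the two middle
  # voxels for even counts)
  halfdown <- function(x) ceiling(x - 0.5)
  ic <- halfdown(center / spacing)
  origin <- (ic - (shape - 1) / 2) * spacing
  # for odd shapes the origin is itself on the lattice; for even shapes it
  # lands on a half-lattice point -- snap (half-down again) so voxel
  # centers stay on the lattice
  origin <- halfdown(origin / spacing) * spacing
  list(origin = origin, spacing = spacing, shape = shape)
}

#' Grid shape covering a requested physical extent
#'
#' @param extent numeric(3) lengths in Angstrom.
#' @param spacing voxel edge.
#' @return integer(3) voxel counts (extent/spacing rounded to nearest).
#' @export
shapeForExtent <- function(extent, spacing) {
  as.integer(round(extent / spacing))
}

#' Truncate a grid to a comparison window
#'
#' Exact voxel-index slicing of \code{grid} onto the geometry of
#' \code{target} (same spacing, lattice-aligned origins); no interpolation.
#'
#' @param grid a Grid3D to cut.
#' @param target a Grid3D (or list with origin/spacing/shape) defining the
#'   window.
#' @return a Grid3D with the target geometry.
#' @export
truncateGrid <- function(grid, target) {
  tOrigin <- if (is(target, "Grid3D")) target@origin else target$origin
  tSpacing <- if (is(target, "Grid3D")) target@spacing else target$spacing
  tShape <- if (is(target, "Grid3D")) dim(target@values) else target$shape
  if (abs(tSpacing - grid@spacing) > 1e-9)
    stop("truncation requires equal spacing")
  off <- (tOrigin - grid@origin) / grid@spacing
  if (max(abs(off - round(off))) > 1e-6)
    stop("grids are not lattice-aligned")
  off <- as.integer(round(off))
  d <- dim(grid@values)
  if (any(off < 0) || any(off + tShape > d))
    stop("target window not contained in grid")
  vals <- grid@values[off[1] + seq_len(tShape[1]),
                      off[2] + seq_len(tShape[2]),
                      off[3] + seq_len(tShape[3]), drop = FALSE]
  grid3D(tOrigin, tSpacing, vals)
}

#' Spherically averaged radial profile of a 3D field
#'
#' Bins voxel values by distance from \code{center} and returns the mean,
#' spread, and count per shell.  Used to compare grid solutions of
#' spherically symmetric problems against references.
#'
#' @param grid a Grid3D.
#' @param center numeric(3); defaults to the grid's geometric center.
#' @param dr shell width, defaults to the grid spacing.
#' @param rmax maximum radius (default: largest inscribed sphere).
#' @return data.frame with r, mean, sd, n.
#' @export
radialAverage <- function(grid, center = NULL, dr = grid@spacing,
                          rmax = NULL) {
  d <- dim(grid@values)
  cc <- voxelCenters(grid)
  if (is.null(center))
    center <- grid@origin + grid@spacing * (d - 1) / 2
  if (is.null(rmax))
    rmax <- min((d - 1) * grid@spacing) / 2
  dx2 <- (cc$x - center[1])^2
  dy2 <- (cc$y - center[2])^2
  dz2 <- (cc$z - center[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  keep <- r <= rmax
  bin <- floor(r[keep] / dr) + 1L
  v <- grid@values[keep]
  mean_ <- tapply(v, bin, mean)
  sd_ <- tapply(v, bin, stats::sd)
  n_ <- tapply(v, bin, length)
  idx <- as.integer(names(mean_))
  data.frame(r = (idx - 0.5) * dr, mean = as.numeric(mean_),
             sd = as.numeric(sd_), n = as.integer(n_))
}

#' Periodically translate a 3D field by whole voxels
#'
#' @param values a 3D array.
#' @param shift integer(3) voxel shift (value at index i moves to i+shift,
#'   wrapping around).
#' @return shifted array.
#' @export
translateGrid <- function(values, shift) {
  d <- dim(values)
  idx <- lapply(1:3, function(a) {
    s <- ((seq_len(d[a]) - 1 - shift[a]) %% d[a]) + 1L
    s
  })
  values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# |k| magnitudes and component frequencies of the 3D FFT lattice for an
# n1 x n2 x n3 grid with voxel edge h (angular frequencies, Angstrom^-1).
.kLattice <- function(d, h) {
  freq <- function(n) {
    f <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * h)
    2 * pi * f
  }
  kx <- freq(d[1]); ky <- freq(d[2]); kz <- freq(d[3])
  k2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  list(kx = kx, ky = ky, kz = kz, kmag = sqrt(k2))
}

# 3D convolution of two sampled fields via FFT (periodic),
# result = conv(f, g) * voxelVolume.  Used by tests as the oracle partner
# of the k-space pipeline.
.fftConvolve <- function(f, g, spacing) {
  Re(stats::fft(stats::fft(f) * stats::fft(g), inverse = TRUE)) /
    length(f) * spacing^3
}

# Direct-space periodic discrete convolution (O(N^2); tiny grids only).
.directConvolve <- function(f, g, spacing) {
  d <- dim(f)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (cc in seq_len(d[3])) {
      ii <- ((i - a) %% d[1]) + 1L
      jj <- ((j - b) %% d[2]) + 1L
      kk <- ((k - cc) %% d[3]) + 1L
      acc <- acc + f[a, b, cc] * g[ii, jj, kk]
    }
    out[i, j, k] <- acc
  }
  out * spacing^3
}
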