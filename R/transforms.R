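#' Construct a radial grid
#'
#' @param n number of points (a power of two keeps the underlying FFT fast,
#'   but any length is accepted).
#' @param dr spacing in Angstrom.
#' @return a \linkS4class{RadialGrid}.
#' @export
radialGrid <- function(n, dr) new("RadialGrid", n = as.integer(n), dr = dr)

#' Real and reciprocal abscissae of a radial grid
#'
#' r_i = i*dr (i = 1..n) and k_j = j*dk with dk = pi/((n+1)*dr), the pairing
#' under which the type-I discrete sine transform is its own inverse.
#'
#' @param grid a RadialGrid.
#' @return list with numeric vectors \code{r} and \code{k} and spacings
#'   \code{dr}, \code{dk}.
#' @export
radialAbscissae <- function(grid) {
  n <- grid@n
  dk <- pi / ((n + 1) * grid@dr)
  list(r = seq_len(n) * grid@dr, k = seq_len(n) * dk,
       dr = grid@dr, dk = dk)
}

# Orthogonal DST-I via a length-2(n+1) complex FFT.
# y_j = sum_{i=1}^n x_i sin(pi i j/(n+1)).  Applying it twice multiplies by
# (n+1)/2.
.dst1 <- function(x) {
  n <- length(x)
  ext <- c(0, x, 0, -rev(x))
  -Im(stats::fft(ext))[2:(n + 1)] / 2
}

#' Radial Fourier-Bessel (j0) transform pair on a RadialGrid
#'
#' Forward: fhat(k) = 4*pi/k * integral r f(r) sin(kr) dr;
#' inverse: f(r) = 1/(2*pi^2 r) * integral k fhat(k) sin(kr) dk.
#' Implemented with the orthogonal DST-I so that the round trip is exact to
#' machine precision.
#'
#' @param f values of f at r_i (forward) or of fhat at k_j (inverse).
#' @param grid a RadialGrid.
#' @return the transformed values on the paired abscissae.
#' @export
radialFT <- function(f, grid) {
  ax <- radialAbscissae(grid)
  4 * pi * ax$dr * .dst1(ax$r * f) / ax$k
}

#' @rdname radialFT
#' @export
radialIFT <- function(f, grid) {
  ax <- radialAbscissae(grid)
  ax$dk * .dst1(ax$k * f) / (2 * pi^2 * ax$r)
}
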