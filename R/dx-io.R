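# OpenDX regular-grid reader/writer.  The dialect is the one volumetric
# tools exchange: "object 1" gridpositions with origin and three axis
# deltas, "object 2" gridconnections, "object 3" the data array, values in
# z-fastest order, three per line.

#' Write a 3D grid as an OpenDX file
#'
#' @param grid a \linkS4class{Grid3D}.
#' @param path output file.
#' @param comment optional header comment lines (written with a leading #).
#' @export
writeDX <- function(grid, path, comment = NULL) {
  d <- dim(grid@values)
  h <- grid@spacing
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(sprintf(
    "object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %.7g %.7g %.7g",
                     grid@origin[1], grid@origin[2], grid@origin[3]), con)
  writeLines(sprintf("delta %.7g 0 0", h), con)
  writeLines(sprintf("delta 0 %.7g 0", h), con)
  writeLines(sprintf("delta 0 0 %.7g", h), con)
  writeLines(sprintf(
    "object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(d)), con)
  # OpenDX stores z fastest: permute so that R's column-major flattening
  # emits x slowest
  v <- aperm(grid@values, c(3, 2, 1))
  vals <- sprintf("%.8e", as.vector(v))
  n <- length(vals)
  full <- n %/% 3 * 3
  if (full > 0) {
    m <- matrix(vals[seq_len(full)], ncol = 3, byrow = TRUE)
    writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
  }
  if (full < n) writeLines(paste(vals[(full + 1):n], collapse = " "), con)
  writeLines("object \"regular positions regular connections\" class field",
             con)
  invisible(path)
}

#' Read an OpenDX regular-grid file
#'
#' Accepts the regular-grid dialect written by \code{writeDX} (and by the
#' common volumetric-map producers): axis-aligned deltas, cubic voxels,
#' z-fastest data ordering.
#'
#' @param path input file.
#' @return a \linkS4class{Grid3D}.
#' @export
readDX <- function(path) {
  ln <- readLines(path)
  strip <- grepl("^\\s*#", ln)
  lineNo <- which(!strip)
  ln <- ln[!strip]
  fail <- function(i, what) {
    stop("malformed DX file at line ", lineNo[i], ": ", what)
  }
  ig <- grep("class gridpositions", ln)[1]
  if (is.na(ig)) stop("malformed DX file: no gridpositions object")
  counts <- suppressWarnings(as.integer(
    utils::tail(strsplit(trimws(ln[ig]), "\\s+")[[1]], 3)))
  if (any(is.na(counts)) || any(counts < 1)) fail(ig, "bad counts")
  io <- grep("^\\s*origin", ln)[1]
  if (is.na(io)) stop("malformed DX file: no origin")
  origin <- suppressWarnings(as.numeric(
    strsplit(trimws(ln[io]), "\\s+")[[1]][2:4]))
  if (any(is.na(origin))) fail(io, "bad origin")
  id <- grep("^\\s*delta", ln)
  if (length(id) != 3) stop("malformed DX file: need 3 delta lines")
  deltas <- t(vapply(id, function(i) {
    suppressWarnings(as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]][2:4]))
  }, numeric(3)))
  diag3 <- c(deltas[1, 1], deltas[2, 2], deltas[3, 3])
  offdiag <- deltas - diag(diag3)
  if (max(abs(offdiag)) > 1e-9) stop("only axis-aligned grids are supported")
  if (max(abs(diff(diag3))) > 1e-7) stop("only cubic voxels are supported")
  ia <- grep("data follows", ln)[1]
  if (is.na(ia)) stop("malformed DX file: no data array")
  nitems <- suppressWarnings(as.integer(
    sub(".*items\\s+(\\d+)\\s+data.*", "\\1", ln[ia])))
  if (is.na(nitems)) fail(ia, "bad items count")
  if (nitems != prod(counts)) fail(ia, "items do not match counts")
  dataLines <- ln[(ia + 1):length(ln)]
  dataLines <- dataLines[!grepl("^\\s*(object|attribute|component|$)",
                                dataLines)]
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(dataLines), "\\s+"))))
  if (anyNA(vals)) stop("malformed DX file: non-numeric data value")
  if (length(vals) != nitems)
    stop("malformed DX file: expected ", nitems, " values, found ",
         length(vals))
  v <- aperm(array(vals, rev(counts)), c(3, 2, 1))
  grid3D(origin, diag3[1], v)
}
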