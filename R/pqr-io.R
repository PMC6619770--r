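#' Read a solute from a PQR file
#'
#' Whitespace-tolerant PQR dialect: ATOM/HETATM records with x, y, z,
#' charge, radius as the last five numeric fields.  The Lennard-Jones
#' diameter is derived from the radius by a configurable convention; the
#' default treats the PQR radius as the energy-minimum radius r_min of the
#' site, sigma = 2 * radius * 2^(-1/6).  Well depths are not carried by
#' PQR; they are taken from an optional per-atom-name parameter table, with
#' a single default otherwise.
#'
#' @param path PQR file.
#' @param sigmaFromRadius function mapping radius to sigma; default
#'   \code{function(r) 2 * r * 2^(-1/6)}.
#' @param epsilonTable optional named numeric: well depth (kcal/mol) per
#'   atom name.
#' @param epsilonDefault well depth for atoms not in the table.
#' @return a \linkS4class{SoluteStructure}.
#' @export
readPQR <- function(path, sigmaFromRadius = function(r) 2 * r * 2^(-1 / 6),
                    epsilonTable = NULL, epsilonDefault = 0.15) {
  ln <- readLines(path)
  recs <- grep("^(ATOM|HETATM)", ln, value = TRUE)
  if (length(recs) == 0) stop("no ATOM/HETATM records in ", path)
  rows <- lapply(seq_along(recs), function(i) {
    f <- strsplit(trimws(recs[i]), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(f))
    numeric_idx <- which(!is.na(nums))
    if (length(numeric_idx) < 5)
      stop("PQR record ", i, " lacks x y z charge radius fields")
    lastFive <- nums[utils::tail(numeric_idx, 5)]
    name <- if (length(f) >= 3) f[3] else paste0("A", i)
    data.frame(name = name, x = lastFive[1], y = lastFive[2],
               z = lastFive[3], charge = lastFive[4], radius = lastFive[5],
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  if (any(atoms$radius <= 0)) stop("non-positive radius in PQR")
  atoms$sigma <- sigmaFromRadius(atoms$radius)
  eps <- rep(epsilonDefault, nrow(atoms))
  if (!is.null(epsilonTable)) {
    hit <- match(atoms$name, names(epsilonTable))
    eps[!is.na(hit)] <- epsilonTable[hit[!is.na(hit)]]
  }
  atoms$epsilon <- eps
  new("SoluteStructure", atoms = atoms)
}

#' Construct a solute from an atom table
#'
#' @param atoms data.frame with x, y, z, charge, sigma, epsilon (and
#'   optionally name).
#' @return a \linkS4class{SoluteStructure}.
#' @export
soluteStructure <- function(atoms) {
  if (is.null(atoms$name)) atoms$name <- paste0("A", seq_len(nrow(atoms)))
  new("SoluteStructure", atoms = atoms)
}

#' Net charge of a solute
#' @param solute a SoluteStructure.
#' @export
netCharge <- function(solute) sum(solute@atoms$charge)
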