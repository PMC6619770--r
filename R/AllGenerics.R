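#' Site table of a solvent model
#' @param object a SolventModel
#' @export
setGeneric("solventSites", function(object) standardGeneric("solventSites"))

#' @rdname solventSites
setMethod("solventSites", "SolventModel", function(object) object@sites)

#' Temperature accessor
#' @param object an object carrying a temperature
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))

#' @rdname temperature
setMethod("temperature", "SolventModel", function(object) object@temperature)
#' @rdname temperature
setMethod("temperature", "RismState", function(object) object@temperature)

#' Voxel values of a 3D grid
#' @param object a Grid3D
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))

#' @rdname gridValues
setMethod("gridValues", "Grid3D", function(object) object@values)

#' Grid origin (first voxel center, Angstrom)
#' @param object a gridded object
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname gridOrigin
setMethod("gridOrigin", "Grid3D", function(object) object@origin)
#' @rdname gridOrigin
setMethod("gridOrigin", "RismState", function(object) object@origin)
#' @rdname gridOrigin
setMethod("gridOrigin", "GistResults", function(object) object@origin)

#' Voxel spacing (Angstrom)
#' @param object a gridded object
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname gridSpacing
setMethod("gridSpacing", "Grid3D", function(object) object@spacing)
#' @rdname gridSpacing
setMethod("gridSpacing", "RismState", function(object) object@spacing)
#' @rdname gridSpacing
setMethod("gridSpacing", "GistResults", function(object) object@spacing)

#' Final residual of an iterative solution
#' @param object a converged solver result
#' @export
setGeneric("residual", function(object) standardGeneric("residual"))

#' @rdname residual
setMethod("residual", "BulkSolvent", function(object) object@residual)
#' @rdname residual
setMethod("residual", "RismState", function(object) object@residual)

#' Has the iterative solution converged?
#' @param object a solver result
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname isConverged
setMethod("isConverged", "BulkSolvent", function(object) object@converged)
#' @rdname isConverged
setMethod("isConverged", "RismState", function(object) object@converged)

#' Solute atom table
#' @param object a SoluteStructure
#' @export
setGeneric("soluteAtoms", function(object) standardGeneric("soluteAtoms"))

#' @rdname soluteAtoms
setMethod("soluteAtoms", "SoluteStructure", function(object) object@atoms)

setMethod("show", "SolventModel", function(object) {
  cat("SolventModel:", nrow(object@sites), "site types,",
      nrow(object@positions), "positions\n")
  cat("  T =", object@temperature, "K, density =",
      signif(object@molecularDensity, 6), "A^-3, target dielectric =",
      object@targetDielectric, "\n")
  print(object@sites, row.names = FALSE)
})

setMethod("show", "BulkSolvent", function(object) {
  cat("BulkSolvent (", object@closure, "): ", object@grid@n, " x ",
      object@grid@dr, " A radial grid\n", sep = "")
  cat("  residual", format(object@residual, digits = 3), "of tolerance",
      format(object@tolerance, digits = 3),
      if (object@converged) "(converged)\n" else "(NOT converged)\n")
})

setMethod("show", "Grid3D", function(object) {
  d <- dim(object@values)
  cat("Grid3D ", paste(d, collapse = " x "), " voxels, spacing ",
      object@spacing, " A, origin (",
      paste(signif(object@origin, 6), collapse = ", "), ")\n", sep = "")
  cat("  value range [", signif(min(object@values), 6), ", ",
      signif(max(object@values), 6), "]\n", sep = "")
})

setMethod("show", "SoluteStructure", function(object) {
  cat("SoluteStructure:", nrow(object@atoms), "atoms, net charge",
      signif(sum(object@atoms$charge), 6), "e\n")
})

setMethod("show", "RismState", function(object) {
  cat("RismState: sites", paste(object@siteNames, collapse = ", "),
      "on", paste(dim(object@h[[1]]), collapse = " x "), "grid\n")
  cat("  closure order", object@closure, "- residual",
      format(object@residual, digits = 3),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  if (length(object@dT))
    cat("  temperature derivatives present (mode:", object@dT$mode, ")\n")
})

setMethod("show", "ThermoMaps", function(object) {
  cat("ThermoMaps on", paste(dim(object@dmu[[1]]), collapse = " x "),
      "grid; pmv =", signif(object@pmv, 6), "A^3\n")
  print(object@totals, row.names = FALSE)
  if (length(object@uct)) cat("  UCT correction applied\n")
})

setMethod("show", "GistResults", function(object) {
  cat("GistResults:", paste(dim(object@g), collapse = " x "),
      "voxels from", object@nFrames, "frames\n")
})

setMethod("show", "WaterFrameSet", function(object) {
  cat("WaterFrameSet:", length(object@frames), "frames,",
      nrow(object@frames[[1]]$O), "waters/frame\n")
})

setMethod("show", "UctParams", function(object) {
  cat("UctParams: a0 =", object@a0, "a1 =", object@a1,
      "b0 =", object@b0, "b1 =", object@b1, "\n")
})
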