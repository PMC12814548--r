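#' @title Accessors for trajectory and distribution objects
#' @name ringlink-accessors
NULL

#' Number of frames in a trajectory
#' @param x a [Trajectory-class] object.
#' @return integer.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' Number of atoms in a trajectory
#' @param x a [Trajectory-class] object.
#' @return integer.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' Atom metadata table
#' @param x a [Trajectory-class] object.
#' @return data.frame with one row per atom.
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname atomData
#' @export
setMethod("atomData", "Trajectory", function(x) x@atoms)

#' Coordinates of one frame
#' @param x a [Trajectory-class] object.
#' @param i frame number (1-based).
#' @return numeric matrix `nAtoms x 3`, nm.
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nFrames(x))
  x@coords[, , i, drop = TRUE]
})

#' Box edge lengths
#' @param x a [Trajectory-class] object.
#' @param i frame number (1-based); if missing, the full `3 x nFrames` matrix.
#' @return numeric vector of 3 edges (nm), or the full matrix.
#' @export
setGeneric("boxDims", function(x, i) standardGeneric("boxDims"))

#' @rdname boxDims
#' @export
setMethod("boxDims", "Trajectory", function(x, i) {
  if (missing(i)) x@box else x@box[, i]
})

#' Frame times (ps)
#' @param x a [Trajectory-class] object.
#' @return numeric vector.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@time)

#' Bin centers of a radial distribution
#' @param x a [RadialDistribution-class] object.
#' @return numeric vector, nm.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname binCenters
#' @export
setMethod("binCenters", "RadialDistribution", function(x) {
  e <- x@binEdges
  (head(e, -1) + tail(e, -1)) / 2
})

#' Minima table of an effective potential
#' @param x an [EffectivePotential-class] object (after [findMinima()]).
#' @return data.frame with columns `r`, `depth`, `rank`.
#' @export
setGeneric("potentialMinima", function(x) standardGeneric("potentialMinima"))

#' @rdname potentialMinima
#' @export
setMethod("potentialMinima", "EffectivePotential", function(x) x@minima)

#' Plateau intervals of an effective potential
#' @param x an [EffectivePotential-class] object (after [findMinima()]).
#' @return data.frame with columns `r_start`, `r_end`, `n_bins`.
#' @export
setGeneric("potentialPlateaus", function(x) standardGeneric("potentialPlateaus"))

#' @rdname potentialPlateaus
#' @export
setMethod("potentialPlateaus", "EffectivePotential", function(x) x@plateaus)

setMethod("show", "Trajectory", function(object) {
  rid <- object@atoms$ring_id
  cat("Trajectory:", nAtoms(object), "atoms x", nFrames(object), "frames\n")
  cat("  ring 0:", sum(rid == 0L), "atoms; ring 1:", sum(rid == 1L),
      "atoms; other:", sum(rid == -1L), "\n")
  sp <- table(object@atoms$species[rid == -1L])
  if (length(sp))
    cat("  non-ring species:",
        paste(names(sp), as.integer(sp), sep = ":", collapse = " "), "\n")
  b <- object@box[, 1]
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f nm\n", b[1], b[2], b[3]))
})

setMethod("show", "RadialDistribution", function(object) {
  cat("RadialDistribution (", object@normalization, "): ",
      length(object@counts), " bins over [",
      sprintf("%.3f", object@binEdges[1]), ", ",
      sprintf("%.3f", max(object@binEdges)), "] nm, ",
      sum(object@counts), " pair counts\n", sep = "")
})

setMethod("show", "EffectivePotential", function(object) {
  ok <- is.finite(object@betaV)
  cat("EffectivePotential: ", sum(ok), "/", length(object@betaV),
      " defined bins", sep = "")
  if (nrow(object@minima))
    cat("; ", nrow(object@minima), " minima at r = ",
        paste(sprintf("%.2f", object@minima$r), collapse = ", "), " nm",
        sep = "")
  cat("\n")
})

setMethod("show", "DensityMap", function(object) {
  m <- densityMode(object)
  cat(sprintf(
    "DensityMap: %d x %d grid, sigma = %.2f (standardized); mode at r = %.2f nm, theta = %.1f deg\n",
    length(object@rGrid), length(object@thetaGrid), object@bandwidth,
    m[["r"]], m[["theta"]]))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nBeads, "beads/ring, R =", object@ringRadius,
      "nm, e =", object@eccentricity, ", bend =", object@bendAmplitude,
      "nm\n")
  cat("  separation mixture:",
      paste(sprintf("%.2f nm (w=%.2f, s=%.2f)", object@separationModel$mean,
                    object@separationModel$weight,
                    object@separationModel$sigma), collapse = "; "), "\n")
  cat(sprintf("  orientation: %.1f deg (sd %.1f); %d frames, box %.1f nm, seed %d\n",
              object@orientationModel[1], object@orientationModel[2],
              object@nFrames, object@boxEdge, object@seed))
  cat("  cations:", paste(object@ions$species, collapse = ", "), "\n")
})
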