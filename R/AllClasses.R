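#' @title Core S4 containers
#' @name ringlink-classes
#' @description S4 classes holding trajectories, binned radial distributions,
#'   effective potentials, 2D density maps and synthetic-ensemble
#'   parameterizations. Objects are created by the package's reader,
#'   analysis and generator functions rather than by calling `new()`.
NULL

REQUIRED_ATOM_COLS <- c("atom_index", "atom_name", "residue_index",
                        "residue_name", "chain_id", "ring_id", "species",
                        "mass")

#' Trajectory of a catenated system
#'
#' Coordinates are stored as an `nAtoms x 3 x nFrames` array in nm, the
#' orthorhombic box as a `3 x nFrames` matrix of edge lengths in nm, and the
#' atom metadata as a data frame with one row per atom (columns
#' `atom_index` (0-based), `atom_name`, `residue_index`, `residue_name`,
#' `chain_id`, `ring_id` (0/1 for the two rings, -1 otherwise), `species`,
#' `mass`).
#'
#' @slot atoms data.frame of per-atom metadata.
#' @slot coords numeric array, `nAtoms x 3 x nFrames`, nm.
#' @slot box numeric matrix, `3 x nFrames`, nm.
#' @slot time numeric vector of frame times, ps.
#' @slot frameIndex integer vector of source frame indices (0-based).
#' @export
setClass("Trajectory",
  slots = c(atoms = "data.frame", coords = "array", box = "matrix",
            time = "numeric", frameIndex = "integer"))

setValidity("Trajectory", function(object) {
  msg <- character()
  a <- object@atoms
  miss <- setdiff(REQUIRED_ATOM_COLS, names(a))
  if (length(miss))
    msg <- c(msg, paste("atoms lacks columns:", paste(miss, collapse = ", ")))
  if (!length(msg) && nrow(a) &&
      !identical(as.integer(a$atom_index), seq_len(nrow(a)) - 1L))
    msg <- c(msg, "atom_index must be unique and contiguous from 0")
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
  else {
    if (d[1] != nrow(a))
      msg <- c(msg, "coords atom dimension does not match atom table")
    if (nrow(object@box) != 3L || ncol(object@box) != d[3])
      msg <- c(msg, "box must be 3 x nFrames")
    else if (any(object@box <= 0))
      msg <- c(msg, "box edges must be strictly positive")
    if (length(object@time) != d[3])
      msg <- c(msg, "time length must equal nFrames")
    if (length(object@frameIndex) != d[3])
      msg <- c(msg, "frameIndex length must equal nFrames")
  }
  if (length(msg)) msg else TRUE
})

#' Binned radial distribution function
#'
#' @slot binEdges ascending bin edges, nm.
#' @slot g dimensionless g(r) per bin (`NA` marks empty bins where the
#'   normalization is undefined).
#' @slot counts raw pair counts per bin.
#' @slot normalization `"pair_density"` (bonded COM pair, shell-normalized so
#'   the distribution integrates to one) or `"ideal_gas"` (ion RDF,
#'   normalized by the uncorrelated pair density so g -> 1 at large r).
#' @slot nUsed number of frames (pair_density) or frame-pair normalization
#'   denominator metadata (ideal_gas).
#' @export
setClass("RadialDistribution",
  slots = c(binEdges = "numeric", g = "numeric", counts = "numeric",
            normalization = "character", nUsed = "numeric"))

setValidity("RadialDistribution", function(object) {
  msg <- character()
  if (length(object@binEdges) < 2L || is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly ascending, length >= 2")
  nb <- length(object@binEdges) - 1L
  if (length(object@g) != nb || length(object@counts) != nb)
    msg <- c(msg, "g and counts must have one value per bin")
  if (any(object@g < 0, na.rm = TRUE))
    msg <- c(msg, "g must be non-negative")
  if (!object@normalization %in% c("pair_density", "ideal_gas", "histogram"))
    msg <- c(msg, "normalization must be 'pair_density', 'ideal_gas' or 'histogram'")
  if (length(msg)) msg else TRUE
})

#' Effective potential of mean force along the COM separation
#'
#' `betaV = -log(g(r))` in units of kBT, shifted so the minimum over defined
#' bins is zero; bins with zero counts are `NA` (missing, never infinite).
#' `minima` and `plateaus` are filled in by [findMinima()].
#'
#' @slot r bin-center grid, nm.
#' @slot betaV potential per bin, kBT.
#' @slot minima data.frame with columns `r`, `depth`, `rank` (rank 1 is the
#'   global minimum; rows ordered by ascending r).
#' @slot plateaus data.frame with columns `r_start`, `r_end`, `n_bins`.
#' @slot smoothWindow integer, moving-average window used for minima search.
#' @export
setClass("EffectivePotential",
  slots = c(r = "numeric", betaV = "numeric", minima = "data.frame",
            plateaus = "data.frame", smoothWindow = "integer"))

setValidity("EffectivePotential", function(object) {
  msg <- character()
  if (length(object@r) != length(object@betaV))
    msg <- c(msg, "r and betaV lengths differ")
  ok <- is.finite(object@betaV)
  if (any(ok) && abs(min(object@betaV[ok]) - 0) > 1e-9)
    msg <- c(msg, "betaV must be shifted so its minimum over defined bins is 0")
  if (length(msg)) msg else TRUE
})

#' 2D separation-orientation kernel density map
#'
#' @slot rGrid grid of separations, nm.
#' @slot thetaGrid grid of angles, degrees.
#' @slot density matrix `length(rGrid) x length(thetaGrid)`, normalized so
#'   that the cell-area-weighted sum is one.
#' @slot bandwidth kernel sigma in standardized (per-axis sd) units.
#' @export
setClass("DensityMap",
  slots = c(rGrid = "numeric", thetaGrid = "numeric", density = "matrix",
            bandwidth = "numeric"))

setValidity("DensityMap", function(object) {
  msg <- character()
  if (!identical(dim(object@density),
                 c(length(object@rGrid), length(object@thetaGrid))))
    msg <- c(msg, "density must be length(rGrid) x length(thetaGrid)")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Parameterization of a synthetic catenane ensemble
#'
#' Defines the geometry, fluctuation statistics, ion placement and seed of a
#' generated two-ring catenane trajectory. Create with [syntheticSpec()],
#' which documents the fields and their defaults.
#'
#' @slot nBeads beads per ring.
#' @slot ringRadius target ring radius, nm (contour length is 2*pi*ringRadius).
#' @slot eccentricity in-plane ellipse eccentricity in [0, 1).
#' @slot bendAmplitude out-of-plane Fourier-mode amplitude, nm.
#' @slot separationModel data.frame(weight, mean, sigma) of shell-Gaussian
#'   mixture components for the COM separation, nm.
#' @slot orientationModel c(mean, sigma) of the wrapped-Gaussian ring-plane
#'   angle, degrees.
#' @slot ions data.frame(species, valence, n_salt, condensed_fraction,
#'   shell_mu, shell_sigma) per cation species; chloride is added
#'   automatically for electroneutrality.
#' @slot bridgeScript data.frame(ion, start_frame, end_frame) of scripted
#'   bridging ions (1-based ion index within its species; frames 0-based).
#' @slot boxEdge cubic box edge, nm.
#' @slot nFrames number of frames.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticSpec",
  slots = c(nBeads = "integer", ringRadius = "numeric",
            eccentricity = "numeric", bendAmplitude = "numeric",
            separationModel = "data.frame", orientationModel = "numeric",
            ions = "data.frame", bridgeScript = "data.frame",
            boxEdge = "numeric", nFrames = "integer", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nBeads < 12L) msg <- c(msg, "nBeads must be >= 12")
  if (object@ringRadius <= 0) msg <- c(msg, "ringRadius must be > 0")
  if (object@eccentricity < 0 || object@eccentricity >= 1)
    msg <- c(msg, "eccentricity must be in [0, 1)")
  if (object@bendAmplitude < 0) msg <- c(msg, "bendAmplitude must be >= 0")
  sm <- object@separationModel
  if (!all(c("weight", "mean", "sigma") %in% names(sm)) || nrow(sm) < 1L)
    msg <- c(msg, "separationModel needs columns weight, mean, sigma")
  else if (any(sm$weight <= 0) || any(sm$sigma <= 0) || any(sm$mean <= 0))
    msg <- c(msg, "separationModel entries must be positive")
  if (length(object@orientationModel) != 2L)
    msg <- c(msg, "orientationModel must be c(mean, sigma) in degrees")
  need <- c("species", "valence", "n_salt", "condensed_fraction",
            "shell_mu", "shell_sigma")
  if (!all(need %in% names(object@ions)))
    msg <- c(msg, paste("ions needs columns:", paste(need, collapse = ", ")))
  else {
    if (!all(object@ions$valence %in% c(1L, 2L)))
      msg <- c(msg, "cation valence must be 1 or 2")
    if (any(object@ions$condensed_fraction < 0 | object@ions$condensed_fraction > 1))
      msg <- c(msg, "condensed_fraction must be in [0, 1]")
  }
  if (object@boxEdge <= 0) msg <- c(msg, "boxEdge must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (length(msg)) msg else TRUE
})
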