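#' @title Ring-ring orientation and separation-orientation density maps
#' @name orientation-analysis
#' @description The relative orientation angle between principal axes of the
#'   two rings, folded to [0, 90] degrees, and joint 2D Gaussian kernel
#'   density maps of (separation, angle) with axis standardization.
NULL

#' Relative angle between two principal axes
#'
#' `theta = arccos(|a . b| / (|a| |b|))` in degrees. The absolute value
#' folds the arbitrary eigenvector sign into [0, 90] degrees.
#'
#' @param vecA,vecB numeric 3-vectors (need not be unit length).
#' @return angle in degrees, in [0, 90].
#' @export
relativeAngle <- function(vecA, vecB) {
  na <- sqrt(sum(vecA^2))
  nb <- sqrt(sum(vecB^2))
  if (na < 1e-12 || nb < 1e-12)
    rlError("zero-norm eigenvector", "ringlink_numerical_error")
  acos(min(1, abs(sum(vecA * vecB)) / (na * nb))) * 180 / pi
}

#' Per-frame separation and relative orientation
#'
#' For each frame, the COM separation of the two rings and the angle between
#' the chosen gyration-tensor eigenvectors: `"smallest"` (default) is the
#' ring-plane normal, so 90 degrees means perpendicular ring planes;
#' `"largest"` is the major in-plane axis.
#'
#' @param traj a [Trajectory-class] object.
#' @param ringA,ringB 1-based atom indices of the two rings.
#' @param choice `"smallest"` or `"largest"` eigenvalue's eigenvector.
#' @return data.frame with columns `frame`, `r` (nm), `theta` (degrees).
#' @export
orientationSeries <- function(traj, ringA, ringB,
                              choice = c("smallest", "largest")) {
  choice <- match.arg(choice)
  col <- if (choice == "smallest") 3L else 1L
  sa <- ringSpectra(traj, ringA)
  sb <- ringSpectra(traj, ringB)
  sep <- suppressWarnings(separationSeries(traj, ringA, ringB))
  theta <- vapply(seq_len(nFrames(traj)), function(i)
    relativeAngle(sa$vectors[, col, i], sb$vectors[, col, i]), numeric(1))
  data.frame(frame = traj@frameIndex, r = sep$r, theta = theta)
}

#' 2D Gaussian kernel density estimate on standardized axes
#'
#' Separation (nm) and angle (degrees) are incommensurate, so each axis is
#' divided by its sample standard deviation before the isotropic Gaussian
#' kernel `exp(-d^2 / (2 sigma^2))` is applied; the resulting grid density
#' is renormalized so the cell-area-weighted sum is one.
#'
#' @param r,theta numeric vectors (>= 10 points), or pass the
#'   [orientationSeries()] data.frame as `r`.
#' @param sigma kernel bandwidth in standardized units (default 0.3).
#' @param gridSize nodes per axis (default c(100, 100)).
#' @return a [DensityMap-class] object.
#' @export
kde2D <- function(r, theta = NULL, sigma = 0.3, gridSize = c(100L, 100L)) {
  if (is.data.frame(r)) { theta <- r$theta; r <- r$r }
  stopifnot(length(r) == length(theta))
  if (length(r) < 10L)
    rlError("need >= 10 points for a density map",
            "ringlink_insufficient_data_error")
  if (sigma <= 0) rlError("sigma must be > 0", "ringlink_usage_error")
  sdr <- sd(r)
  sdt <- sd(theta)
  if (sdr < 1e-12 || sdt < 1e-12)
    rlError("zero-variance axis: density map degenerate",
            "ringlink_degenerate_data_error")
  pad <- 3 * sigma
  rGrid <- seq(min(r) - pad * sdr, max(r) + pad * sdr,
               length.out = gridSize[1])
  tGrid <- seq(min(theta) - pad * sdt, max(theta) + pad * sdt,
               length.out = gridSize[2])
  # separable kernel: D[i, j] = sum_k A[i, k] * B[j, k]
  A <- exp(-outer(rGrid / sdr, r / sdr, "-")^2 / (2 * sigma^2))
  B <- exp(-outer(tGrid / sdt, theta / sdt, "-")^2 / (2 * sigma^2))
  D <- A %*% t(B)
  cell <- diff(rGrid[1:2]) * diff(tGrid[1:2])
  D <- D / (sum(D) * cell)
  new("DensityMap", rGrid = rGrid, thetaGrid = tGrid, density = D,
      bandwidth = sigma)
}

#' Mode of a density map
#'
#' Grid node of maximum density; exact ties are broken by smallest r, then
#' smallest theta.
#'
#' @param map a [DensityMap-class] object.
#' @return named numeric vector `c(r = ..., theta = ...)`.
#' @export
densityMode <- function(map) {
  D <- map@density
  mx <- max(D)
  hits <- which(D == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(r = map@rGrid[hits[1, 1]], theta = map@thetaGrid[hits[1, 2]])
}
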