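#' @title Center-of-mass separation and effective potential
#' @name pair-potential
#' @description The separation series between the two ring centers of mass,
#'   its radial pair distribution, the effective potential of mean force
#'   `beta*V_eff = -ln g(r)`, multi-well minima detection with plateau
#'   flagging, and per-frame basin (state) assignment.
NULL

#' Center of mass of a selection in one frame
#'
#' Uniform-weight centroid by default, consistent with the shape module;
#' pass `weights` for mass weighting.
#'
#' @param coords `N x 3` coordinate matrix, nm.
#' @param indices 1-based row indices of the selection.
#' @param weights optional weights of length `length(indices)`.
#' @return length-3 numeric vector, nm.
#' @export
centerOfMass <- function(coords, indices, weights = NULL) {
  if (!length(indices))
    rlError("empty selection", "ringlink_selection_error")
  m <- coords[indices, , drop = FALSE]
  if (is.null(weights)) colMeans(m)
  else colSums(m * (weights / sum(weights)))
}

#' Per-frame COM separation of the two rings
#'
#' The distance is Euclidean without minimum-image wrapping: the catenane is
#' one mechanically bonded object and frames are expected whole-molecule
#' unwrapped. A warning is raised if any separation exceeds half the
#' shortest box edge (suggesting a wrapping artifact) or jumps by more than
#' 1 nm between consecutive frames.
#'
#' @param traj a [Trajectory-class] object.
#' @param ringA,ringB 1-based atom indices of the two rings.
#' @param weights optional list of per-ring weights.
#' @return data.frame with columns `frame` (0-based source index) and `r` (nm).
#' @export
separationSeries <- function(traj, ringA, ringB, weights = NULL) {
  nf <- nFrames(traj)
  r <- numeric(nf)
  for (i in seq_len(nf)) {
    co <- traj@coords[, , i]
    d <- centerOfMass(co, ringA, weights[[1]]) -
         centerOfMass(co, ringB, weights[[2]])
    r[i] <- sqrt(sum(d^2))
  }
  halfmin <- min(traj@box) / 2
  if (any(r > halfmin))
    warning("COM separation exceeds half the shortest box edge; ",
            "frames may not be whole-molecule unwrapped")
  if (nf > 1 && any(abs(diff(r)) > 1))
    warning("COM separation jumps > 1 nm/frame; check unwrapping")
  if (any(r == 0))
    warning("zero COM separation encountered")
  data.frame(frame = traj@frameIndex, r = r)
}

#' Radial distribution of the bonded COM pair
#'
#' Shell-normalized histogram of the separation series:
#' `g(r) = h(r) / (n 4 pi r_c^2 dr)` with `r_c` the bin centers, so that
#' `sum g * 4 pi r_c^2 dr = 1` exactly. Bins with zero counts carry `g = 0`
#' (their emptiness is recorded in `counts`; the potential marks them
#' missing). Set `normalization = "histogram"` for the bare normalized
#' histogram without the shell factor.
#'
#' @param r numeric vector of separations (nm), or the data.frame from
#'   [separationSeries()].
#' @param binWidth bin width, nm (default 0.05).
#' @param normalization `"pair_density"` (default, shell factor) or
#'   `"histogram"` (bare); both are stored under the `pair_density` tag with
#'   the shell factor, or `ideal_gas` is never used here.
#' @return a [RadialDistribution-class] object.
#' @export
comPairDistribution <- function(r, binWidth = 0.05,
                                normalization = c("pair_density", "histogram")) {
  normalization <- match.arg(normalization)
  if (is.data.frame(r)) r <- r$r
  if (!length(r))
    rlError("empty separation series", "ringlink_insufficient_data_error")
  if (binWidth <= 0) rlError("binWidth must be > 0", "ringlink_usage_error")
  lo <- floor(min(r) / binWidth) * binWidth
  nb <- max(1L, ceiling((max(r) - lo) / binWidth))
  edges <- lo + (0:nb) * binWidth
  if (max(r) >= max(edges)) edges <- c(edges, max(edges) + binWidth)
  counts <- as.numeric(binPairsCpp(cbind(r, 0, 0), matrix(0, 1, 3),
                                   c(0, 0, 0), edges))
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  n <- length(r)
  g <- if (normalization == "pair_density")
    counts / (n * 4 * pi * centers^2 * binWidth)
  else counts / (n * binWidth)
  new("RadialDistribution", binEdges = edges, g = g, counts = counts,
      normalization = normalization, nUsed = n)
}

#' Effective potential of mean force
#'
#' `betaV(r) = -ln g(r)` in kBT, shifted so the minimum over defined bins is
#' zero (the additive constant of a PMF is arbitrary). Zero-count bins are
#' `NA`, never infinite.
#'
#' @param rd a [RadialDistribution-class] object from [comPairDistribution()].
#' @return an [EffectivePotential-class] object (minima not yet located;
#'   see [findMinima()]).
#' @export
effectivePotential <- function(rd) {
  stopifnot(is(rd, "RadialDistribution"))
  if (all(rd@counts == 0))
    rlError("all bins empty", "ringlink_insufficient_data_error")
  v <- ifelse(rd@counts > 0, -log(rd@g), NA_real_)
  v <- v - min(v, na.rm = TRUE)
  new("EffectivePotential", r = binCenters(rd), betaV = v,
      minima = data.frame(r = numeric(0), depth = numeric(0), rank = integer(0)),
      plateaus = data.frame(r_start = numeric(0), r_end = numeric(0),
                            n_bins = integer(0)),
      smoothWindow = 1L)
}

movingAverage <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - half):min(n, i + half)
    mean(x[j], na.rm = TRUE)
  }, numeric(1))
}

#' Locate minima and plateau intervals of an effective potential
#'
#' The profile is smoothed by a centered moving average over
#' `smoothWindow` bins; local minima whose separating barriers are below
#' `barrierMin` kBT are merged (the deeper survives). Intervals where the
#' smoothed profile stays within `plateauTol` kBT of its local minimum over
#' at least `plateauSpan` bins are flagged as plateaus. Minima are ranked
#' by depth (rank 1 = global minimum) and listed in ascending r.
#'
#' @param ep an [EffectivePotential-class] object (>= 5 defined bins).
#' @param smoothWindow moving-average window in bins (default 5).
#' @param barrierMin minimum barrier height separating distinct minima,
#'   kBT (default 0.2).
#' @param plateauTol flatness tolerance for plateau detection, kBT
#'   (default 0.15).
#' @param plateauSpan minimum plateau extent in bins (default 6).
#' @return the input object with `minima` and `plateaus` slots filled.
#' @export
findMinima <- function(ep, smoothWindow = 5L, barrierMin = 0.2,
                       plateauTol = 0.15, plateauSpan = 6L) {
  ok <- which(is.finite(ep@betaV))
  if (length(ok) < 5L)
    rlError("need >= 5 defined bins", "ringlink_insufficient_data_error")
  r <- ep@r[ok]
  v <- movingAverage(ep@betaV[ok], as.integer(smoothWindow))
  n <- length(v)
  # local minima of the smoothed profile (plateaus of equal values: keep first)
  is_min <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) v[i - 1] else Inf
    right <- if (i < n) v[i + 1] else Inf
    v[i] < left && v[i] <= right
  }, logical(1))
  idx <- which(is_min)
  # merge minima separated by barriers below barrierMin (deeper one survives)
  repeat {
    if (length(idx) < 2L) break
    merged <- FALSE
    for (k in seq_len(length(idx) - 1L)) {
      i1 <- idx[k]; i2 <- idx[k + 1L]
      barrier <- max(v[i1:i2]) - max(v[i1], v[i2])
      if (barrier < barrierMin) {
        idx <- idx[-(if (v[i1] <= v[i2]) k + 1L else k)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  minima <- data.frame(r = r[idx], depth = v[idx],
                       rank = rank(v[idx], ties.method = "first"))
  # plateau intervals: runs staying within plateauTol of their running minimum
  plateaus <- data.frame(r_start = numeric(0), r_end = numeric(0),
                         n_bins = integer(0))
  i <- 1L
  while (i <= n) {
    j <- i
    lo <- v[i]
    while (j < n && max(abs(v[i:(j + 1L)] - min(v[i:(j + 1L)]))) <= plateauTol) {
      j <- j + 1L
    }
    if (j - i + 1L >= plateauSpan)
      plateaus <- rbind(plateaus, data.frame(r_start = r[i], r_end = r[j],
                                             n_bins = j - i + 1L))
    i <- j + 1L
  }
  ep@minima <- minima
  ep@plateaus <- plateaus
  ep@smoothWindow <- as.integer(smoothWindow)
  ep
}

#' Assign each frame to a potential basin
#'
#' Basin boundaries are the barrier maxima of the smoothed potential between
#' adjacent minima; states are numbered by ascending minimum position. A
#' separation exactly on a boundary goes to the lower-r state.
#'
#' @param series separation data.frame from [separationSeries()] (or a
#'   numeric vector of separations, nm).
#' @param ep an [EffectivePotential-class] object with minima located
#'   ([findMinima()]).
#' @return integer vector of 1-based state labels, one per frame.
#' @export
assignStates <- function(series, ep) {
  r <- if (is.data.frame(series)) series$r else as.numeric(series)
  if (!nrow(ep@minima))
    rlError("no minima located; run findMinima first", "ringlink_usage_error")
  mins <- sort(ep@minima$r)
  if (length(mins) == 1L) return(rep(1L, length(r)))
  ok <- which(is.finite(ep@betaV))
  rg <- ep@r[ok]
  v <- movingAverage(ep@betaV[ok], ep@smoothWindow)
  bounds <- vapply(seq_len(length(mins) - 1L), function(k) {
    seg <- which(rg >= mins[k] & rg <= mins[k + 1L])
    rg[seg[which.max(v[seg])]]
  }, numeric(1))
  # boundary itself belongs to the lower-r state: strict '>' to move up
  1L + vapply(r, function(x) sum(x > bounds), integer(1))
}
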