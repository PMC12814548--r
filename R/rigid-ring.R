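#' @title Rigid linked-ring model
#' @name rigid-ring-model
#' @description The analytic insertion-probability density for a rigid
#'   circular ring, its mode, the discrete Gauss linking number of closed
#'   polylines, and a Monte Carlo sampler for the COM separation of two
#'   perpendicular rigid circles constrained to linking number +/-1.
NULL

#' Insertion probability density for a rigid circular ring
#'
#' The probability density of finding a topological insertion perpendicular
#' to the plane of a rigid circle of radius `R` at in-plane distance `r`:
#' `p(r) = (r / (pi R^2)) * arccos(r / (2R))` on `[0, 2R]`, vanishing at
#' both ends. This closed form is not exactly unit-normalized; with
#' `normalized = TRUE` it is divided by its numerical integral over
#' `[0, 2R]`.
#'
#' @param r distance(s), nm, in `[0, 2R]`.
#' @param R ring radius, nm.
#' @param normalized divide by the numerical integral (default FALSE).
#' @return density value(s), 1/nm.
#' @export
insertionProbability <- function(r, R, normalized = FALSE) {
  if (R <= 0) rlError("R must be > 0", "ringlink_usage_error")
  if (any(r < 0 | r > 2 * R))
    rlError("r must lie in [0, 2R]", "ringlink_domain_error")
  p <- (r / (pi * R^2)) * acos(r / (2 * R))
  if (normalized) {
    Z <- stats::integrate(function(x) (x / (pi * R^2)) * acos(x / (2 * R)),
                          0, 2 * R, rel.tol = 1e-10)$value
    p <- p / Z
  }
  p
}

#' Mode of the insertion probability density
#'
#' Bracketed scalar maximization of `insertionProbability` on `(0, 2R)` to
#' 1e-6 relative tolerance. Scales linearly with R.
#'
#' @param R ring radius, nm.
#' @return location of the maximum, nm.
#' @export
insertionMode <- function(R) {
  if (R <= 0) rlError("R must be > 0", "ringlink_usage_error")
  optimize(function(x) insertionProbability(x, R),
           interval = c(0, 2 * R), maximum = TRUE,
           tol = 1e-6 * R)$maximum
}

#' Discrete Gauss linking number of two closed polylines
#'
#' Double sum of signed solid-angle contributions over all segment pairs
#' (segments close each curve from its last vertex back to its first),
#' divided by 4 pi. For disjoint closed curves the sum is an integer up to
#' discretization error; values further than `tol` from an integer raise a
#' degeneracy error.
#'
#' @param curveA,curveB `n x 3` vertex matrices of the closed curves.
#' @param tol allowed distance from the nearest integer (default 0.1).
#' @return integer linking number.
#' @export
linkingNumber <- function(curveA, curveB, tol = 0.1) {
  lk <- gaussLinkingCpp(as.matrix(curveA), as.matrix(curveB))
  lkr <- round(lk)
  if (abs(lk - lkr) > tol)
    rlError(sprintf("Gauss sum %.4f is not close to an integer (degenerate geometry)", lk),
            "ringlink_numerical_error")
  as.integer(lkr)
}

#' Vertices of a discretized circle
#'
#' Regular `n`-gon inscribed in the circle of radius `R` centered at
#' `center`, in the plane spanned by orthonormal `e1`, `e2`.
#'
#' @param R radius, nm.
#' @param n number of vertices (default 64).
#' @param center length-3 center.
#' @param e1,e2 orthonormal in-plane basis vectors.
#' @return `n x 3` matrix.
#' @export
circlePoints <- function(R, n = 64L, center = c(0, 0, 0),
                         e1 = c(1, 0, 0), e2 = c(0, 1, 0)) {
  t <- 2 * pi * (seq_len(n) - 1L) / n
  sweep(outer(R * cos(t), e1) + outer(R * sin(t), e2), 2, center, "+")
}

#' Monte Carlo sampling of linked perpendicular rigid circles
#'
#' Ring A is a 64-segment circle of radius `R` fixed in the xy-plane at the
#' origin. Ring B is the same circle in a plane perpendicular to A's plane
#' (normal azimuth uniform in A's plane), its center uniform in a cube of
#' half-width `3R`. Candidates are accepted iff the discrete Gauss linking
#' number is +/-1. Returns the accepted COM distances and the mode of their
#' histogram (bin `0.02R`, 5-bin centered smoothing). Results are
#' reproducible bit-for-bit at a fixed seed and sample count.
#'
#' @param R ring radius, nm (default 1).
#' @param nSamples number of accepted samples (>= 1000 for distribution
#'   outputs; default 1e5).
#' @param seed RNG seed (default 1).
#' @param nSegments polygon discretization (default 64).
#' @param orientation only `"perpendicular"` is implemented (an isotropic
#'   `"uniform"` variant is out of the model's scope).
#' @return list with `samples` (accepted |COM| distances), `mode` (smoothed
#'   histogram mode, nm), `acceptanceRate`, `histogram` (data.frame `r`,
#'   `counts`, `smoothed`), `params` (matrix phi, cx, cy, cz of accepted
#'   configurations) and `nTrials`.
#' @export
mcLinkedCircles <- function(R = 1, nSamples = 1e5, seed = 1L,
                            nSegments = 64L,
                            orientation = c("perpendicular")) {
  orientation <- match.arg(orientation)
  if (R <= 0) rlError("R must be > 0", "ringlink_usage_error")
  if (nSamples < 1e3)
    rlError("nSamples must be >= 1000 for distribution outputs",
            "ringlink_usage_error")
  set.seed(as.integer(seed))
  res <- mcLinkedCpp(R, as.integer(nSamples), as.integer(nSegments), 3 * R,
                     as.numeric(nSamples) * 1e4)
  if (res$n_accepted < nSamples)
    rlError("trial budget exhausted before reaching nSamples",
            "ringlink_sampling_error")
  if (res$n_accepted / res$n_trials < 1e-3)
    warning("linking acceptance rate below 1e-3")
  d <- res$dist
  bw <- 0.02 * R
  edges <- seq(0, ceiling(max(d) / bw) * bw + bw, by = bw)
  counts <- as.numeric(binPairsCpp(cbind(d, 0, 0), matrix(0, 1, 3),
                                   c(0, 0, 0), edges))
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  sm <- movingAverage(counts, 5L)
  list(samples = d,
       mode = centers[which.max(sm)],
       acceptanceRate = res$n_accepted / res$n_trials,
       histogram = data.frame(r = centers, counts = counts, smoothed = sm),
       params = res$params,
       nTrials = res$n_trials)
}
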