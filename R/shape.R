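#' @title Gyration-tensor shape descriptors
#' @name shape-analysis
#' @description Per-ring gyration tensors, eigenvalue spectra, and the
#'   ensemble shape descriptors of ring polymers: radius of gyration,
#'   relative shape anisotropy, asphericity, prolateness and eigenvalue
#'   ratios, with block-averaged standard errors.
NULL

#' Gyration tensor of a point set
#'
#' The second-moment dyadic `S = (1/N) sum_i r_i r_i^T` about the set's own
#' centroid, with uniform weights by default (set `weights` for
#' mass-weighting).
#'
#' @param coords `N x 3` matrix, nm.
#' @param weights optional non-negative weights of length N.
#' @return symmetric positive semidefinite `3 x 3` matrix, nm^2.
#' @export
gyrationTensor <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (!nrow(coords))
    rlError("empty ring selection", "ringlink_selection_error")
  if (is.null(weights)) {
    c0 <- colMeans(coords)
    r <- sweep(coords, 2, c0)
    crossprod(r) / nrow(coords)
  } else {
    w <- weights / sum(weights)
    c0 <- colSums(coords * w)
    r <- sweep(coords, 2, c0)
    crossprod(r * sqrt(w))
  }
}

#' Eigen-decomposition of a gyration tensor
#'
#' Eigenvalues are returned in descending order; each eigenvector's sign is
#' fixed so its first component of magnitude above 1e-12 is positive. On
#' exact eigenvalue ties the corresponding eigenvectors are ordered
#' lexicographically for determinism.
#'
#' @param tensor symmetric `3 x 3` matrix (asymmetry beyond 1e-6 is an error).
#' @return list with `values` (descending, nm^2), `vectors` (columns,
#'   orthonormal), `I1` (trace, nm^2) and `Rg` (sqrt(I1), nm).
#' @export
gyrationSpectrum <- function(tensor) {
  tensor <- as.matrix(tensor)
  if (max(abs(tensor - t(tensor))) > 1e-6)
    rlError("gyration tensor is not symmetric", "ringlink_numerical_error")
  e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # stable ordering on exact ties: lexicographic by eigenvector
  ord <- order(-vals)
  ties <- duplicated(vals[ord]) | duplicated(vals[ord], fromLast = TRUE)
  if (any(ties)) {
    key <- apply(vecs, 2, function(v) paste(sprintf("%.12f", abs(v)), collapse = ","))
    ord <- order(-vals, key)
  }
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  for (j in 1:3) {
    nz <- which(abs(vecs[, j]) > 1e-12)
    if (length(nz) && vecs[nz[1], j] < 0) vecs[, j] <- -vecs[, j]
  }
  I1 <- sum(diag(tensor))
  list(values = vals, vectors = vecs, I1 = I1, Rg = sqrt(max(I1, 0)))
}

#' Relative shape anisotropy
#'
#' `kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2` for a triple
#' of (mean) squared eigenvalues; 0 for spherically symmetric mass
#' distributions, 1 for a collinear array.
#'
#' @param lambda numeric triple of non-negative (mean) eigenvalues, nm^2.
#' @return dimensionless value in [0, 1].
#' @export
shapeAnisotropy <- function(lambda) {
  lambda <- as.numeric(lambda)
  stopifnot(length(lambda) == 3L)
  if (any(lambda < 0))
    rlError("eigenvalues must be non-negative", "ringlink_usage_error")
  s <- sum(lambda)
  if (s <= 0)
    rlError("all-zero eigenvalue triple has no defined shape",
            "ringlink_undefined_shape_error")
  1 - 3 * (lambda[1] * lambda[2] + lambda[2] * lambda[3] +
           lambda[3] * lambda[1]) / s^2
}

#' Asphericity
#'
#' `b = l1 - (l2 + l3) / 2`, non-negative for a descending triple; zero for
#' spherical symmetry.
#'
#' @param lambda numeric triple of (mean) eigenvalues in descending order, nm^2.
#' @return asphericity, nm^2.
#' @export
asphericity <- function(lambda) {
  lambda <- as.numeric(lambda)
  stopifnot(length(lambda) == 3L)
  lambda[1] - (lambda[2] + lambda[3]) / 2
}

#' Per-frame prolateness
#'
#' `s = (3 l1 - I1)(3 l2 - I1)(3 l3 - I1) / I1^3` with `I1 = l1 + l2 + l3`;
#' ranges from -0.25 (oblate, disk-like) to 2 (prolate, rod-like). The
#' ensemble prolateness is the mean of this per-frame ratio (the average
#' encloses the whole expression).
#'
#' @param lambda numeric triple, or an `n x 3` matrix of per-frame triples.
#' @return per-frame prolateness value(s) in [-0.25, 2].
#' @export
prolateness <- function(lambda) {
  m <- if (is.matrix(lambda)) lambda else matrix(as.numeric(lambda), nrow = 1)
  stopifnot(ncol(m) == 3L)
  I1 <- rowSums(m)
  if (any(I1 <= 0))
    rlError("zero trace: prolateness undefined", "ringlink_undefined_shape_error")
  out <- (3 * m[, 1] - I1) * (3 * m[, 2] - I1) * (3 * m[, 3] - I1) / I1^3
  if (is.matrix(lambda)) out else out[[1]]
}

#' Per-frame gyration spectra of one ring
#'
#' @param traj a [Trajectory-class] object.
#' @param ring integer vector of 1-based atom indices of the ring (from
#'   [resolveSelection()]).
#' @param weights optional per-atom weights (default uniform).
#' @return list with `eigenvalues` (`nFrames x 3`, descending, nm^2),
#'   `I1`, `Rg` (vectors) and `vectors` (`3 x 3 x nFrames` array).
#' @export
ringSpectra <- function(traj, ring, weights = NULL) {
  if (!length(ring))
    rlError("empty ring selection", "ringlink_selection_error")
  nf <- nFrames(traj)
  ev <- matrix(0, nf, 3)
  I1 <- numeric(nf)
  vecs <- array(0, dim = c(3, 3, nf))
  for (i in seq_len(nf)) {
    s <- gyrationSpectrum(gyrationTensor(traj@coords[ring, , i], weights))
    ev[i, ] <- s$values
    I1[i] <- s$I1
    vecs[, , i] <- s$vectors
  }
  list(eigenvalues = ev, I1 = I1, Rg = sqrt(I1), vectors = vecs)
}

blockMeans <- function(x, nBlocks) {
  n <- length(x)
  cut <- floor(seq(0, n, length.out = nBlocks + 1))
  vapply(seq_len(nBlocks),
         function(b) mean(x[(cut[b] + 1):cut[b + 1]]), numeric(1))
}

descriptorSet <- function(ev) {
  ml <- colMeans(ev)
  c(Rg = mean(sqrt(rowSums(ev))),
    lambda1 = ml[[1]], lambda2 = ml[[2]], lambda3 = ml[[3]],
    kappa2 = shapeAnisotropy(ml), b = asphericity(ml),
    S = mean(prolateness(ev)),
    r12 = ml[[1]] / ml[[2]], r13 = ml[[1]] / ml[[3]])
}

#' Ensemble shape summary with block-averaged errors
#'
#' Central values: `Rg` and the eigenvalues are averaged over all frames;
#' anisotropy and asphericity are evaluated at the ensemble-mean eigenvalues
#' (the averages sit inside those formulas); prolateness is the ensemble
#' mean of the per-frame ratio; `r12 = <l1>/<l2>`, `r13 = <l1>/<l3>`.
#' Standard errors come from block averaging: the trajectory is split into
#' `nBlocks` contiguous blocks, every descriptor is recomputed per block,
#' and the spread of block values gives `stderr = sd(blocks)/sqrt(nBlocks)`.
#'
#' @param spectra result of [ringSpectra()] (or a list with an
#'   `eigenvalues` matrix).
#' @param nBlocks number of contiguous blocks (>= 2).
#' @return one-row data.frame with each descriptor and its `_se` companion,
#'   plus `n_frames` and `n_blocks`.
#' @export
shapeSummary <- function(spectra, nBlocks = 5L) {
  ev <- spectra$eigenvalues
  nBlocks <- as.integer(nBlocks)
  if (nBlocks < 2L)
    rlError("nBlocks must be >= 2 (stderr undefined for one block)",
            "ringlink_usage_error")
  if (nrow(ev) < nBlocks)
    rlError("need at least nBlocks frames", "ringlink_insufficient_data_error")
  central <- descriptorSet(ev)
  cut <- floor(seq(0, nrow(ev), length.out = nBlocks + 1))
  blocks <- t(vapply(seq_len(nBlocks), function(b)
    descriptorSet(ev[(cut[b] + 1):cut[b + 1], , drop = FALSE]),
    numeric(length(central))))
  se <- apply(blocks, 2, sd) / sqrt(nBlocks)
  out <- as.data.frame(as.list(central))
  for (nmq in names(central)) out[[paste0(nmq, "_se")]] <- se[[nmq]]
  out$n_frames <- nrow(ev)
  out$n_blocks <- nBlocks
  out
}
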