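#' @title Synthetic catenane generator
#' @name synthetic-catenane
#' @description Generates catenated two-ring bead trajectories with ions
#'   possessing the statistical structure the analysis assumes: stiff
#'   charged rings with tunable in-plane anisotropy and out-of-plane
#'   bending noise, a shell-Gaussian mixture of COM separations, a
#'   wrapped-Gaussian relative plane orientation, species-specific
#'   condensed ion shells plus a diffuse background, and scripted bridge
#'   ions. Every generated frame is a verified catenane (|Lk| = 1).
NULL

#' Construct a synthetic-catenane specification
#'
#' Defaults emulate a 65-bp DNA minicircle [2]-catenane in dilute sodium
#' solution: 130 beads per ring (one bead per backbone phosphate), ring
#' radius 3.5 nm (contour 2 pi R = 22 nm, i.e. 65 bp at 0.34 nm/bp),
#' in-plane moment ratio `r12 = 1/(1 - e^2)` of about 1.43, out-of-plane
#' bending noise giving a smallest eigenvalue near 0.3 nm^2, a single
#' separation well at 3.0 nm, near-perpendicular ring planes, and sodium
#' counterions plus NaCl salt with a condensed shell at 0.4 nm from the
#' beads. Each bead carries one negative unit charge; chloride is added so
#' the cell is exactly electroneutral.
#'
#' @param nBeads beads per ring (default 130).
#' @param ringRadius ring radius, nm (default 3.5).
#' @param eccentricity in-plane eccentricity in [0, 1): the bead
#'   second-moment ratio is `1/(1 - e^2)` (default 0.55).
#' @param bendAmplitude out-of-plane Fourier amplitude, nm; modes k = 2..5
#'   enter with amplitude `bendAmplitude / k^2`, giving
#'   `<lambda3^2> = bendAmplitude^2 * sum(1/k^4)` (default 1.9, about
#'   0.29 nm^2).
#' @param separationModel data.frame(weight, mean, sigma): shell-Gaussian
#'   mixture of COM separations, nm.
#' @param orientationModel c(mean, sigma) in degrees of the wrapped-Gaussian
#'   plane-normal angle, folded to [0, 90].
#' @param ions data.frame(species, valence, n_salt, condensed_fraction,
#'   shell_mu, shell_sigma). Neutralizing counterions (2 * nBeads /
#'   valence) are added to the first listed species.
#' @param bridgeScript data.frame(species, ion, start_frame, end_frame):
#'   scripted bridge ions (ion = 1-based index within the species; frames
#'   0-based, inclusive).
#' @param boxEdge cubic box edge, nm (default 30).
#' @param nFrames frames to generate (default 2000).
#' @param seed RNG seed (default 1).
#' @return a [SyntheticSpec-class] object.
#' @export
syntheticSpec <- function(nBeads = 130L, ringRadius = 3.5,
                          eccentricity = 0.55, bendAmplitude = 1.9,
                          separationModel = data.frame(weight = 1,
                                                       mean = 3.0,
                                                       sigma = 0.25),
                          orientationModel = c(mean = 85, sigma = 8),
                          ions = data.frame(species = "NA", valence = 1L,
                                            n_salt = 200L,
                                            condensed_fraction = 0.5,
                                            shell_mu = 0.40,
                                            shell_sigma = 0.01),
                          bridgeScript = data.frame(species = character(0),
                                                    ion = integer(0),
                                                    start_frame = integer(0),
                                                    end_frame = integer(0)),
                          boxEdge = 30, nFrames = 2000L, seed = 1L) {
  obj <- new("SyntheticSpec", nBeads = as.integer(nBeads),
             ringRadius = ringRadius, eccentricity = eccentricity,
             bendAmplitude = bendAmplitude,
             separationModel = separationModel,
             orientationModel = as.numeric(orientationModel),
             ions = ions, bridgeScript = bridgeScript,
             boxEdge = boxEdge, nFrames = as.integer(nFrames),
             seed = as.integer(seed))
  validObject(obj)
  obj
}

.templateCache <- new.env(parent = emptyenv())

# equal-arc bead template of an ellipse whose bead moment ratio equals
# 1/(1 - e^2), scaled so the polyline contour length is 2 pi R
ringTemplate <- function(nBeads, ringRadius, eccentricity) {
  key <- paste(nBeads, ringRadius, eccentricity, sep = "|")
  if (!is.null(.templateCache[[key]])) return(.templateCache[[key]])
  momentRatio <- function(rho) {
    t <- seq(0, 2 * pi, length.out = 4001)
    sp <- sqrt(rho^2 * sin(t)^2 + cos(t)^2)  # speed on ellipse (rho, 1)
    sum(rho^2 * cos(t)^2 * sp) / sum(sin(t)^2 * sp)
  }
  target <- 1 / (1 - eccentricity^2)
  rho <- if (eccentricity == 0) 1
  else stats::uniroot(function(x) momentRatio(x) - target,
                      interval = c(1, 1 / (1 - eccentricity^2) + 2),
                      tol = 1e-10)$root
  tt <- seq(0, 2 * pi, length.out = 20001)
  x <- rho * cos(tt)
  y <- sin(tt)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  ti <- stats::approx(s, tt, xout = max(s) * (seq_len(nBeads) - 1L) / nBeads)$y
  xy <- cbind(rho * cos(ti), sin(ti))
  per <- sum(sqrt(rowSums((xy[c(2:nBeads, 1L), ] - xy)^2)))
  xy <- xy * (2 * pi * ringRadius / per)
  xy <- sweep(xy, 2, colMeans(xy))
  .templateCache[[key]] <- xy
  xy
}

#' Bead coordinates of one synthetic ring
#'
#' Closed ellipse at equal arc spacing (bead moment ratio `1/(1 - e^2)`,
#' contour `2 pi R`) plus out-of-plane Fourier modes k = 2..5 with
#' amplitude `bendAmplitude / k^2` and standard-normal coefficients, in
#' the xy-plane centered at the origin. Uses the current RNG state.
#'
#' @param spec a [SyntheticSpec-class] object.
#' @param which ring id (0 or 1; both rings share one template).
#' @return `nBeads x 3` coordinate matrix, nm.
#' @export
makeRing <- function(spec, which = 0L) {
  xy <- ringTemplate(spec@nBeads, spec@ringRadius, spec@eccentricity)
  n <- spec@nBeads
  phase <- 2 * pi * (seq_len(n) - 1L) / n
  z <- numeric(n)
  for (k in 2:5) {
    z <- z + (spec@bendAmplitude / k^2) *
      (rnorm(1) * cos(k * phase) + rnorm(1) * sin(k * phase))
  }
  cbind(xy, z - mean(z))
}

rodrigues <- function(coords, axis, angle) {
  na <- sqrt(sum(axis^2))
  if (na < 1e-12 || abs(angle) < 1e-12) return(coords)
  k <- axis / na
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  Rm <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  coords %*% t(Rm)
}

smallestAxis <- function(coords) {
  gyrationSpectrum(gyrationTensor(coords))$vectors[, 3]
}

#' Assemble a linked two-ring frame at prescribed separation and angle
#'
#' Ring B is rotated so the angle between the two plane normals (smallest
#' gyration eigenvectors) equals `theta`, then translated along the
#' intersection line of the two ring planes to COM distance `r`; the
#' discrete Gauss linking number is verified to be +/-1. Both translation
#' senses are tried; failure after `retries` fresh attempts (the caller
#' may re-draw ring noise between attempts) raises the infeasible-geometry
#' error. A coincident-COM request (`r` near 0) is geometrically degenerate
#' for rigid rings and rejected.
#'
#' @param ringA,ringB `n x 3` bead matrices centered at the origin.
#' @param r requested COM separation, nm (> 0).
#' @param theta requested plane-normal angle, degrees in (0, 90].
#' @param retries direction/jitter attempts before giving up (default 20).
#' @return list with `A`, `B` (coordinate matrices; A centered at the
#'   origin), `r`, `theta`, `lk`.
#' @export
assembleFrame <- function(ringA, ringB, r, theta, retries = 20L) {
  if (r < 1e-6)
    rlError("coincident ring centers are geometrically infeasible for linked rigid rings",
            "ringlink_infeasible_geometry_error")
  vA <- smallestAxis(ringA)
  vB <- smallestAxis(ringB)
  u <- vB - sum(vB * vA) * vA
  if (sqrt(sum(u^2)) < 1e-8) {
    maj <- gyrationSpectrum(gyrationTensor(ringA))$vectors[, 1]
    u <- maj - sum(maj * vA) * vA
  }
  u <- u / sqrt(sum(u^2))
  th <- theta * pi / 180
  tgt <- cos(th) * vA + sin(th) * u
  if (sum(vB * tgt) < 0) vB <- -vB
  axis <- c(vB[2] * tgt[3] - vB[3] * tgt[2],
            vB[3] * tgt[1] - vB[1] * tgt[3],
            vB[1] * tgt[2] - vB[2] * tgt[1])
  ang <- acos(min(1, max(-1, sum(vB * tgt))))
  B0 <- rodrigues(ringB, axis, ang)
  L <- c(vA[2] * tgt[3] - vA[3] * tgt[2],
         vA[3] * tgt[1] - vA[1] * tgt[3],
         vA[1] * tgt[2] - vA[2] * tgt[1])
  nl <- sqrt(sum(L^2))
  L <- if (nl > 1e-8) L / nl else u
  spin <- 0
  for (att in seq_len(retries)) {
    Bs <- if (spin == 0) B0 else rodrigues(B0, tgt, spin)
    for (sgn in c(1, -1)) {
      B <- sweep(Bs, 2, sgn * r * L, "+")
      lk <- tryCatch(linkingNumber(ringA, B), error = function(e) NA_integer_)
      if (!is.na(lk) && abs(lk) == 1L)
        return(list(A = ringA, B = B, r = r, theta = theta, lk = lk))
    }
    spin <- runif(1, 0, 2 * pi)  # spin B about its normal and retry
  }
  rlError(sprintf("no linked placement found for r = %.3f nm, theta = %.1f deg",
                  r, theta),
          "ringlink_infeasible_geometry_error")
}

sampleShellGaussian <- function(model) {
  comp <- if (nrow(model) == 1L) 1L
  else sample.int(nrow(model), 1L, prob = model$weight)
  mu <- model$mean[comp]
  sg <- model$sigma[comp]
  M <- mu + 5 * sg
  repeat {
    x <- rnorm(1, mu, sg)
    if (x > 0 && runif(1) < min(1, (x / M)^2))
      return(list(r = x, component = comp))
  }
}

foldAngle <- function(deg) acos(abs(cos(deg * pi / 180))) * 180 / pi

ionCounts <- function(spec) {
  ringCharge <- 2L * spec@nBeads
  v1 <- spec@ions$valence[1]
  if (ringCharge %% v1 != 0L)
    rlError("ring charge not divisible by first species' valence",
            "ringlink_usage_error")
  nCounter <- ringCharge %/% v1
  nCation <- spec@ions$n_salt + ifelse(seq_len(nrow(spec@ions)) == 1L,
                                       nCounter, 0L)
  nCl <- sum(spec@ions$n_salt * spec@ions$valence)
  list(cation = as.integer(nCation), cl = as.integer(nCl),
       counter = nCounter)
}

#' Place ions around an assembled frame
#'
#' For each cation species, every ion is condensed with probability
#' `condensed_fraction`: it is placed at a distance drawn from
#' `Normal(shell_mu, shell_sigma)` (truncated positive) in a uniform
#' direction from a uniformly chosen ring bead; otherwise it is uniform in
#' the box. Chloride is always diffuse. Scripted bridge ions are pinned at
#' the midpoint of the closest inter-ring bead pair during their window
#' and are re-drawn outside it if a diffuse draw would accidentally bridge.
#' Placements falling outside the box are re-drawn.
#'
#' @param beads list with elements `A` and `B` (bead matrices, already in
#'   box coordinates).
#' @param spec a [SyntheticSpec-class] object.
#' @param frame 0-based frame index (drives the bridge script).
#' @return matrix of ion coordinates (cations in species order, then Cl).
#' @keywords internal
placeIons <- function(beads, spec, frame) {
  counts <- ionCounts(spec)
  box <- spec@boxEdge
  allBeads <- rbind(beads$A, beads$B)
  nb <- nrow(allBeads)
  bs <- spec@bridgeScript
  out <- list()
  for (s in seq_len(nrow(spec@ions))) {
    n <- counts$cation[s]
    frac <- spec@ions$condensed_fraction[s]
    mu <- spec@ions$shell_mu[s]
    sg <- spec@ions$shell_sigma[s]
    co <- matrix(0, n, 3)
    cond <- runif(n) < frac
    idx <- which(cond)
    while (length(idx)) {
      # shell placement: the drawn distance must be the minimum over ALL
      # beads (the chosen bead is the nearest), emulating excluded volume;
      # re-draw off-box or bead-overlapping placements
      m <- length(idx)
      b <- allBeads[sample.int(nb, m, replace = TRUE), , drop = FALSE]
      dir <- matrix(rnorm(3 * m), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      d <- rnorm(m, mu, sg)
      p <- b + dir * d
      dmin <- rowMinDistCpp(p, allBeads, c(0, 0, 0))
      bad <- d <= 0 | rowSums(p < 0 | p > box) > 0 | dmin < d - 1e-9
      if (any(!bad)) co[idx[!bad], ] <- p[!bad, , drop = FALSE]
      idx <- idx[bad]
    }
    # diffuse ions stay outside the condensation layer (DIFFUSE_EXCLUSION)
    idx <- which(!cond)
    while (length(idx)) {
      p <- matrix(runif(3 * length(idx), 0, box), ncol = 3)
      bad <- rowMinDistCpp(p, allBeads, c(0, 0, 0)) <= DIFFUSE_EXCLUSION
      if (any(!bad)) co[idx[!bad], ] <- p[!bad, , drop = FALSE]
      idx <- idx[bad]
    }
    scripted <- if (nrow(bs)) bs[bs$species == spec@ions$species[s], ]
    else bs
    for (b in seq_len(nrow(scripted))) {
      i <- scripted$ion[b]
      if (frame >= scripted$start_frame[b] && frame <= scripted$end_frame[b]) {
        k <- closestBeadPair(beads$A, beads$B)
        co[i, ] <- (beads$A[k[1], ] + beads$B[k[2], ]) / 2
      } else {
        # guarantee scripted ions bridge only in their window
        while (min(rowMinDistCpp(co[i, , drop = FALSE], beads$A,
                                 rep(box, 3))) <= 0.6 &&
               min(rowMinDistCpp(co[i, , drop = FALSE], beads$B,
                                 rep(box, 3))) <= 0.6) {
          co[i, ] <- runif(3, 0, box)
        }
      }
    }
    out[[s]] <- co
  }
  cl <- matrix(0, counts$cl, 3)
  idx <- seq_len(counts$cl)
  while (length(idx)) {
    p <- matrix(runif(3 * length(idx), 0, box), ncol = 3)
    bad <- rowMinDistCpp(p, allBeads, c(0, 0, 0)) <= DIFFUSE_EXCLUSION
    if (any(!bad)) cl[idx[!bad], ] <- p[!bad, , drop = FALSE]
    idx <- idx[bad]
  }
  do.call(rbind, c(out, list(cl)))
}

# diffuse ions are kept outside the condensation layer so the measured
# condensed fraction equals the Bernoulli condensation draw exactly
DIFFUSE_EXCLUSION <- 0.6

closestBeadPair <- function(A, B) {
  best <- c(1L, 1L)
  bd <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- rowSums(sweep(B, 2, A[i, ])^2)
    j <- which.min(d2)
    if (d2[j] < bd) { bd <- d2[j]; best <- c(i, j) }
  }
  best
}

syntheticAtomTable <- function(spec) {
  n <- spec@nBeads
  counts <- ionCounts(spec)
  beadNames <- rep(c("O1P", "O2P"), length.out = n)
  mkRing <- function(chain) {
    data.frame(atom_name = beadNames, residue_index = seq_len(n),
               residue_name = "DNB", chain_id = chain, ring_id =
                 if (chain == "A") 0L else 1L,
               species = "DNA", mass = BEAD_MASS,
               stringsAsFactors = FALSE)
  }
  ionRows <- function(species, count, start_res) {
    if (!count) return(NULL)
    data.frame(atom_name = species, residue_index = start_res + seq_len(count),
               residue_name = species, chain_id = "I", ring_id = -1L,
               species = species, mass = massFromSpecies(species),
               stringsAsFactors = FALSE)
  }
  rows <- list(mkRing("A"), mkRing("B"))
  res0 <- 0L
  for (s in seq_len(nrow(spec@ions))) {
    rows <- c(rows, list(ionRows(spec@ions$species[s], counts$cation[s], res0)))
    res0 <- res0 + counts$cation[s]
  }
  rows <- c(rows, list(ionRows("CL", counts$cl, res0)))
  tab <- do.call(rbind, rows)
  tab <- cbind(data.frame(atom_index = seq_len(nrow(tab)) - 1L), tab)
  rownames(tab) <- NULL
  tab
}

#' Generate a synthetic catenane trajectory
#'
#' Draws, for every frame, a COM separation from the shell-Gaussian
#' mixture, a folded wrapped-Gaussian plane angle, fresh out-of-plane ring
#' noise, assembles a verified |Lk| = 1 catenane centered in the box, and
#' places ions. Deterministic for a fixed seed. If `dir` is given, writes
#' `topology.pdb`, `traj.xyz` and `ground_truth.json` there.
#'
#' @param spec a [SyntheticSpec-class] object.
#' @param dir optional output directory.
#' @return list with `trajectory` (a [Trajectory-class]) and `groundTruth`
#'   (list: per-frame `separation`, `component`, `theta`; per-ring
#'   `targetEigenvalues`; `bridge` table with global 0-based atom indices;
#'   ion `counts`; `seed`).
#' @export
generateCatenane <- function(spec, dir = NULL) {
  set.seed(spec@seed)
  atoms <- syntheticAtomTable(spec)
  counts <- ionCounts(spec)
  n <- spec@nBeads
  nf <- spec@nFrames
  natoms <- nrow(atoms)
  coords <- array(0, dim = c(natoms, 3, nf))
  sep <- numeric(nf)
  comp <- integer(nf)
  theta <- numeric(nf)
  center <- rep(spec@boxEdge / 2, 3)
  template <- ringTemplate(n, spec@ringRadius, spec@eccentricity)
  inPlane <- colMeans(template^2)
  lam3 <- spec@bendAmplitude^2 * sum(1 / (2:5)^4)
  bs <- spec@bridgeScript
  inWindow <- function(f0) nrow(bs) > 0 &&
    any(f0 >= bs$start_frame & f0 <= bs$end_frame)
  for (f in seq_len(nf)) {
    sdraw <- sampleShellGaussian(spec@separationModel)
    th <- foldAngle(rnorm(1, spec@orientationModel[1],
                          spec@orientationModel[2]))
    th <- min(max(th, 1), 90)  # keep the plane intersection well defined
    # frames holding a scripted bridge need the rings in close contact so
    # the pinned midpoint lies within the bridge cutoff of both rings
    needGap <- if (inWindow(f - 1L)) 2 * DIFFUSE_EXCLUSION * 0.8 else Inf
    asm <- NULL
    for (attempt in 1:80) {
      cand <- tryCatch(assembleFrame(makeRing(spec, 0L), makeRing(spec, 1L),
                                     sdraw$r, th, retries = 5L),
                       error = function(e) NULL)
      if (is.null(cand)) next
      if (is.finite(needGap) &&
          min(rowMinDistCpp(cand$A, cand$B, c(0, 0, 0))) > needGap) next
      asm <- cand
      break
    }
    if (is.null(asm))
      rlError(sprintf("frame %d: no linked geometry for r = %.2f nm, theta = %.1f deg",
                      f - 1L, sdraw$r, th),
              "ringlink_infeasible_geometry_error")
    mid <- (colMeans(asm$A) + colMeans(asm$B)) / 2
    A <- sweep(asm$A, 2, center - mid, "+")
    B <- sweep(asm$B, 2, center - mid, "+")
    ions <- placeIons(list(A = A, B = B), spec, f - 1L)
    coords[, , f] <- rbind(A, B, ions)
    sep[f] <- sdraw$r
    comp[f] <- sdraw$component
    theta[f] <- th
  }
  traj <- new("Trajectory", atoms = atoms, coords = coords,
              box = matrix(spec@boxEdge, 3, nf),
              time = as.numeric(seq_len(nf) - 1L),
              frameIndex = seq_len(nf) - 1L)
  bridge <- spec@bridgeScript
  if (nrow(bridge)) {
    gidx <- integer(nrow(bridge))
    for (b in seq_len(nrow(bridge))) {
      s <- match(bridge$species[b], spec@ions$species)
      offset <- 2L * n + if (s > 1) sum(counts$cation[seq_len(s - 1L)]) else 0L
      gidx[b] <- offset + bridge$ion[b] - 1L
    }
    bridge$atom_index <- gidx
  }
  gt <- list(separation = sep, component = comp, theta = theta,
             targetEigenvalues = c(lambda1 = inPlane[[1]],
                                   lambda2 = inPlane[[2]],
                                   lambda3 = lam3),
             bridge = bridge,
             counts = counts,
             condensedFraction = setNames(spec@ions$condensed_fraction,
                                          spec@ions$species),
             seed = spec@seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeTopologyPDB(atoms, coords[, , 1], boxDims(traj, 1),
                     file.path(dir, "topology.pdb"))
    writeFramesXYZ(traj, file.path(dir, "traj.xyz"))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trajectory = traj, groundTruth = gt)
}
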