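#' @title Ionic atmosphere analysis
#' @name ionic-atmosphere
#' @description Ion-DNA radial distribution functions under the minimum-image
#'   convention, first-peak location, condensed-ion fractions, inter-ring
#'   residue contacts and ion-bridge detection with lifetimes.
NULL

#' Ionic strength of a salt composition
#'
#' `I = 1/2 sum c_i z_i^2` over all ionic species.
#'
#' @param concentration molar concentrations of the species.
#' @param valence signed valences (same length).
#' @return ionic strength, mol/l.
#' @export
ionicStrength <- function(concentration, valence) {
  stopifnot(length(concentration) == length(valence))
  sum(concentration * valence^2) / 2
}

#' Ion-target radial distribution function
#'
#' `g(r) = <n_pairs(r)> / (N_ion N_target 4 pi r^2 dr / V)` accumulated over
#' frames with minimum-image distances in the orthorhombic box
#' (`ideal_gas` normalization: g -> 1 at large r for uncorrelated placement).
#'
#' @param traj a [Trajectory-class] object.
#' @param ions 1-based atom indices of the ion species.
#' @param targets 1-based atom indices of the target group (e.g. the OP
#'   phosphate oxygens).
#' @param rMax maximum distance, nm (must be <= half the minimum box edge;
#'   default 1.2).
#' @param binWidth bin width, nm (default 0.002; the first condensation
#'   peak sits at a few hundredths of a nm from the surface).
#' @return a [RadialDistribution-class] object.
#' @export
ionRDF <- function(traj, ions, targets, rMax = 1.2, binWidth = 0.002) {
  if (!length(ions) || !length(targets))
    rlError("both ion and target selections must be non-empty",
            "ringlink_selection_error")
  if (rMax > min(traj@box) / 2)
    rlError("rMax exceeds half the minimum box edge", "ringlink_geometry_error")
  edges <- seq(0, rMax, by = binWidth)
  if (max(edges) < rMax) edges <- c(edges, max(edges) + binWidth)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  expected_scale <- 0
  for (i in seq_len(nFrames(traj))) {
    co <- traj@coords[, , i]
    counts <- counts + as.numeric(binPairsCpp(co[ions, , drop = FALSE],
                                              co[targets, , drop = FALSE],
                                              boxDims(traj, i), edges))
    expected_scale <- expected_scale + 1 / prod(boxDims(traj, i))
  }
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  shell <- 4 * pi * centers^2 * binWidth
  expected <- length(ions) * length(targets) * shell * expected_scale
  g <- counts / expected
  new("RadialDistribution", binEdges = edges, g = g, counts = counts,
      normalization = "ideal_gas", nUsed = nFrames(traj))
}

#' First peak of a radial distribution function
#'
#' Position and height of the first local maximum above `heightMin` after a
#' centered moving-average smoothing. An empty result (no qualifying peak)
#' is legal and returned as a zero-row data.frame.
#'
#' @param rd a [RadialDistribution-class] object.
#' @param heightMin minimum peak height (default 1.5).
#' @param smoothWindow smoothing window in bins (default 3).
#' @return data.frame with columns `r_peak` (nm) and `height` (0 or 1 rows).
#' @export
firstPeak <- function(rd, heightMin = 1.5, smoothWindow = 3L) {
  g <- movingAverage(ifelse(is.na(rd@g), 0, rd@g), as.integer(smoothWindow))
  r <- binCenters(rd)
  n <- length(g)
  for (i in seq_len(n)) {
    left <- if (i > 1) g[i - 1] else -Inf
    right <- if (i < n) g[i + 1] else -Inf
    if (g[i] > heightMin && g[i] >= left && g[i] > right)
      return(data.frame(r_peak = r[i], height = g[i]))
  }
  data.frame(r_peak = numeric(0), height = numeric(0))
}

#' Fraction of ions condensed on the DNA surface
#'
#' Per frame, the fraction of the given ions within `cutoff` of any DNA
#' atom (atom-to-atom minimum-image distance, i.e. distance from the
#' surface, not from the COM).
#'
#' @param traj a [Trajectory-class] object.
#' @param ions 1-based atom indices of the ion species.
#' @param dnaAtoms 1-based atom indices of the DNA (both rings by default
#'   usage).
#' @param cutoff condensation cutoff, nm (default 0.6, i.e. 6.0 Angstrom).
#' @return list with `perFrame` (numeric vector) and `mean`.
#' @export
condensedFraction <- function(traj, ions, dnaAtoms, cutoff = 0.6) {
  if (cutoff <= 0) rlError("cutoff must be > 0", "ringlink_usage_error")
  if (!length(ions))
    rlError("empty ion selection", "ringlink_selection_error")
  pf <- vapply(seq_len(nFrames(traj)), function(i) {
    co <- traj@coords[, , i]
    d <- rowMinDistCpp(co[ions, , drop = FALSE],
                       co[dnaAtoms, , drop = FALSE], boxDims(traj, i))
    mean(d <= cutoff)
  }, numeric(1))
  list(perFrame = pf, mean = mean(pf))
}

#' Inter-ring residue contacts with persistence
#'
#' Residue pairs (one residue per ring) with any interatomic minimum-image
#' distance at or below `cutoff`; persistence is the fraction of frames in
#' which a pair is in contact.
#'
#' @param traj a [Trajectory-class] object.
#' @param ringA,ringB 1-based atom indices of the two rings.
#' @param cutoff contact cutoff, nm (default 0.6 = the 6.0 Angstrom
#'   convention).
#' @return list with `perFrame` (list of two-column matrices of residue
#'   indices) and `persistence` (data.frame `residue_A`, `residue_B`,
#'   `n_frames`, `persistence`, sorted by descending persistence).
#' @export
contactResidues <- function(traj, ringA, ringB, cutoff = 0.6) {
  if (cutoff <= 0) rlError("cutoff must be > 0", "ringlink_usage_error")
  resA <- traj@atoms$residue_index[ringA]
  resB <- traj@atoms$residue_index[ringB]
  nf <- nFrames(traj)
  perFrame <- vector("list", nf)
  tally <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    co <- traj@coords[, , i]
    prs <- contactPairsCpp(co[ringA, , drop = FALSE],
                           co[ringB, , drop = FALSE],
                           boxDims(traj, i), cutoff)
    if (nrow(prs)) {
      rp <- unique(cbind(resA[prs[, 1]], resB[prs[, 2]]))
      perFrame[[i]] <- rp
      keys <- paste(rp[, 1], rp[, 2], sep = "_")
      for (k in keys)
        assign(k, (if (exists(k, tally)) get(k, tally) else 0L) + 1L, tally)
    } else {
      perFrame[[i]] <- matrix(integer(0), 0, 2)
    }
  }
  keys <- ls(tally)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
    nfr <- vapply(keys, function(k) get(k, tally), integer(1))
    persistence <- data.frame(residue_A = as.integer(parts[, 1]),
                              residue_B = as.integer(parts[, 2]),
                              n_frames = as.integer(nfr),
                              persistence = nfr / nf)
    persistence <- persistence[order(-persistence$persistence,
                                     persistence$residue_A,
                                     persistence$residue_B), ]
    rownames(persistence) <- NULL
  } else {
    persistence <- data.frame(residue_A = integer(0), residue_B = integer(0),
                              n_frames = integer(0), persistence = numeric(0))
  }
  list(perFrame = perFrame, persistence = persistence)
}

#' Detect ion bridges between the two rings
#'
#' An ion bridges when it is simultaneously within `cutoff` of at least one
#' atom of each ring. Events are maximal frame intervals per ion, tolerating
#' interruptions of at most `maxGap` frames; the survival-time distribution
#' of event lifetimes is returned alongside.
#'
#' @param traj a [Trajectory-class] object.
#' @param ions 1-based atom indices of the ion species.
#' @param ringA,ringB 1-based atom indices of the two rings.
#' @param cutoff bridge cutoff, nm (default 0.6).
#' @param maxGap tolerated interruption, frames (default 0 = strict).
#' @return list with `events` (data.frame `ion`, `start_frame`, `end_frame`,
#'   `lifetime`, plus partner residue lists) and `survival` (data.frame
#'   `lifetime`, `n_events`, `fraction_surviving`).
#' @export
ionBridges <- function(traj, ions, ringA, ringB, cutoff = 0.6, maxGap = 0L) {
  if (cutoff <= 0) rlError("cutoff must be > 0", "ringlink_usage_error")
  nf <- nFrames(traj)
  bridging <- matrix(FALSE, length(ions), nf)
  for (i in seq_len(nf)) {
    co <- traj@coords[, , i]
    dA <- rowMinDistCpp(co[ions, , drop = FALSE],
                        co[ringA, , drop = FALSE], boxDims(traj, i))
    dB <- rowMinDistCpp(co[ions, , drop = FALSE],
                        co[ringB, , drop = FALSE], boxDims(traj, i))
    bridging[, i] <- dA <= cutoff & dB <= cutoff
  }
  events <- list()
  resA <- traj@atoms$residue_index[ringA]
  resB <- traj@atoms$residue_index[ringB]
  for (k in seq_along(ions)) {
    on <- which(bridging[k, ])
    if (!length(on)) next
    # split into maximal runs tolerating gaps <= maxGap
    breaks <- which(diff(on) > maxGap + 1L)
    starts <- on[c(1L, breaks + 1L)]
    ends <- on[c(breaks, length(on))]
    for (e in seq_along(starts)) {
      fr <- starts[e]:ends[e]
      mids <- fr[bridging[k, fr]]
      pa <- pb <- integer(0)
      for (i in mids) {
        co <- traj@coords[, , i]
        ion <- co[ions[k], , drop = FALSE]
        pa <- union(pa, resA[rowMinDistCpp(co[ringA, , drop = FALSE], ion,
                                           boxDims(traj, i)) <= cutoff])
        pb <- union(pb, resB[rowMinDistCpp(co[ringB, , drop = FALSE], ion,
                                           boxDims(traj, i)) <= cutoff])
      }
      events[[length(events) + 1L]] <- data.frame(
        ion = ions[k],
        start_frame = traj@frameIndex[starts[e]],
        end_frame = traj@frameIndex[ends[e]],
        lifetime = ends[e] - starts[e] + 1L,
        partners_A = I(list(sort(pa))),
        partners_B = I(list(sort(pb))))
    }
  }
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(ion = integer(0), start_frame = integer(0),
                  end_frame = integer(0), lifetime = integer(0))
  lt <- events$lifetime
  survival <- if (length(lt)) {
    u <- sort(unique(lt))
    data.frame(lifetime = u,
               n_events = vapply(u, function(x) sum(lt == x), integer(1)),
               fraction_surviving = vapply(u, function(x) mean(lt >= x),
                                           numeric(1)))
  } else data.frame(lifetime = integer(0), n_events = integer(0),
                    fraction_surviving = numeric(0))
  list(events = events, survival = survival)
}
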