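test_that("ionic strength arithmetic covers mono- and divalent salts", {
  expect_equal(ionicStrength(c(0.26, 0.26), c(1, -1)), 0.26)
  # CaCl2: I = (4 c_Ca + c_Cl) / 2
  expect_equal(ionicStrength(c(0.070, 0.140), c(2, -1)), 0.210)
  expect_equal(ionicStrength(c(0.140, 0.280), c(2, -1)), 0.420)
  expect_error(ionicStrength(c(0.1), c(1, -1)))
})

test_that("minimum-image distances agree with a 27-image brute-force oracle", {
  set.seed(2)
  box <- c(3, 4, 5)
  A <- matrix(runif(30, 0, 3), ncol = 3)
  B <- matrix(runif(45, 0, 5), ncol = 3)
  oracle <- function(a, b) {
    best <- Inf
    for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
      d <- a - (b + c(ix, iy, iz) * box)
      best <- min(best, sqrt(sum(d^2)))
    }
    best
  }
  want <- vapply(seq_len(nrow(A)), function(i)
    min(vapply(seq_len(nrow(B)), function(j) oracle(A[i, ], B[j, ]),
               numeric(1))), numeric(1))
  got <- ringlink:::rowMinDistCpp(A, B, box)
  expect_equal(got, want, tolerance = 1e-12)

  # binned pair counts against the same oracle
  edges <- seq(0, 1.4, by = 0.2)
  alld <- c(vapply(seq_len(nrow(A)), function(i)
    vapply(seq_len(nrow(B)), function(j) oracle(A[i, ], B[j, ]), numeric(1)),
    numeric(nrow(B))))
  want2 <- as.numeric(table(cut(alld, edges, right = FALSE)))
  got2 <- as.numeric(ringlink:::binPairsCpp(A, B, box, edges))
  expect_equal(got2, want2)
})

test_that("RDF of uniformly placed ions converges to 1 and pair counting is symmetric", {
  set.seed(6)
  box <- 6
  nI <- 150; nT <- 120; nf <- 12
  at <- rbind(mkAtoms(nT), mkAtoms(0L, 0L, nI)[, ])
  at$atom_index <- seq_len(nrow(at)) - 1L
  frames <- lapply(seq_len(nf), function(i)
    matrix(runif(3 * (nI + nT), 0, box), ncol = 3))
  tr <- mkTraj(frames, at, box = rep(box, 3))
  ions <- which(at$ring_id == -1L)
  targets <- which(at$ring_id == 0L)
  rd <- ionRDF(tr, ions, targets, rMax = 2.5, binWidth = 0.05)
  rc <- binCenters(rd)
  outer_half <- rc > 1.25
  expect_lt(abs(mean(rd@g[outer_half]) - 1), 0.01)
  expect_true(all(abs(rd@g - 1) < 3 / sqrt(pmax(rd@counts, 1)) + 0.5))

  swapped <- ionRDF(tr, targets, ions, rMax = 2.5, binWidth = 0.05)
  expect_equal(swapped@g, rd@g, tolerance = 1e-12)

  expect_error(ionRDF(tr, ions, targets, rMax = 4),
               class = "ringlink_geometry_error")
  expect_error(ionRDF(tr, integer(0), targets),
               class = "ringlink_selection_error")
})

test_that("RDF resolves an exact shell as a single spike bin", {
  at <- mkAtoms(1L, 0L, 60L)
  set.seed(10)
  d <- 0.31
  dirs <- matrix(rnorm(180), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  frames <- list(rbind(c(5, 5, 5), sweep(dirs * d, 2, c(5, 5, 5), "+")))
  tr <- mkTraj(frames, at, box = c(10, 10, 10))
  rd <- ionRDF(tr, 2:61, 1L, rMax = 1, binWidth = 0.02)
  expect_equal(sum(rd@counts > 0), 1L)
  expect_equal(sum(rd@counts), 60)
  expect_lt(abs(binCenters(rd)[which(rd@counts > 0)] - d), 0.02)
})

test_that("first peak: Gaussian shell position, flat g empty, inner of two shells", {
  mkrd <- function(g, edges) new("RadialDistribution", binEdges = edges,
                                 g = g, counts = round(g * 100 + 1),
                                 normalization = "ideal_gas", nUsed = 1)
  edges <- seq(0, 1, by = 0.01)
  rc <- (head(edges, -1) + tail(edges, -1)) / 2
  shell <- 1 + 8 * exp(-(rc - 0.4)^2 / (2 * 0.03^2))
  fp <- firstPeak(mkrd(shell, edges))
  expect_lt(abs(fp$r_peak - 0.4), 0.011)

  expect_equal(nrow(firstPeak(mkrd(rep(1, length(rc)), edges))), 0L)

  two <- 1 + 6 * exp(-(rc - 0.16)^2 / (2 * 0.02^2)) +
             9 * exp(-(rc - 0.39)^2 / (2 * 0.02^2))
  fp2 <- firstPeak(mkrd(two, edges))
  expect_lt(abs(fp2$r_peak - 0.16), 0.011)  # inner shell wins even if lower
})

test_that("condensed fraction hits the 0/1 limits and the generator contract", {
  th <- 2 * pi * (0:19) / 20
  ring <- cbind(2 + cos(th), 2 + sin(th), 2)
  at <- mkAtoms(20L, 0L, 10L)
  near <- sweep(matrix(rnorm(30, sd = 0.05), ncol = 3), 2,
                ring[1, ], "+")
  far <- matrix(19.5 + runif(30, 0, 0.4), ncol = 3)
  tr1 <- mkTraj(list(rbind(ring, near)), at, box = c(20, 20, 20))
  expect_equal(condensedFraction(tr1, 21:30, 1:20, cutoff = 0.6)$mean, 1)
  tr0 <- mkTraj(list(rbind(ring, far)), at, box = c(40, 40, 40))
  expect_equal(condensedFraction(tr0, 21:30, 1:20, cutoff = 0.6)$mean, 0)

  g <- smallRun()
  tr <- g$trajectory
  at2 <- atomData(tr)
  na <- resolveSelection(at2, species = "NA")
  cf <- condensedFraction(tr, na, resolveSelection(at2, species = "DNA"))
  p <- g$groundTruth$condensedFraction[["NA"]]
  nDraw <- length(na) * nFrames(tr)
  expect_lt(abs(cf$mean - p), 3 * sqrt(p * (1 - p) / nDraw))
})

test_that("inter-ring contacts: empty when far, engineered pair has top persistence", {
  th <- 2 * pi * (0:11) / 12
  A <- cbind(cos(th), sin(th), 0)
  B <- cbind(cos(th), sin(th), 0)
  at <- mkAtoms(12L, 12L)
  farB <- sweep(B, 2, c(5, 0, 0), "+")
  trFar <- mkTraj(list(rbind(A, farB)), at, box = c(20, 20, 20))
  ctFar <- contactResidues(trFar, 1:12, 13:24, cutoff = 0.6)
  expect_equal(nrow(ctFar$persistence), 0L)

  # residue 3 of ring A engineered next to residue 7 of ring B in 4/5 frames
  # (placed along the outward normal so no other bead is within the cutoff)
  frames <- lapply(1:5, function(f) {
    Bk <- sweep(B, 2, c(5, 0, 0), "+")
    if (f <= 4) Bk[7, ] <- A[3, ] * 1.3
    rbind(A, Bk)
  })
  trC <- mkTraj(frames, at, box = c(20, 20, 20))
  ct <- contactResidues(trC, 1:12, 13:24, cutoff = 0.6)
  expect_equal(ct$persistence$residue_A[1], 3L)
  expect_equal(ct$persistence$residue_B[1], 7L)
  expect_equal(ct$persistence$persistence[1], 0.8)
})

test_that("ion bridges: spanning, empty, gap tolerance and scripted recovery", {
  th <- 2 * pi * (0:11) / 12
  A <- cbind(cos(th), sin(th), 0)
  B <- sweep(cbind(cos(th), sin(th), 0), 2, c(0, 0, 0.8), "+")
  at <- mkAtoms(12L, 12L, 2L)
  mid <- (A[1, ] + B[1, ]) / 2
  nf <- 10
  frames <- lapply(1:nf, function(f) {
    ion1 <- if (f %in% c(3:5, 7:9)) mid else c(8, 8, 8)
    rbind(A, B, ion1, c(9, 9, 9))
  })
  tr <- mkTraj(frames, at, box = c(20, 20, 20))
  br0 <- ionBridges(tr, 25:26, 1:12, 13:24, cutoff = 0.6, maxGap = 0)
  ev <- br0$events
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start_frame, c(2L, 6L))
  expect_equal(ev$end_frame, c(4L, 8L))
  expect_equal(ev$lifetime, c(3L, 3L))
  expect_true(all(ev$ion == 25L))

  # one-frame interruption is absorbed with maxGap = 1
  br1 <- ionBridges(tr, 25:26, 1:12, 13:24, cutoff = 0.6, maxGap = 1)
  expect_equal(nrow(br1$events), 1L)
  expect_equal(br1$events$lifetime, 7L)
  expect_equal(br1$survival$fraction_surviving[1], 1)

  # always-bridging ion spans the trajectory; far ions contribute nothing
  frames2 <- lapply(1:nf, function(f) rbind(A, B, mid, c(9, 9, 9)))
  tr2 <- mkTraj(frames2, at, box = c(20, 20, 20))
  br2 <- ionBridges(tr2, 25:26, 1:12, 13:24)
  expect_equal(nrow(br2$events), 1L)
  expect_equal(br2$events$lifetime, nf)
  expect_equal(br2$events$start_frame, 0L)

  # partner residues include the beads actually within the cutoff
  expect_true(1L %in% br2$events$partners_A[[1]])
})
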