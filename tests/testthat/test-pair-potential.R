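test_that("center of mass matches the brute-force mean and midpoint cases", {
  set.seed(3)
  co <- matrix(rnorm(90), ncol = 3)
  expect_equal(centerOfMass(co, 1:30), colMeans(co), tolerance = 1e-12)
  two <- rbind(c(1, 1, 1), c(3, 5, 7))
  expect_equal(centerOfMass(two, 1:2), c(2, 3, 4))
  th <- 2 * pi * (0:49) / 50
  ring <- cbind(1 + cos(th), 2 + sin(th), 3)
  expect_equal(centerOfMass(ring, 1:50), c(1, 2, 3), tolerance = 1e-12)
  expect_error(centerOfMass(co, integer(0)), class = "ringlink_selection_error")
})

test_that("separation series is exact for rigid translations and warns on wrap artifacts", {
  th <- 2 * pi * (0:11) / 12
  A <- cbind(cos(th), sin(th), 0)
  B <- cbind(cos(th), 0, sin(th)) + matrix(rep(c(1.5, 0, 0), each = 12), ncol = 3)
  at <- mkAtoms(12L, 12L)
  frames <- lapply(0:4, function(k) rbind(A, B) + k * 0.1)
  tr <- mkTraj(frames, at, box = c(10, 10, 10))
  ser <- separationSeries(tr, 1:12, 13:24)
  expect_equal(ser$r, rep(1.5, 5), tolerance = 1e-12)

  # separation beyond half the box edge suggests missing unwrapping
  Bfar <- sweep(B, 2, c(8, 0, 0), "+")
  trf <- mkTraj(list(rbind(A, Bfar)), at, box = c(10, 10, 10))
  expect_warning(separationSeries(trf, 1:12, 13:24), "half the shortest box")
})

test_that("COM pair distribution is shell-normalized to unity and matches brute-force binning", {
  set.seed(21)
  for (rep in 1:4) {
    r <- abs(rnorm(5000, mean = 3, sd = 0.4))
    rd <- comPairDistribution(r, binWidth = 0.05)
    rc <- binCenters(rd)
    expect_lt(abs(sum(rd@g * 4 * pi * rc^2 * 0.05) - 1), 1e-6)
    expect_equal(sum(rd@counts), length(r))
    # brute-force histogram oracle, bin by bin
    oracle <- as.numeric(table(cut(r, rd@binEdges, right = FALSE,
                                   include.lowest = FALSE)))
    expect_equal(rd@counts, oracle)
  }

  delta <- comPairDistribution(rep(2.6001, 500), binWidth = 0.05)
  expect_equal(sum(delta@counts > 0), 1L)
  expect_error(comPairDistribution(numeric(0)),
               class = "ringlink_insufficient_data_error")
})

test_that("uniform-in-shell samples give a flat g(r)", {
  set.seed(8)
  r1 <- 2; r2 <- 4
  u <- runif(2e5)
  r <- (u * (r2^3 - r1^3) + r1^3)^(1 / 3)  # exact inverse-CDF oracle
  rd <- comPairDistribution(r, binWidth = 0.1)
  inside <- binCenters(rd) > r1 + 0.1 & binCenters(rd) < r2 - 0.1
  g <- rd@g[inside]
  expect_lt(max(abs(g - mean(g))) / mean(g), 0.05)
})

test_that("effective potential: -ln g with min shift, missing bins, scale invariance", {
  # counts proportional to r^2 => exactly flat g => betaV identically 0
  edges <- seq(2, 3, by = 0.05)
  rc <- (head(edges, -1) + tail(edges, -1)) / 2
  counts <- rc^2 * 1000
  rd <- new("RadialDistribution", binEdges = edges,
            g = counts / (sum(counts) * 4 * pi * rc^2 * 0.05),
            counts = counts, normalization = "pair_density",
            nUsed = sum(counts))
  ep <- effectivePotential(rd)
  expect_lt(max(abs(ep@betaV)), 1e-10)

  # scaling all counts leaves the shifted potential unchanged
  rd2 <- rd
  rd2@counts <- rd@counts * 7
  rd2@g <- rd@g  # g is count-shape invariant after normalization
  expect_equal(effectivePotential(rd2)@betaV, ep@betaV)

  # zero-count bins become NA, never infinite
  counts3 <- counts
  counts3[5] <- 0
  g3 <- counts3 / (sum(counts3) * 4 * pi * rc^2 * 0.05)
  rd3 <- new("RadialDistribution", binEdges = edges, g = g3, counts = counts3,
             normalization = "pair_density", nUsed = sum(counts3))
  ep3 <- effectivePotential(rd3)
  expect_true(is.na(ep3@betaV[5]))
  expect_true(all(is.finite(ep3@betaV[-5])))
})

test_that("a Gaussian shell series yields a quadratic well with curvature 1/sigma^2", {
  set.seed(5)
  mu <- 3; sigma <- 0.25
  # shell-Gaussian sampling oracle: p(r) ~ r^2 exp(-(r-mu)^2/(2 sigma^2))
  n <- 2e5
  r <- numeric(0)
  while (length(r) < n) {
    x <- rnorm(n, mu, sigma)
    keep <- x > 0 & runif(n) < (x / (mu + 5 * sigma))^2
    r <- c(r, x[keep])
  }
  r <- r[1:n]
  rd <- comPairDistribution(r, binWidth = 0.05)
  ep <- effectivePotential(rd)
  sel <- which(is.finite(ep@betaV) & abs(ep@r - mu) < 1.5 * sigma)
  fit <- lm(ep@betaV[sel] ~ I((ep@r[sel] - mu)^2))
  expect_equal(unname(coef(fit)[2]), 1 / (2 * sigma^2), tolerance = 0.2)
})

test_that("minima detection resolves a bimodal mixture and merges sub-threshold barriers", {
  set.seed(9)
  n <- 4e4
  comp <- sample(1:2, n, TRUE, prob = c(0.6, 0.4))
  mus <- c(2.6, 3.4); sg <- 0.15
  r <- rnorm(n, mus[comp], sg)
  rd <- comPairDistribution(r, binWidth = 0.05)
  ep <- findMinima(effectivePotential(rd), smoothWindow = 5,
                   barrierMin = 0.2)
  mins <- potentialMinima(ep)
  expect_equal(nrow(mins), 2L)
  expect_lt(abs(mins$r[1] - mus[1]), 0.05 + 1e-9)
  expect_lt(abs(mins$r[2] - mus[2]), 0.05 + 1e-9)
  expect_equal(mins$rank[1], 1L)  # heavier component is the global minimum
  expect_equal(mins$r, sort(mins$r))  # reported in ascending separation

  # a barrier threshold above the actual barrier merges the wells
  barrier <- max(ep@betaV[ep@r > mus[1] & ep@r < mus[2]], na.rm = TRUE)
  epm <- findMinima(effectivePotential(rd), smoothWindow = 5,
                    barrierMin = barrier + 1)
  expect_equal(nrow(potentialMinima(epm)), 1L)
})

test_that("state assignment recovers mixture components and honors the boundary tie rule", {
  set.seed(13)
  n <- 2e4
  comp <- sample(1:2, n, TRUE)
  mus <- c(2.4, 3.6); sg <- 0.15  # wells 8 sigma apart
  r <- rnorm(n, mus[comp], sg)
  rd <- comPairDistribution(r, binWidth = 0.05)
  ep <- findMinima(effectivePotential(rd))
  st <- assignStates(r, ep)
  expect_gt(mean(st == comp), 0.95)

  # single minimum: everything is state 1
  ep1 <- findMinima(effectivePotential(comPairDistribution(rnorm(5e3, 3, 0.2))))
  expect_true(all(assignStates(rnorm(100, 3, 0.2), ep1) == 1L))

  # a frame exactly on the basin boundary goes to the lower-r state
  ok <- which(is.finite(ep@betaV))
  v <- ringlink:::movingAverage(ep@betaV[ok], ep@smoothWindow)
  rg <- ep@r[ok]
  seg <- which(rg >= mus[1] & rg <= mus[2])
  boundary <- rg[seg[which.max(v[seg])]]
  expect_equal(assignStates(c(boundary), ep), 1L)
  expect_equal(assignStates(c(boundary + 1e-9), ep), 2L)
})
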