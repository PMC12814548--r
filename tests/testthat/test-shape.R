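test_that("gyration tensor reproduces analytic point-set spectra", {
  th <- 2 * pi * (0:99) / 100
  circ <- cbind(cos(th), sin(th), 0)
  expect_equal(gyrationSpectrum(gyrationTensor(circ))$values, c(0.5, 0.5, 0),
               tolerance = 1e-12)

  line <- cbind(seq(-1, 1, length.out = 9), 0, 0)
  sp <- gyrationSpectrum(gyrationTensor(line))
  expect_equal(sp$values[2:3], c(0, 0), tolerance = 1e-12)

  a <- 1.7
  oct <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0),
               c(0, -a, 0), c(0, 0, a), c(0, 0, -a))
  expect_equal(gyrationSpectrum(gyrationTensor(oct))$values,
               rep(a^2 / 3, 3), tolerance = 1e-12)

  expect_error(gyrationTensor(matrix(0, 0, 3)),
               class = "ringlink_selection_error")
  expect_error(gyrationSpectrum(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               class = "ringlink_numerical_error")
})

test_that("Rg agrees with the brute-force mean-squared-distance oracle and is rigid-motion invariant", {
  set.seed(101)
  for (rep in 1:5) {
    pts <- matrix(rnorm(3 * 40), ncol = 3)
    sp <- gyrationSpectrum(gyrationTensor(pts))
    ctr <- colMeans(pts)
    rg2_brute <- mean(rowSums(sweep(pts, 2, ctr)^2))  # independent oracle
    expect_equal(sp$Rg^2, rg2_brute, tolerance = 1e-10)

    Rm <- randomRotation()
    shift <- rnorm(3, sd = 5)
    moved <- sweep(pts %*% t(Rm), 2, shift, "+")
    sp2 <- gyrationSpectrum(gyrationTensor(moved))
    expect_equal(sp2$values, sp$values, tolerance = 1e-8)
    expect_equal(sp2$I1, sp$I1, tolerance = 1e-8)
  }
})

test_that("eigen conventions: descending order, deterministic signs, tie handling", {
  sp <- gyrationSpectrum(diag(c(1, 2, 3)))
  expect_equal(sp$values, c(3, 2, 1))
  expect_true(all(abs(crossprod(sp$vectors) - diag(3)) < 1e-8))

  dg <- gyrationSpectrum(diag(c(1, 1, 0)))
  expect_equal(dg$values, c(1, 1, 0))
  expect_true(all(abs(crossprod(dg$vectors) - diag(3)) < 1e-8))
  # in-plane eigenvectors orthogonal to z
  expect_lt(max(abs(dg$vectors[3, 1:2])), 1e-8)
})

test_that("shape descriptors respect their analytic bounds and limits", {
  expect_equal(shapeAnisotropy(c(5, 0, 0)), 1)
  expect_equal(shapeAnisotropy(c(2, 2, 2)), 0)
  expect_equal(prolateness(c(3, 3, 0)), -0.25)
  expect_equal(prolateness(c(3, 0, 0)), 2)
  expect_equal(prolateness(c(4, 4, 4)), 0)
  expect_equal(asphericity(c(2, 2, 2)), 0)
  expect_error(shapeAnisotropy(c(0, 0, 0)),
               class = "ringlink_undefined_shape_error")
  expect_error(prolateness(c(0, 0, 0)),
               class = "ringlink_undefined_shape_error")

  set.seed(7)
  for (rep in 1:200) {
    lam <- sort(rexp(3), decreasing = TRUE)
    k2 <- shapeAnisotropy(lam)
    expect_gte(k2, 0)
    expect_lte(k2, 1)
    s <- prolateness(lam)
    expect_gte(s, -0.25 - 1e-12)
    expect_lte(s, 2 + 1e-12)
    expect_gte(asphericity(lam), 0)
  }
})

test_that("shape summary: central values, zero spread for rigid ensembles, block errors", {
  th <- 2 * pi * (0:63) / 64
  circ <- cbind(3 * cos(th), 3 * sin(th), 0)
  frames <- replicate(20, circ, simplify = FALSE)
  at <- mkAtoms(64L)
  tr <- mkTraj(frames, at, box = c(20, 20, 20))
  sm <- shapeSummary(ringSpectra(tr, seq_len(64)), nBlocks = 5)
  expect_equal(sm$Rg, 3 * sqrt(2) / sqrt(2), tolerance = 1e-10)  # Rg of a circle = R
  expect_equal(sm$Rg_se, 0, tolerance = 1e-12)
  expect_equal(sm$kappa2_se, 0, tolerance = 1e-12)
  expect_equal(sm$r12, 1, tolerance = 1e-10)

  expect_error(shapeSummary(ringSpectra(tr, seq_len(64)), nBlocks = 1),
               class = "ringlink_usage_error")
  expect_error(shapeSummary(list(eigenvalues = matrix(1, 3, 3)), nBlocks = 5),
               class = "ringlink_insufficient_data_error")
})

test_that("block-averaged stderr matches the i.i.d. expectation within sampling noise", {
  set.seed(12)
  n <- 1000
  lam3 <- 0.3 + 0.05 * rnorm(n)
  ev <- cbind(7 + 0.2 * rnorm(n), 5 + 0.2 * rnorm(n), pmax(lam3, 0.01))
  sm <- shapeSummary(list(eigenvalues = ev), nBlocks = 5)
  # for i.i.d. data, block stderr of the lambda1 mean ~ sd/sqrt(n)
  expect_equal(sm$lambda1_se, 0.2 / sqrt(n), tolerance = 0.6)
  expect_gt(sm$lambda1_se, 0)
})

test_that("ensemble means recover the generator's target eigenvalue triple within 3 stderr", {
  g <- smallRun()
  tr <- g$trajectory
  ring <- resolveSelection(atomData(tr), ringId = 0)
  sm <- shapeSummary(ringSpectra(tr, ring), nBlocks = 5)
  tgt <- g$groundTruth$targetEigenvalues
  for (i in 1:3) {
    nm <- paste0("lambda", i)
    # 3 block-stderr plus the first-order target's own truncation floor
    # (O(bend^2/nBeads), well below 0.1% of the eigenvalue)
    expect_lt(abs(sm[[nm]] - tgt[[nm]]),
              3 * sm[[paste0(nm, "_se")]] + 1e-3 * tgt[[nm]])
  }
  expect_true(sm$kappa2 >= 0 && sm$kappa2 <= 1)
  expect_gte(sm$r12, 1)
  expect_gte(sm$r13, sm$r12)
})
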