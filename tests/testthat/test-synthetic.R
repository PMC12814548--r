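test_that("ring builder: circle limit, moment-ratio contract, closure, bend response", {
  spec0 <- syntheticSpec(nBeads = 64L, ringRadius = 2, eccentricity = 0,
                         bendAmplitude = 0, nFrames = 1L)
  set.seed(1)
  ring <- makeRing(spec0)
  sp <- gyrationSpectrum(gyrationTensor(ring))
  # (R^2/2, R^2/2, 0) up to the contour-true polygon inflation (pi/n)^2/3
  expect_equal(sp$values, c(2, 2, 0), tolerance = 2e-3)

  specE <- syntheticSpec(nBeads = 130L, ringRadius = 3.5, eccentricity = 0.6,
                         bendAmplitude = 0, nFrames = 1L)
  ringE <- makeRing(specE)
  spE <- gyrationSpectrum(gyrationTensor(ringE))
  expect_equal(spE$values[1] / spE$values[2], 1 / (1 - 0.6^2),
               tolerance = 0.01)
  # contour preserved and closure bond indistinguishable from the mean bond
  bonds <- sqrt(rowSums((ringE[c(2:130, 1), ] - ringE)^2))
  expect_equal(sum(bonds), 2 * pi * 3.5, tolerance = 1e-6)
  expect_lt(abs(bonds[130] - mean(bonds)) / mean(bonds), 0.01)

  # out-of-plane noise raises the smallest eigenvalue monotonically
  lam3 <- vapply(c(0.3, 0.9, 1.9, 3), function(b) {
    sp <- syntheticSpec(nBeads = 130L, bendAmplitude = b, nFrames = 1L)
    set.seed(99)
    mean(vapply(1:25, function(i)
      gyrationSpectrum(gyrationTensor(makeRing(sp)))$values[3], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(lam3) > 0))
  # and matches the analytic expectation bend^2 * sum(1/k^4)
  expect_equal(lam3[3], 1.9^2 * sum(1 / (2:5)^4), tolerance = 0.25)
})

test_that("frame assembly hits requested separation and angle with |Lk| = 1", {
  spec <- syntheticSpec(nBeads = 64L, ringRadius = 1, eccentricity = 0,
                        bendAmplitude = 0, nFrames = 1L)
  set.seed(2)
  asm <- assembleFrame(makeRing(spec), makeRing(spec), r = 1, theta = 90)
  expect_equal(abs(asm$lk), 1L)
  expect_equal(sqrt(sum((colMeans(asm$A) - colMeans(asm$B))^2)), 1,
               tolerance = 1e-9)
  vA <- gyrationSpectrum(gyrationTensor(asm$A))$vectors[, 3]
  vB <- gyrationSpectrum(gyrationTensor(asm$B))$vectors[, 3]
  expect_equal(relativeAngle(vA, vB), 90, tolerance = 0.5)

  # coincident centers are degenerate for rigid rings
  expect_error(assembleFrame(makeRing(spec), makeRing(spec), r = 0, theta = 90),
               class = "ringlink_infeasible_geometry_error")
  # far beyond the maximal linked separation
  expect_error(assembleFrame(makeRing(spec), makeRing(spec), r = 12, theta = 90),
               class = "ringlink_infeasible_geometry_error")
})

test_that("fixed (r, theta) round-trips as constant series through the pipeline", {
  spec <- syntheticSpec(nBeads = 48L, ringRadius = 2, eccentricity = 0.3,
                        bendAmplitude = 0,
                        separationModel = data.frame(weight = 1, mean = 1.8,
                                                     sigma = 1e-12),
                        orientationModel = c(mean = 80, sigma = 1e-12),
                        nFrames = 15L, seed = 4L,
                        ions = data.frame(species = "NA", valence = 1L,
                                          n_salt = 0L,
                                          condensed_fraction = 0,
                                          shell_mu = 0.4, shell_sigma = 0.01))
  g <- generateCatenane(spec)
  tr <- g$trajectory
  at <- atomData(tr)
  rA <- resolveSelection(at, ringId = 0)
  rB <- resolveSelection(at, ringId = 1)
  ser <- suppressWarnings(separationSeries(tr, rA, rB))
  expect_lt(diff(range(ser$r)), 1e-6)
  os <- orientationSeries(tr, rA, rB)
  expect_lt(diff(range(os$theta)), 1e-3)
})

test_that("electroneutrality holds exactly for the derived ion counts", {
  for (ions in list(
    data.frame(species = "NA", valence = 1L, n_salt = 37L,
               condensed_fraction = 0.4, shell_mu = 0.4, shell_sigma = 0.01),
    data.frame(species = "CA", valence = 2L, n_salt = 12L,
               condensed_fraction = 0.6, shell_mu = 0.25, shell_sigma = 0.01),
    data.frame(species = c("MG", "NA"), valence = c(2L, 1L),
               n_salt = c(9L, 5L), condensed_fraction = c(0.7, 0.4),
               shell_mu = c(0.16, 0.4), shell_sigma = c(0.01, 0.01)))) {
    spec <- syntheticSpec(nBeads = 30L, nFrames = 1L, ions = ions)
    counts <- ringlink:::ionCounts(spec)
    charge <- sum(counts$cation * ions$valence) - counts$cl - 2L * 30L
    expect_identical(charge, 0L)
  }
})

test_that("generation is deterministic: same seed gives identical files, different seed differs", {
  mk <- function(seed, dir) {
    spec <- syntheticSpec(nBeads = 24L, nFrames = 3L, seed = seed,
                          ions = data.frame(species = "NA", valence = 1L,
                                            n_salt = 5L,
                                            condensed_fraction = 0.5,
                                            shell_mu = 0.4,
                                            shell_sigma = 0.01))
    generateCatenane(spec, dir = dir)
  }
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  d3 <- file.path(tempdir(), "gen3")
  g1 <- mk(5L, d1); g2 <- mk(5L, d2); g3 <- mk(6L, d3)
  expect_identical(g1$trajectory@coords, g2$trajectory@coords)
  for (f in c("topology.pdb", "traj.xyz", "ground_truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_false(identical(g1$trajectory@coords, g3$trajectory@coords))
})

test_that("every generated frame is a verified catenane", {
  g <- smallRun()
  tr <- g$trajectory
  at <- atomData(tr)
  rA <- resolveSelection(at, ringId = 0)
  rB <- resolveSelection(at, ringId = 1)
  lks <- vapply(seq_len(nFrames(tr)), function(i) {
    co <- frameCoords(tr, i)
    linkingNumber(co[rA, ], co[rB, ])
  }, integer(1))
  expect_true(all(abs(lks) == 1L))
})

test_that("invalid specifications are rejected", {
  expect_error(syntheticSpec(eccentricity = 1.2), "eccentricity")
  expect_error(syntheticSpec(nBeads = 4), "nBeads")
  expect_error(syntheticSpec(separationModel = data.frame(weight = 1,
                                                          mean = -2,
                                                          sigma = 0.1)),
               "separationModel")
  expect_error(syntheticSpec(ions = data.frame(species = "XX", valence = 3L,
                                               n_salt = 1L,
                                               condensed_fraction = 0.5,
                                               shell_mu = 0.3,
                                               shell_sigma = 0.01)),
               "valence")
})
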