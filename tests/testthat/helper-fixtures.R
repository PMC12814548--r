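# Fixtures and independent oracles shared across the suite.

# minimal atom table: two rings of nA/nB beads plus nIon ions of one species
mkAtoms <- function(nA, nB = 0L, nIon = 0L, ionSpecies = "NA") {
  rows <- list()
  if (nA) rows$A <- data.frame(
    atom_name = rep(c("O1P", "O2P"), length.out = nA),
    residue_index = seq_len(nA), residue_name = "DNB", chain_id = "A",
    ring_id = 0L, species = "DNA", mass = 94.97)
  if (nB) rows$B <- data.frame(
    atom_name = rep(c("O1P", "O2P"), length.out = nB),
    residue_index = seq_len(nB), residue_name = "DNB", chain_id = "B",
    ring_id = 1L, species = "DNA", mass = 94.97)
  if (nIon) rows$I <- data.frame(
    atom_name = ionSpecies, residue_index = seq_len(nIon),
    residue_name = ionSpecies, chain_id = "I", ring_id = -1L,
    species = ionSpecies, mass = 23)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cbind(data.frame(atom_index = seq_len(nrow(tab)) - 1L), tab)
}

# Trajectory from a list of nAtoms x 3 coordinate matrices
mkTraj <- function(frames, atoms, box = c(10, 10, 10)) {
  nf <- length(frames)
  co <- array(0, dim = c(nrow(atoms), 3, nf))
  for (i in seq_len(nf)) co[, , i] <- frames[[i]]
  new("Trajectory", atoms = atoms, coords = co,
      box = matrix(box, 3, nf), time = as.numeric(seq_len(nf) - 1L),
      frameIndex = seq_len(nf) - 1L)
}

# random rigid rotation matrix
randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# exact geometric linked test for two unit circles: A in the xy-plane at the
# origin; B with center cc and plane normal (cos(phi), sin(phi), 0).
# Independent of the package's Gauss-sum path.
circlesLinkedOracle <- function(phi, cc) {
  if (abs(cc[3]) > 1) return(FALSE)
  s <- sqrt(1 - cc[3]^2)
  p1 <- c(cc[1] - s * sin(phi), cc[2] + s * cos(phi))
  p2 <- c(cc[1] + s * sin(phi), cc[2] - s * cos(phi))
  xor(sum(p1^2) < 1, sum(p2^2) < 1)
}

# small default generator runs, built once and cached for the whole suite
.fixtureCache <- new.env()

smallRun <- function() {
  if (is.null(.fixtureCache$small)) {
    spec <- syntheticSpec(nFrames = 150L, seed = 42L,
                          ions = data.frame(species = "NA", valence = 1L,
                                            n_salt = 40L,
                                            condensed_fraction = 0.5,
                                            shell_mu = 0.40,
                                            shell_sigma = 0.01))
    .fixtureCache$small <- generateCatenane(spec)
  }
  .fixtureCache$small
}
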