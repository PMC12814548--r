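# ringlink

Conformational and ionic-atmosphere analysis of catenated ring-polymer
trajectories — two mechanically interlocked (linking number ±1) closed
molecules, such as double-stranded DNA minicircles forming a
[2]-catenane, together with their mobile counterions.

The package is aimed at people analysing molecular-dynamics
trajectories of linked stiff polyelectrolyte rings, and at anyone who
needs a ground-truthed synthetic testbed for such analyses. It
implements, as one tested pipeline:

* **Shape**: per-ring gyration tensors
  `S = (1/N) Σ rᵢ rᵢᵀ` with descending eigenvalues
  `λ₁² ≥ λ₂² ≥ λ₃²`, the radius of gyration `Rg = √(λ₁²+λ₂²+λ₃²)`,
  relative shape anisotropy
  `κ² = 1 − 3(λ₁²λ₂²+λ₂²λ₃²+λ₃²λ₁²)/(λ₁²+λ₂²+λ₃²)² ∈ [0,1]`,
  asphericity `b = λ₁² − (λ₂²+λ₃²)/2`, prolateness
  `S = ⟨(3λ₁²−I₁)(3λ₂²−I₁)(3λ₃²−I₁)/I₁³⟩ ∈ [−0.25, 2]`, and the
  ratios `r₁₂`, `r₁₃`, all with block-averaged standard errors.
* **Effective potential**: the center-of-mass separation series of the
  two rings, its shell-normalized pair distribution `g(r)`, the
  potential of mean force `βV_eff(r) = −ln g(r)` (minimum shifted to
  zero), multi-well minima and plateau detection, and per-frame basin
  assignment with per-state shape tables.
* **Orientation**: the ring-plane angle
  `θ = arccos|p̂_A·p̂_B| ∈ [0°, 90°]` and 2D Gaussian-kernel density
  maps of `(r, θ)` on standardized axes, with mode extraction.
* **Ions**: minimum-image radial distribution functions of cations
  versus named atom groups (phosphate OP = {O1P, O2P}, minor-groove
  O2, major-groove O4/O6), first-peak location, condensed-ion
  fractions within the 0.6 nm (6.0 Å) surface cutoff, inter-ring
  residue contacts with persistence, and ion-bridge events with
  lifetime survival distributions.
* **Rigid-ring model**: the insertion density
  `p(r) = (r/πR²)·arccos(r/2R)` on `[0, 2R]`, its mode, the discrete
  Gauss linking number of closed polylines (Rcpp), and a Monte Carlo
  sampler of two perpendicular rigid linked circles that reproduces
  the "COM distance ≈ 1.5 R" geometric argument as an approximate
  histogram mode.
* **Synthetic generator**: seeded, electroneutral two-ring bead
  trajectories with tunable in-plane anisotropy, out-of-plane bending
  noise, separation mixtures, orientation distributions, condensed
  ion shells, and scripted bridge ions — every frame a verified
  catenane, every drawn quantity stored as ground truth.

Trajectory input: PDB topologies (via bio3d), multi-model PDB, DCD,
and a plain XYZ dialect with an explicit `box=… unit=…` header.
Everything is nm internally. Outputs are TSV tables and JSON
summaries; `runAnalysis()` orchestrates
`generate | shape | potential | orientation | ions | rigidmodel`
from one YAML config and writes a provenance manifest per run
(a thin CLI wrapper lives in `inst/scripts/ringlink-cli.R`).

## A worked example

Generate a 400-frame synthetic 65-bp-like catenane in dilute NaCl and
run the main analyses:

```r
library(ringlink)

spec <- syntheticSpec(nFrames = 400L, seed = 11L)
g    <- generateCatenane(spec)
traj <- g$trajectory
traj
#> Trajectory: 920 atoms x 400 frames
#>   ring 0: 130 atoms; ring 1: 130 atoms; other: 660
#>   non-ring species: CL:200 NA:460
#>   box (frame 1): 30.00 x 30.00 x 30.00 nm

at    <- atomData(traj)
ringA <- resolveSelection(at, ringId = 0)
ringB <- resolveSelection(at, ringId = 1)

sm <- shapeSummary(ringSpectra(traj, ringA), nBlocks = 5)
sprintf("Rg = %.2f nm; kappa2 = %.3f; b = %.2f nm^2; S = %.3f; r12 = %.2f",
        sm$Rg, sm$kappa2, sm$b, sm$S, sm$r12)
#> "Rg = 3.53 nm; kappa2 = 0.236; b = 4.51 nm^2; S = -0.138; r12 = 1.43"

ser <- separationSeries(traj, ringA, ringB)
ep  <- findMinima(effectivePotential(comPairDistribution(ser)))
potentialMinima(ep)
#>       r     depth rank
#> 1 2.975 0.2061659    1

m <- densityMode(kde2D(orientationSeries(traj, ringA, ringB)))
sprintf("preferred state: r = %.2f nm, theta = %.1f deg", m[["r"]], m[["theta"]])
#> "preferred state: r = 2.93 nm, theta = 87.2 deg"

na <- resolveSelection(at, species = "NA")
condensedFraction(traj, na, resolveSelection(at, species = "DNA"))$mean
#> [1] 0.50025

mc <- mcLinkedCircles(R = 1, nSamples = 1e5, seed = 11)
sprintf("rigid-ring MC mode = %.2f R; insertion-density mode = %.3f R",
        mc$mode, insertionMode(1))
#> "rigid-ring MC mode = 1.35 R; insertion-density mode = 1.304 R"
```

Reading the numbers: the ring is a slightly anisotropic oblate disk
(`κ² ≈ 0.24`, negative prolateness), as a stiff catenated minicircle
should be; the effective potential has a single well at the
generator's 3.0 nm separation (the `−2σ²/μ` shell shift puts the
smoothed minimum a fraction of a bin below it); the two ring planes
stay nearly perpendicular (≈ 87°); half the sodium is condensed, as
parameterized; and the rigid-linked-circle construction puts the most
probable COM distance a bit above 1.3 R from the analytic insertion
density and ≈ 1.35 R from the full Monte Carlo — the geometric
"about 1.5 R" figure as an approximate mode.

## Package layout

```
R/                 S4 classes (Trajectory, RadialDistribution,
                   EffectivePotential, DensityMap, SyntheticSpec),
                   one file per analysis stage
src/               Rcpp kernels: Gauss linking number, linked-circle
                   Monte Carlo, minimum-image pair binning
tests/testthat/    unit, property and acceptance suites
scripts/           acceptance.R
vignettes/         the methods vignette (model, parameters, design
                   decisions, limitations)
inst/scripts/      command-line wrapper around runAnalysis()
```
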