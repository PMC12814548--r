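---
title: "Conformational and ionic-atmosphere analysis of catenated ring polymers"
author: "ringlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational and ionic-atmosphere analysis of catenated ring polymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringlink)
```

# The system and the questions

A [2]-catenane is a pair of closed ring molecules that are mechanically
interlocked: no covalent bond joins them, but their linking number
(the signed count of crossings of the two closed curves) is fixed at
&plusmn;1 and cannot change without breaking a ring. For stiff, highly
charged rings such as double-stranded DNA minicircles of 65-180 base
pairs, the conformation of the linked pair is governed by a balance of
bending stiffness, electrostatic repulsion between the two
polyanions, and the screening and bridging action of the surrounding
counterions. `ringlink` implements the complete trajectory-analysis
pipeline for such systems:

* per-ring **gyration-tensor shape descriptors** with block-averaged
  uncertainties;
* the **effective potential of mean force** along the ring-ring
  center-of-mass (COM) separation, with multi-well detection and
  per-frame state assignment;
* joint **separation-orientation kernel density maps**;
* the **ionic atmosphere**: ion-DNA radial distribution functions,
  condensed-ion fractions, inter-ring contacts and divalent ion
  bridges;
* an analytic **rigid-linked-ring model** with a Monte Carlo sampler
  constrained by the discrete Gauss linking number;
* a **synthetic catenane generator** that gives every stage of the
  pipeline a testable, ground-truthed input without atomistic MD data.

All lengths are nanometres internally; file readers convert at the
boundary (PDB fields are Angstrom and are divided by ten on input; the
package's XYZ dialect declares its unit in the frame header). The
familiar 6.0-Angstrom contact convention therefore appears as 0.6 nm.

# Shape descriptors

For each ring and frame the gyration tensor is the uniform-weight
dyadic about the ring centroid,
$$S = \frac{1}{N}\sum_{i=1}^{N} \mathbf{r}_i \mathbf{r}_i^{T},$$
with eigenvalues $\lambda_1^2 \ge \lambda_2^2 \ge \lambda_3^2$ and
$R_g = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}$. Uniform weighting
follows the dyadic as written; a mass-weighted variant is available
through the `weights` arguments but is off by default. From the
ensemble-mean eigenvalues the pipeline reports

* relative shape anisotropy
  $\kappa^2 = 1 - 3\,\frac{\langle\lambda_1^2\rangle\langle\lambda_2^2\rangle+\langle\lambda_2^2\rangle\langle\lambda_3^2\rangle+\langle\lambda_3^2\rangle\langle\lambda_1^2\rangle}{(\langle\lambda_1^2\rangle+\langle\lambda_2^2\rangle+\langle\lambda_3^2\rangle)^2} \in [0,1]$
  (0 for spherical symmetry, 1 for a collinear array);
* asphericity
  $b = \langle\lambda_1^2\rangle - \tfrac12(\langle\lambda_2^2\rangle+\langle\lambda_3^2\rangle) \ge 0$
  in nm^2^;
* prolateness
  $S = \big\langle (3\lambda_1^2-I_1)(3\lambda_2^2-I_1)(3\lambda_3^2-I_1)/I_1^3 \big\rangle \in [-0.25, 2]$,
  negative for oblate (disk-like), positive for prolate (rod-like)
  shapes;
* the eigenvalue ratios $r_{12}$ and $r_{13}$.

The placement of the ensemble averages follows each formula's standard form:
$\kappa^2$ and $b$ are evaluated at the ensemble-mean eigenvalues
(averages inside), while the prolateness averages the whole per-frame
ratio (average outside). Statistical errors use block averaging: the
trajectory is cut into `nBlocks` contiguous blocks (default 5 — the
method names no canonical count; five gives a usable spread estimate
for the trajectory lengths at hand), every descriptor is recomputed
per block, and the standard error is the spread of block values over
$\sqrt{n_\mathrm{blocks}}$. For derived descriptors this block-wise
recomputation propagates the nonlinearity honestly, at the price of a
slightly conservative error for strongly correlated series.

Eigen-decomposition conventions: eigenvalues descending, each
eigenvector's sign fixed by making its first non-negligible component
positive, and exact ties ordered by a lexicographic eigenvector rule,
so repeated analyses are bit-reproducible.

# Effective potential of the COM separation

The separation series $r(t)$ between the two ring centroids is
measured without minimum-image wrapping: the catenane is one bonded
object and frames must be whole-molecule unwrapped (the reader cannot
know a format's wrapping policy, so unwrapping is a stated
precondition and suspicious jumps above 1 nm/frame only raise a
warning). The radial pair distribution of the bonded pair is the
shell-normalized histogram
$$g(r) = \frac{h(r)}{n\,4\pi r_c^2 \Delta r},$$
which integrates to one by construction, and the effective potential
is $\beta V_\mathrm{eff}(r) = -\ln g(r)$, shifted so its minimum over
defined bins is zero (a PMF is defined up to an additive constant).
Empty bins are reported as missing, never as infinities. The default
bin width of 0.05 nm resolves the 2-5 nm separation range into ~60
bins. Whether the observable should carry the $4\pi r^2$ shell factor
is a modelling choice; the bare normalized histogram is available via
`normalization = "histogram"`.

Minima are located on a centered moving average (default 5 bins) of
the potential; adjacent minima merge unless separated by a barrier of
at least `barrierMin` (default 0.2 kBT), and stretches flatter than
`plateauTol` (0.15 kBT) over at least `plateauSpan` (6) bins are
flagged as plateaus. These thresholds make explicit what is otherwise
an identification "by eye"; all are configurable. States are the
basins between barrier maxima, numbered by ascending separation, with
boundary frames assigned to the lower-separation state, and per-state
shape tables allow the stretched-versus-contracted comparison of
separation basins.

# Separation-orientation maps

The relative orientation of the two rings is
$\theta = \arccos|\hat p_A \cdot \hat p_B| \in [0^\circ, 90^\circ]$,
where the eigenvector sign ambiguity is folded away by the absolute
value. The plane normal (the eigenvector of the *smallest*
eigenvalue) is the default axis, because "perpendicular rings" is a
statement about ring planes; the major in-plane axis (largest
eigenvalue) is selectable — the two conventions answer different
geometric questions and both are exposed.

The joint density of $(r, \theta)$ uses a 2D Gaussian kernel
$K(x,x') = \exp(-\|x-x'\|^2/2\sigma^2)$ on **axis-standardized**
coordinates: nm and degrees are incommensurate, so each axis is
divided by its sample standard deviation before the isotropic kernel
is applied; $\sigma = 0.3$ standardized units by default, on a
100&times;100 grid spanning the data range padded by $3\sigma$. The
grid density is renormalized to integrate to one. The reported mode
is the grid argmax with deterministic tie-breaking (smallest $r$,
then smallest $\theta$).

A statistical caveat documented here deliberately: the grid cell
shrinks proportionally to the data spread while the sampling
fluctuation of a KDE mode shrinks only with effective sample size, so
"mode correct to one grid cell" is an estimator property that needs
tens of thousands of frames at the default bandwidth — at a
2000-frame study size the mode's sampling scatter is comparable to a
little over one cell. The estimator is unbiased for the symmetric
orientation models used here; only its scatter is at issue.

# Ionic atmosphere

Ion-target radial distribution functions use the ideal-gas
normalization
$$g_{ij}(r) = \frac{\langle n_\mathrm{pairs}(r)\rangle}{N_i N_j\, 4\pi r^2 \Delta r / V},$$
with minimum-image distances in the orthorhombic box (triclinic cells
are rejected explicitly), so $g \to 1$ for uncorrelated placement.
Fine default bins (0.002 nm up to 1.2 nm) resolve condensation peaks
at a few hundredths of a nanometre. Atom groups follow the AMBER-style
naming: `OP` is the union of O1P and O2P phosphate oxygens, O2 probes
the minor groove, O4/O6 the major groove; the group map is
configurable for other dialects (OP1/OP2). The first peak is the first
local maximum above height 1.5 after 3-bin smoothing; no qualifying
peak is a legal empty result.

Condensation and contacts use atom-to-atom minimum distances (the
"surface" of the molecule, not its COM) with the 0.6 nm cutoff.
An ion bridge is an ion simultaneously within the cutoff of both
rings; events are maximal per-ion frame intervals tolerating
interruptions up to `maxGap` frames (default 0, strict), and the full
lifetime survival distribution is reported rather than a single
"long-lived" threshold, which the underlying method does not define.

# The rigid-linked-ring model

For a rigid circle of radius $R$, the probability density of a
perpendicular topological insertion at in-plane distance $r$ is
$$p(r) = \frac{r}{\pi R^2}\arccos\!\Big(\frac{r}{2R}\Big), \qquad 0 \le r \le 2R,$$
vanishing at both ends with a mode near $1.30R$
(`insertionMode()`). This closed form is not exactly unit-normalized;
both the raw and the numerically normalized density are exposed.

The geometric claim that two perpendicular rigid linked circles put
their COM separation near $1.5R$ is validated by construction rather
than derivation, since no sampling measure accompanies the claim: ring
A is fixed, ring B's plane is perpendicular to A's (azimuth uniform),
its center is uniform in a half-width-$3R$ box, and a configuration is
accepted iff the discrete Gauss linking number of the two 64-segment
polygons is &plusmn;1. The linking number is the double sum of signed
solid-angle contributions over segment pairs, rounded to the nearest
integer; a sum further than 0.1 from an integer marks a degenerate
(touching) geometry. The sampler short-circuits provably equivalent
cases — disjoint convex hulls, and the parity of polygon B's crossings
through the planar region bounded by polygon A, which is homologically
identical to the Gauss integer — and falls back to the full double sum
inside the thin annulus where the two routes could differ; the test
suite asserts the equivalence on random configurations. The mode of
the accepted-distance histogram (bin $0.02R$, 5-bin smoothing) lands
near $1.35R$ under this measure: the $1.5R$ figure is reproduced as an
approximate mode, not an exact constant. Accepted distances are
bounded by $\sqrt{5}R$, and runs are bit-reproducible at a fixed seed.

# The synthetic generator: what it emulates, and what it does not

`syntheticSpec()`/`generateCatenane()` produce bead trajectories with
the statistical structure the analysis assumes. Defaults emulate a
65-bp minicircle catenane in dilute NaCl:

* **130 beads per ring**, one per backbone phosphate, each carrying
  one negative unit charge; ring radius 3.5 nm so the contour
  $2\pi R = 22$ nm matches 65 bp at 0.34 nm/bp. Chloride is added so
  the cell is exactly electroneutral, with neutralizing counterions
  assigned to the first cation species.
* **In-plane anisotropy**: beads lie at equal arc length on an
  ellipse whose axis ratio is solved numerically so that the bead
  second-moment ratio equals $1/(1-e^2)$ — the eccentricity parameter
  is *defined* through the moment ratio it produces. Equal-arc
  placement keeps every bond equal (a closed bead chain), which
  equal-angle placement would violate by over 20% at e = 0.6. The
  default e = 0.55 reproduces in-plane eigenvalue ratios around 1.43,
  typical of catenated short minicircles.
* **Out-of-plane bending**: Fourier modes $k = 2..5$ with amplitude
  $A/k^2$ and standard-normal coefficients, giving
  $\langle\lambda_3^2\rangle = A^2\sum_k k^{-4}$ analytically; the
  default $A = 1.9$ nm yields ~0.29 nm^2^. The ground truth stores
  this first-order target; its truncation error from
  eigenvalue mixing is $O(A^2/N_\mathrm{beads})$, well below 0.1%,
  which is the comparison floor used by the recovery tests.
* **Separation and orientation** are drawn i.i.d. per frame from a
  shell-Gaussian mixture and a folded wrapped-Gaussian; frames carry
  no dynamics, so time-correlation analyses are out of the
  generator's scope by design. Each frame is assembled by rotating
  ring B to the exact drawn plane angle, translating it along the
  intersection line of the two ring planes to the exact drawn COM
  distance, and verifying the discrete linking number — every frame
  of every generated trajectory is a true catenane. A coincident-COM
  request is rejected: for rigid rings both plane crossings would sit
  symmetrically about the shared center, making the crossing parity
  even, so no linked placement exists (consistent with the excluded
  volume of real rings). Ring-rim contact, and hence ion bridging,
  is geometrically possible only at large separations (about
  $1.5R$-$2R$ for the default rings); scripting a bridge therefore
  requires a separation model in that range, and frames inside a
  bridge window are re-assembled until the inter-ring gap admits a
  midpoint within the cutoff of both rings.
* **Ions**: each cation is condensed with probability
  `condensed_fraction`, placed at a distance drawn from
  $N(\mu_\mathrm{shell}, \sigma_\mathrm{shell})$ from a uniformly
  chosen bead, with the drawn distance enforced as the *minimum* over
  all beads (a surrogate for excluded volume — without it, ions land
  arbitrarily close to neighbouring beads 0.17 nm apart and the
  $1/r^2$ RDF normalization amplifies those pairs into spurious
  near-zero peaks). Diffuse ions stay outside the 0.6 nm condensation
  layer, so the measured condensed fraction equals the Bernoulli
  parameter exactly. Species-specific shell distances (defaults: Mg
  0.16 nm, Ca 0.25 nm, Na 0.40 nm, sd 0.01 nm) emulate the *ordering*
  of binding modes — direct backbone contact for magnesium, looser
  association for sodium — not their chemistry; the sharp 0.01 nm
  shell keeps the analytic peak shift of the shell-normalized RDF
  ($2\sigma^2/\mu$) below one 0.002 nm bin. Scripted bridge ions are
  pinned at the midpoint of the closest inter-ring bead pair during
  their window and re-drawn outside it if a diffuse draw would
  accidentally bridge, so scripted intervals are recovered exactly.

Because the generator samples frames independently with exact
geometric control, passing its recovery tests demonstrates that the
analysis operators measure what they claim on data with known truth.
It does *not* demonstrate robustness to features of real MD data that
the generator omits: temporal correlation, sequence-dependent
flexibility, solvent structure, groove geometry, or force-field
specific ion chemistry. Absolute RDF peak positions of real systems,
in particular, emerge from atomistic force fields and are treated as
qualitative references only.

# Problem sizes and reproducibility

The package's own studies are sized for a single CPU: recovery suites
run on 2000-frame ensembles of ~900 atoms (a few tens of seconds
end-to-end), and the rigid-ring Monte Carlo uses 10^6^ accepted
samples (a few seconds) — enough to pin the smoothed histogram mode,
whose argmax over a broad peak is otherwise the noisiest quantity in
the suite. Every stochastic component takes an explicit seed;
generation, analysis tables and the Monte Carlo are bit-reproducible
at a fixed seed, and `runAnalysis()` writes a manifest (config hash,
seed, package version, input checksums) next to every output set.

# Known limitations

* Orthorhombic boxes only; triclinic input is rejected, not wrapped.
* Whole-molecule unwrapping is a precondition of the separation
  analysis, not a service of the reader.
* The KDE mode at default bandwidth needs large ensembles for
  cell-level accuracy (see above); marginal summaries stabilize much
  earlier.
* Block averaging assumes the block count divides the trajectory into
  segments long compared to the correlation time; for the generator's
  i.i.d. frames this is trivially true, for real MD it is the user's
  responsibility.
* The generator's electrostatics are bookkeeping (electroneutral
  counts), not energetics; nothing in it minimizes an energy.
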