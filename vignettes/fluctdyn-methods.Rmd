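---
title: "Comparative fluctuation dynamics: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative fluctuation dynamics: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctdyn)
```

# Scope

fluctdyn compares the conformational dynamics of a multidomain protein under
different binding states from molecular-dynamics ensembles. The motivating
application is the alphaV-beta3 integrin ectodomain head bound to the
wild-type (agonist) or a high-affinity mutant (antagonist) fibronectin FN10
repeat, plus the unliganded receptor as a control: three replicas per
system, analysed per replica and pooled. The package implements the
trajectory statistics for that comparison — distance-fluctuation
coordination, essential dynamics, generalized (mutual-information)
correlation, domain-orientation torsions, aromatic stacking geometry,
contact occupancy, conformational clustering and a Gaussian-network-model
control — together with synthetic-trajectory generators whose ground truth
is known exactly, so every stage can be validated end to end without the
microsecond simulation data, which are not redistributable at desk scale.

Everything internal is in Angstrom; nanometre values appear only at format
boundaries and in reports that conventionally print nm (cluster cutoffs,
cross-structure RMSD).

# Distance fluctuations

For residues (Calpha atoms) $i$ and $j$ with instantaneous distance
$r_{ij}(t)$,

$$\mathrm{DF}_{ij} \;=\; \big\langle\,(r_{ij} - \langle r_{ij}\rangle)^2\,\big\rangle ,$$

the time-averaged mean-square fluctuation of the pair distance. DF is zero
for any pair belonging to one rigid unit, however that unit translates or
rotates, which makes low DF a direct readout of mechanical coordination and
makes the statistic insensitive to imperfect global superposition.

Conventions chosen here, and why:

* **Population variance** (divide by $F$, not $F-1$): the bracket notation
  denotes a plain time average; the validation suite checks exact equality
  with a literal two-pass oracle, which fixes the convention.
* **Replica aggregation = mean of per-replica matrices**, not frame
  concatenation. Concatenation lets static offsets between replicas inflate
  DF even when each replica is internally rigid; averaging measures
  within-replica coordination only. Pooling is available via
  `aggregate = "concatenate"` since the alternative reading is defensible
  for replicas sampling one basin.
* **Two-pass accumulation** (mean distances first, then squared
  deviations): a one-pass second-moment recursion loses ~6 digits when
  fluctuations of order 0.1 A ride on distances of order 100 A; the
  two-pass form keeps the matrix accurate to ~1e-13 A^2 at the problem
  sizes used here, at the cost of a second sweep over frames. Memory stays
  O(N^2).

Per-residue RMSF is the companion statistic,
$\mathrm{RMSF}_i = \sqrt{\langle |\mathbf{x}_i - \langle\mathbf{x}_i\rangle|^2\rangle}$,
computed on superposed frames with the replica mean and between-replica
standard deviation reported. A heuristic flags trajectories that still
carry global motion: a probe frame is re-fitted to the mean structure, and
a warning is raised when the fit removes far more deviation than the six
rigid-body degrees of freedom could absorb by chance (factor
$0.5\sqrt{1-2/n}$ for $n$ atoms).

# Essential dynamics

PCA of the mass-unweighted 3N Calpha coordinate covariance over superposed
frames. Replicas are fitted to one common reference and concatenated for
the pooled analysis; passing a single replica gives the per-replica
analysis. Numerical conventions: population covariance; symmetric eigen
decomposition of the full 3N x 3N matrix (exact and fast up to the ~1100
particles of the motivating systems); eigenvalues clamped at zero below
-1e-8; each eigenvector's largest-magnitude component made positive so
signs are reproducible across platforms.

Sampling diagnostics follow standard practice:

* **Cosine content** of the mode-$k$ projection,
  $c_k = \frac{2}{F}\,\big(\sum_t p_t \cos(k\pi t/T)\big)^2 / \sum_t p_t^2$
  on a midpoint time grid (so a pure cosine gives exactly 1 and a constant
  exactly 0). Values near 1 mean the projection is indistinguishable from
  random diffusion — unconverged sampling.
* **Split-half subspace overlap**: the root-mean-square inner product
  (RMSIP) between the top-m eigenvectors of the two trajectory halves, 1
  for identical essential subspaces. Note that RMSIP of a *degenerate*
  spectrum is ill-defined; the validation uses well-separated synthetic
  spectra for exactly that reason.

# Generalized correlation from mutual information

Pearson cross-correlations of displacement vectors vanish for orthogonal
motions. The generalized correlation instead estimates the mutual
information $I$ between the 3-D displacement series of two atoms and maps
it to

$$r_{\mathrm{MI}} = \sqrt{1 - e^{-2I/3}} \in [0, 1],$$

the dimensionality-3 form appropriate for coordinate triplets; for jointly
Gaussian displacements with isotropic cross-correlation $\rho$ this equals
$|\rho|$, and it is insensitive to the relative orientation of the coupled
motions.

$I$ is estimated with the Kraskov-Stoegbauer-Grassberger k-nearest-
neighbour estimator, variant 1, Chebyshev (max-norm) distances, natural
logarithms, with $k = 6$ neighbours — the bias/variance compromise standard
at MD sample sizes. Implementation notes:

* Exact brute-force O(F^2) neighbour search in compiled code; at the
  default frame cap this is faster in practice than tree indexing at d = 6.
* Small negative estimates (finite-sample noise near independence) are
  clamped to 0 before the $r_{\mathrm{MI}}$ transform; the transform output
  is capped at 1. Identical series produce estimates that grow with F
  without bound, so the cap is the defined behaviour there.
* Exactly duplicated sample points make the k-th neighbour distance zero;
  the default fallback adds negligible jitter (1e-9 of the data sd, drawn
  from the caller's RNG stream) and re-estimates; `on_ties = "error"`
  fails instead.
* Each unordered atom pair is computed once and mirrored, so the matrix is
  symmetric by construction; per-replica matrices are averaged. The
  per-pair cost is quadratic in frames, so a stride subsamples frames to a
  default cap of 2000 per replica (logged); the stride is a parameter, not
  a hidden truncation.

# Domain axes, torsion angles and local geometry

**Inter-domain torsion.** The mutual orientation of two domains is the
dihedral of (tip_a, centroid_a, centroid_b, tip_b), each tip being the
domain centroid displaced by the domain's first gyration-tensor principal
axis; the magnitude is reported in [0, 180] degrees. This operationalises a
"torsion about the inter-domain axis" without reference to any particular
visualisation tool's convention, whose sign convention is not recoverable;
consequently absolute values are comparable only within one convention, and
*ranges* of the torsion series are the robust comparator. Axis signs are
handled intrinsically: the first frame orients each axis along the sign of
the projection skewness of its own atoms (falling back to the farthest
atom for skewness-free shapes), and later frames keep the sign whose
projection pattern overlaps the previous frame's. Both rules depend only on
the point sets, never on lab coordinates, so the series is invariant under
per-frame rigid motion of the whole system and cannot jump by 180 degrees —
two properties the test suite asserts numerically.

**Aromatic stacking.** Ring centroids are means of the ring heavy atoms;
ring planes are total-least-squares fits (smallest eigenvector of the ring
atom covariance); the interplanar angle is folded to [0, 90] degrees so it
is independent of atom order and normal sign. Residue pairs are classified
*paired* below 12 A centroid separation, and *stacked* (stacked or
T-shaped) inside the window 4.9-10.4 A and 1.2-89.9 degrees; both windows
are parameters. The tryptophan centroid uses all nine bicyclic heavy atoms
by default, with the six-membered ring alone as an option — the two
definitions shift centroids by a few tenths of an Angstrom, which is why
the ring-geometry validation tolerance is +/-0.3 A.

**Contacts.** Hydrogen bonds: donor-acceptor heavy-atom distance <= 3.5 A
and donor-H...acceptor angle >= 120 degrees when hydrogens exist, distance
only otherwise (MD-derived analyses often include force-field hydrogens;
crystal-derived ones rarely do — the criterion adapts and both cutoffs are
config keys). Salt bridges: any basic side-chain nitrogen (Arg NH1/NH2/NE,
Lys NZ, His ND1/NE2) within 4.0 A of a carboxylate oxygen. Occupancy is
the percentage of pooled frames in which the criterion holds, reported at
or above 1% by convention.

# Conformational clustering

The GROMOS greedy neighbour-count method: compute all-pairs frame RMSD on
the region of interest; the frame with most neighbours within the cutoff
seeds a cluster with those neighbours; remove and repeat. Ties in the
neighbour count are broken by the lowest frame index, making the partition
deterministic; cluster sizes are provably non-increasing in discovery
order; populations sum to exactly 100%. The intended application is
side-chain-region rotamer analysis (e.g. the eight-residue stretch around
the betaA-domain tryptophan, residues 124-131 of the beta chain) at a
0.2 nm cutoff, with 0.3 nm as the looser preset, on trajectories sampled
at ~5000 frames per replica. Pairwise RMSD uses per-pair proper-rotation
superposition on a fit selection defaulting to the analysis region itself
(local fitting — the natural choice for a side-chain region; global
fitting is one argument away, since the convention is not uniquely
determined by the problem statement). The O(F^2) matrix is computed in
compiled code; a stride and a hard frame cap guard the quadratic cost.

# Gaussian network model control

A truncated simulation construct is only trustworthy if truncation
preserves the collective mechanics. The GNM control compares the slow
modes of the complete crystal Calpha set against the construct subset:
Kirchhoff matrix with unit springs between Calpha pairs within a cutoff,
eigenmodes in ascending eigenvalue order, the single null mode excluded.
Per mode, the Brueschweiler collectivity
$\kappa = N^{-1}\exp(-\sum_i p_i \ln p_i)$ with $p_i = u_i^2/\sum u^2$
measures how many residues move together (1 = fully collective); "the two
slowest modes" are the two smallest non-zero eigenvalues, and their
cumulative contribution to overall mobility is their share of
$\sum_k 1/\lambda_k$, the GNM pseudo-inverse fluctuation weight. The
contact cutoff defaults to 10 A with a 7-13 A sensitivity table always
available, because slow-mode collectivity is cutoff-sensitive and no
single value is canonical. Disconnected contact graphs are refused with
the component sizes named, rather than silently yielding extra zero modes.

# Synthetic trajectories: what they do and do not establish

The generators produce the *analysable features* of MD ensembles with
exact ground truth:

* **Gaussian ensembles** — block atom covariance (within-block correlation,
  optional between-block correlation) applied i.i.d. to x, y, z. Ground
  truth for DF structure, RMSF ($\sigma\sqrt{3}$), PCA spectra and
  $r_{\mathrm{MI}} = |\rho|$.
* **Hinge sweeps** — two rigid domains, one rotated about a prescribed
  axis by a deterministic sweep $A\cos(\pi (f-1)/(F-1))$ covering
  $[-A, +A]$ exactly, so the measured torsion range is exactly $2A$; a
  sinusoid was chosen over a random walk precisely so the range is a
  constant of the construction, not a random variable. Noise is added in
  the lab frame after placement.
* **Ring pairs** — ideal hexagonal rings at exact centroid distance and
  interplanar angle; the packaged defaults of interest are the
  crystallographic antagonist-complex packing values (4.9 A, 25.8 deg).
* **Two-state switches** — i.i.d. Bernoulli choice between two
  conformations with known labels, the stand-in for rotamer flipping.
* **Tagged metal sites** — a carbonyl oxygen and one or two metal
  particles at prescribed separations; the defaults of interest are the
  crystallographic carbonyl-to-metal distances of the agonist-bound
  (14.6 A) and antagonist-bound (2.9 A) states.

All generators are pure functions of (spec, seed) and leave the caller's
RNG state untouched. What they deliberately lack: any force field,
solvent, thermostat, kinetics, or anharmonicity beyond the two-state
switch. A passing suite therefore establishes that the *estimators and
conventions* are correct — exact recovery of constructed truths, agreement
with closed forms and independent oracles, and the invariances (rigid
motion, rotation, ordering) that the statistics must respect. It does not
establish anything about the biology of a real trajectory; trajectory-level
published numbers (torsion ranges, variance fractions, occupancies,
metal-distance histograms, cluster populations) depend on microsecond
simulation data and are outside what desk-scale validation can or should
reproduce.

# Crystal-structure analyses

Structure-level comparisons need the deposited PDB entries, which the
package fetches on demand (`fetch_pdb()`, cached per user) rather than
redistributing. Cross-structure Calpha RMSD pairs residues by (chain role,
author residue number, insertion code) intersection, drops the unpaired
remainder with a logged count, and fits with a proper rotation before
measuring — the pairing convention is stated because published
apo-versus-complex deviations (~0.23-0.26 nm here) move by a few
hundredths of a nanometre under alternative pairings, which is exactly the
tolerance such comparisons should carry. Metal sites in the betaA domain
are identified by proximity to their canonical coordination shells
(ADMIDAS at the D126/D127 carboxylates, MIDAS at the S121/S123/E220 shell,
LIMBS at D158/N215/D217), a documented heuristic in place of hand-curated
atom serials.

# Problem sizes in the validation suite

The suite and the reproduction script run on synthetic fixtures sized for
exactness rather than realism: 50-atom ensembles at 2000 frames for the DF
oracle; 10000 samples for the mutual-information closed forms and the PCA
spectrum recovery; 500-frame switches and 20-frame random sets (50 seeds)
for clustering; 200-frame hinge sweeps. These sizes were chosen so each
statistic sits comfortably inside its stated tolerance with margin, and
the full suite completes in about a minute.

# Known limitations

* No XTC reader: binary trajectory input is DCD (or multi-model PDB);
  convert upstream.
* The KSG estimator's brute-force search is quadratic in frames; very long
  series must be strided (the default cap does this).
* The torsion convention is this package's own; absolute angles are not
  comparable across tools, only ranges and time structure.
* Contact detection uses geometric criteria only — no energies, no
  pi-cation models.
* GNM is isotropic (no anisotropic network model), with uniform springs.
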