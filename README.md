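# fluctdyn

Comparative fluctuation dynamics of molecular-dynamics ensembles in R.

Ligand binding can change what a receptor *does* without changing much of
what it *looks like*: in the alphaV-beta3 integrin ectodomain, the
agonist-bound and antagonist-bound crystal structures differ by only about
0.2 nm of Calpha RMSD, yet one complex drifts towards activation-competent
states while the other stays frozen. Telling those regimes apart requires
statistics of the trajectory, not of any single structure. fluctdyn
implements that comparative toolbox for structural-bioinformatics users
working with multi-replica MD of multidomain proteins:

- **Distance-fluctuation (DF) matrices** — the pairwise coordination
  statistic DF_ij = <(r_ij − <r_ij>)²>; low values mark mechanically
  coupled residue pairs, and the matrix contrast between binding states
  maps where a ligand rigidifies or loosens the structure.
- **Essential dynamics** — covariance PCA of Calpha coordinates with
  per-frame projections, variance fractions, cosine-content and split-half
  subspace-overlap (RMSIP) sampling diagnostics.
- **Generalized correlation** — r_MI = sqrt(1 − exp(−2I/3)) from
  Kraskov k-nearest-neighbour mutual information (k = 6) of 3-D
  displacement series: orientation-independent, nonlinearity-aware
  coupling in [0, 1].
- **Geometry descriptors** — radius of gyration, tagged pair distances
  (metal sites, end-to-end anchors), principal-axis inter-domain torsion
  series, aromatic ring centroid/interplanar-angle stacking
  classification, hydrogen-bond and salt-bridge occupancy tables.
- **GROMOS conformational clustering** — greedy neighbour-count
  partitioning on all-pairs RMSD with central structures and populations.
- **Gaussian network model control** — Kirchhoff slow modes with
  Brueschweiler collectivity, for checking that a truncated simulation
  construct preserves full-length collective mechanics.
- **Synthetic-trajectory generators** — Gaussian ensembles with prescribed
  block covariance, rigid hinge sweeps with exact torsion range, ring
  pairs at exact stacking geometry, two-state switches with known
  populations, tagged metal sites: every analysis above is validated
  against constructions whose truth is known exactly.
- **A pipeline driver** (`run_pipeline()` / `inst/cli/fluctdyn`) that runs
  the battery over systems × replicas from a YAML config and writes
  CSV/TSV/JSON outputs plus cross-system DF deltas and a manifest.

Structure and trajectory I/O (PDB, binary DCD, multi-model PDB) goes
through bio3d; the statistics are implemented here, with the hot loops
(mutual information, all-pairs RMSD) in compiled code.

## Worked example

Two synthetic "binding states" of a two-domain protein, three replicas
each — one with independently fluctuating domains, one rigidified across
the domain interface — analysed exactly as a real study would be:

```r
library(fluctdyn)

st <- structure_model(data.frame(
  elety = "CA", resid = "GLY", chain = rep(c("A", "B"), each = 10),
  resno = rep(1:10, 2), x = rep(seq(0, 16.2, by = 1.8), 2),
  y = rep(c(0, 7), each = 10), z = 0, het = FALSE))

flexible <- block_covariance(20, blocks = list(1:10, 11:20),
                             var = 0.25, rho_intra = 0.9, rho_inter = 0.0)
rigid    <- block_covariance(20, blocks = list(1:10, 11:20),
                             var = 0.10, rho_intra = 0.9, rho_inter = 0.8)

wt  <- lapply(1:3, function(r) generate_gaussian_ensemble(
  gaussian_ensemble_spec(st, flexible, n_frames = 500, seed = r)))
mut <- lapply(1:3, function(r) generate_gaussian_ensemble(
  gaussian_ensemble_spec(st, rigid, n_frames = 500, seed = r + 10)))

df_wt  <- df_matrix(wt)   # per-replica matrices, averaged
df_mut <- df_matrix(mut)
mean(df_wt$mat[1:10, 11:20])   # inter-domain coordination, state 1
mean(df_mut$mat[1:10, 11:20])  # inter-domain coordination, state 2
```

```
df_matrix: 20 x 20 pairs, 1500 frames, 3 replica(s); DF range [0, 0.554] A^2
df_matrix: 20 x 20 pairs, 1500 frames, 3 replica(s); DF range [0, 0.0439] A^2
mean inter-domain DF, flexible: 0.512 A^2
mean inter-domain DF, rigid:    0.04 A^2
```

The flexible state shows an order of magnitude more inter-domain distance
fluctuation (0.512 vs 0.040 A²) — the DF signature that distinguishes a
loosely coupled (activation-prone) from a cross-rigidified (frozen)
complex. The same objects feed the rest of the battery:

```r
fit_pca(wt)                              # pooled essential dynamics
sampling_diagnostics(wt[[1]])            # split-half RMSIP + cosine content
stacking_series(generate_ring_pair(ring_pair_spec(4.9, 25.8)), "A:1", "B:1")
```

```
ed_result: 60 coordinates, 1500 frames; top-2 variance 33.1%
  replica split_half_overlap cosine_content_1 cosine_content_2
1      r1          0.6269361      0.000130761       0.00080824
stacking A:1 - B:1: 1 frames, mean d 4.90 A, mean theta 25.8 deg; paired 100%, stacked 100%
```

The ring pair was generated at the crystallographic tyrosine–tryptophan
packing geometry of the antagonist complex (centroids 4.9 Å, interplanar
angle 25.8°) and the stacking classifier recovers both numbers and flags
the pair as stacked (inside the 4.9–10.4 Å, 1.2–89.9° window).

For a full study, describe systems, replicas, domains and tagged atoms in
a YAML config and run either `run_pipeline("run.yaml")` or the CLI:

```sh
inst/cli/fluctdyn all --config run.yaml --out results/ --seed 0
```

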