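---
title: "Methods: trajectory analysis, free-energy landscapes and variant consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis, free-energy landscapes and variant consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscope)
```

`trajscope` quantifies how point mutations reshape protein conformational
dynamics. This vignette is the package's own account of the models it
implements, the parameters that matter, the synthetic data it validates
itself on, and the numerical choices made where the design was genuinely
open.

## Coordinates, numbering and selections

Coordinates are held in Angstrom throughout; only reporting ever converts
(free-energy axes are sometimes drawn in nm elsewhere; we keep Å and leave
unit conversion to the caller). Every residue carries two numbers: a 1-based
sequence position (`resindex`) and the author/PDB number (`author_resid`).
Structural papers habitually mix the two — a loop can be "residues 17–27" in
sequence position and "residues 37–47" in author numbering when the mature
chain starts at residue 21 — so all user-facing labels use author numbering
and the selection grammar exposes both (`index 17:27`, `resid 37:47`).

PDB and DCD parsing go through `bio3d`, the standard R package for these
formats; `trajscope` adds the filtering (waters and hetero groups out by
default), element inference from atom names when columns 77–78 are absent,
and the dual-numbering bookkeeping. Van der Waals radii are the Bondi set,
bundled as a versioned table; unknown elements fall back to 1.7 Å with a
warning.

## Superposition and stability metrics

Rigid-body fits use the Kabsch algorithm: SVD of the weighted
cross-covariance with a determinant sign correction so reflections are never
returned. The fit degenerates for fewer than three atoms or coincident
points (error and warning respectively). RMSD series fit each frame's
selection onto the reference (default: backbone N, CA, C) and report the
least-squares minimum. RMSF is computed about the *iterative mean*
structure: frames are fitted to frame 1, the mean of the fitted selection
becomes the new reference, and frames are re-fitted (two passes, the default
`n_pass`, is where the mean stops moving at the ensemble sizes we target).

One behaviour is worth understanding rather than discovering: superposition
absorbs whatever part of the motion looks like a rigid-body mode. On the
package's own synthetic ensembles — which are generated in a fixed
laboratory frame — fitting therefore *removes* part of the planted
fluctuation (about 6/(3n) of the variance for isotropic noise on n atoms).
Every analysis that superposes exposes `superpose = FALSE` for data already
expressed in a common frame, and the package's recovery tests use it.
For real trajectories, where the molecule tumbles, leave superposition on.

SASA is Shrake–Rupley with a deterministic Fibonacci-spiral point set
(default 960 points, probe 1.4 Å), so results are bit-reproducible; the
error against the analytic sphere area decays with point count and is below
2% at the default. Hydrogens are excluded from the default SASA selection.
There is no Lee–Richards slicing and no polar/apolar decomposition.

## Correlated motions

The dynamic cross-correlation matrix is
$$c_{ij} = \frac{\langle \vec d_i \cdot \vec d_j\rangle}
{\sqrt{\langle d_i^2\rangle\,\langle d_j^2\rangle}},$$
with $\vec d_i(t)$ the *vector* displacement of atom $i$ from its time mean
(a 3-D dot product, not per-axis correlation), computed on Cα atoms by
default. The denominator is the product of the two mean-square
displacements under a square root — the standard normalisation that bounds
entries to $[-1, 1]$, with $c_{ii} = 1$ exactly. Zero-variance atoms give
undefined entries; these are reported as `NA` and flagged, never as 0.

PCA diagonalises the $3n \times 3n$ covariance of the (optionally
superposed) selected coordinates. The trace is the total fluctuation in Å²;
eigenvalues are clipped at zero; eigenvector signs follow the convention
that the largest-magnitude component is positive, so outputs are
reproducible across LAPACK builds. Projections of frames onto leading
components reproduce the eigenvalues as projection variances (an identity
the tests assert at 1e-8), and per-residue loading profiles with ±2σ extreme
conformers support porcupine-style interpretation without any rendering.

## Free-energy landscapes

Boltzmann inversion of a 2-D histogram over two collective variables
(default: Rg vs RMSD):
$$G_i = -k_B T \ln(N_i / N_{max}),$$
with $k_B = 0.0019872041$ kcal/(mol·K) and $T = 300$ K by default. The most
populated bin sits at exactly 0. Empty bins receive an artificial barrier of
$\max_{occ} G + k_B T$ and are flagged: the common convention is only that
*some* barrier is set, not its value, so ours is a documented choice that
keeps the surface finite without dominating colour scales. The default grid
is 50 × 50 over the observed range padded by half a bin; no smoothing is
applied before minima detection (smoothing changes basin counts and is off
by default).

Basins are local minima over the 8-neighbourhood of occupied bins, grown by
steepest descent; ties drain toward the smallest (i, j), so a flat surface
yields a single basin deterministically. The representative conformer of a
basin is the frame nearest (per-axis bin-width scaled) to the minimum bin's
centre, ties to the lowest frame index.

For a two-state system with populations $p_1, p_2$ the gap between basin
minima recovers $-k_B T \ln(p_2/p_1)$; with the generator's deterministic
70/30 schedule this is exact ($\approx 0.505$ kcal/mol at 300 K), and with
Bernoulli assignment it lands within binomial sampling error — both are
asserted in the test suite at 10,000 frames.

## Hydrogen bonds, contacts and interaction networks

H-bond criteria follow the common VMD-style geometric convention: donor to
acceptor ≤ 3.0 Å and, when the hydrogen is present, D–H···A within 20° of
linear. Both are configuration, not fidelity claims — the convention a given
study used is often unstated. Donors are N/O atoms with an attached
hydrogen (≤ 1.25 Å); topologies without hydrogens fall back to the
distance-only criterion with a warning, and then report each unordered pair
once since donor/acceptor roles cannot be assigned. Occupancy is the
percentage of examined frames in which at least one H-bond links a residue
pair.

Typed contacts use RING-style thresholds, all exposed: van der Waals at
$r_i + r_j + 0.5$ Å between residues ≥ 2 apart in sequence, salt bridges at
4.0 Å between opposite-charge side-chain N/O, π–π at 6.5 Å between aromatic
ring centroids, disulfides at 2.5 Å between SG atoms. π-cation and
water-mediated interactions are out of scope. The ensemble interaction
network evaluates H-bonds and contacts on strided frames (default stride
chosen to analyse at most 1000 snapshots, echoing common 1000-structure
ensemble-network protocols), keeps an edge iff its occupancy reaches the
threshold (default 10%), weights it by occupancy, and exports GraphML and
edge-list CSV with `CHAIN:RESNAME:AUTHORNUM` labels.

## Secondary structure

Backbone H-bonds are scored with the Kabsch–Sander electrostatic model,
$$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})
\ \text{kcal/mol},$$
bonded at $E < -0.5$. Missing amide hydrogens are constructed 1.0 Å from N,
anti to the preceding carbonyl oxygen; prolines donate nothing. The
assignment is deliberately 3-class — H for residues inside two consecutive
i→i+4 turns (3₁₀/π patterns only extend an existing helix), E for residues
in parallel/antiparallel bridge patterns, C otherwise — because
helix/strand/coil content is what variant studies reason about. 8-class
DSSP fidelity, bends and turns are non-goals, and chains shorter than five
residues are all-coil by definition.

## The synthetic generators — what they emulate and what they don't

The generators exist so that each analysis has a *recovery* test: a known
quantity is planted, the pipeline must measure it back.

* `make_gaussian_ensemble` draws stationary Gaussian displacements about a
  reference, each coordinate axis sampling N(0, σ²C) across atoms. A
  correlation block (A, B, ρ) sets C to ρ between the sets and |ρ| within
  them — the minimal structure that is positive semi-definite for any
  |ρ| ≤ 1 while making the *expected DCCM equal ρ exactly* on the cross
  block. Default σ is 0.5 Å, a typical Cα fluctuation scale for a folded
  domain at 300 K.
* `make_two_state_trajectory` interleaves two conformers with prescribed
  populations plus isotropic jitter. The deterministic schedule plants
  *exactly* round(p·n) frames of state A so tests can assert equalities,
  not just confidence intervals; Bernoulli mode exists for the statistical
  versions of the same checks.
* `make_hbond_toy` plants a textbook linear N–H···O bond (2.9 Å) in a
  prescribed fraction of frames and breaks it (5.0 Å) elsewhere.
* `make_toy_protein` builds ideal backbones by NeRF chain extension from
  ideal dihedrals (helix −57°/−47°; extended −120°/120°). The β-hairpin is
  the one construction that is not pure dihedrals: ideal per-residue angles
  alone do not close a hairpin with correct inter-strand H-bond registry,
  so the two strands are fully-extended templates placed antiparallel by a
  proper 180° rotation, with the rigid inter-strand offset chosen by a
  deterministic grid search that maximises the Kabsch–Sander bond count,
  joined by a geometrically crude 4-residue turn. Strand and turn residue
  indices are attached as metadata so tests can exclude the turn.

All generators are pure functions of their arguments and an explicit seed;
they save and restore the global RNG state. What they do **not** emulate:
force-field physics, solvent, kinetics, anharmonicity, or the
sequence-dependence of real fluctuations. A passing recovery test shows the
*estimator* is correct at the planted signal-to-noise, not that any
particular biological trajectory was reproduced. In the same spirit,
published per-trajectory numbers (RMSD plateaus, PCA traces, specific
occupancy percentages, basin coordinates) depend on private 100-ns
trajectories and are context for the methods, not targets for this package.

## Variant-pathogenicity consensus

Eight predictor cutoffs are bundled as the default rule set: SIFT = 0
(implemented as score ≤ 1e-9, since SIFT prints 0.00 for fully intolerant
positions), PolyPhen-2 > 0.9, PROVEAN < −2.5, I-Mutant ΔΔG < −0.5
(destabilising), FATHMM two-tailed |score| > 3.0, MutPred > 0.75, CADD > 20,
Condel > 0.8. Scores are consumed as input — no predictor is re-implemented
and none is queried over the network. Missing scores shrink both the count
and the denominator. Ranking is by descending deleterious count with
alphabetical tie-breaks, so it is deterministic and permutation-invariant
over tool columns.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes stages in dependency order from one config
(R list or YAML), logs every stage with its parameters to stderr, writes
CSV/GraphML/JSON outputs plus a `report.json` with summaries and provenance
(package version, seed, config hash), and is byte-deterministic given
config + seed. Stage-level independence (disabling one stage does not change
another's outputs) is asserted in the tests.

The test suite and acceptance script run on desk-scale problems chosen so
the statistical assertions have comfortable margins at interactive run
times: 5000-frame ensembles for correlation recovery (±0.05 at ρ = 0.8 is
about three Fisher-z standard errors), 10,000 frames for the two-state
free-energy gap, 2000-frame / 50-residue systems for end-to-end
determinism, and 20-seed replication for binomial coverage of planted
occupancies.

## Known limitations

* No mmCIF input, no bond-topology perception, no protonation logic.
* DCD is assumed X-PLOR/CHARMM-style in Å; no periodic-box unwrapping.
* The RMSF/DCCM/PCA iterative-mean superposition uses a fixed two passes;
  for pathologically noisy ensembles the mean may depend on frame order
  (use `superpose = FALSE` with pre-aligned data, where results are exact).
* The FEL is strictly 2-D and unweighted: no reweighting for biased
  sampling, no kinetics.
* "Backbone" for RMSD defaults to N, CA, C; studies differ on including O,
  so the selection is an argument rather than a constant.
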