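---
title: "Methods: conformational-ensemble analysis with confens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-ensemble analysis with confens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confens)
```

# Scope and data model

`confens` characterises the conformational ensemble of a protein — here
motivated by membrane proteins that combine a structurally stable helix
bundle with an intrinsically disordered loop, such as the vitamin-K
epoxide reductase family — from an ordered set of conformations sharing
one topology.  An `Ensemble` stores an `n_frames x 3N` coordinate matrix
(Angstrom), per-frame times (ps) and per-frame source labels, so that
several proteins (e.g. a wild type and point mutants) can be concatenated
into one labelled ensemble and decomposed again after any pooled
analysis.  Cross-protein merges require equal atom counts; since mutants
differ in side chains, merged analyses are restricted to backbone or
C-alpha selections, which is the convention used throughout.

Because production MD trajectories are far too large to ship, every
analysis stage is exercised on synthetic ensembles with planted ground
truth (`build_two_domain_toy()`, `sample_mixture_ensemble()`,
`build_ideal_helix()`, `plant_cavity_shell()`).  What these emulate — and
what they do not — is discussed at the end.

# Superposition and basic descriptors

Superposition uses the analytic Kabsch solution (SVD of the 3x3
cross-covariance, determinant-corrected to a proper rotation), which is
the global minimiser of the RMSD over rigid motions.  Fitting is
unweighted least squares on the stated selection; mass weighting is off
by default because the descriptor definitions below weight by mass only
where stated.

* **RMSD**: per-frame deviation from a reference after fitting on the
  selection (or without refitting for pre-superposed frames, as when a
  loop is analysed after fitting on the stable domain).
* **RMSF**: frames are fitted to frame 1 on the selection, and
  `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)` is taken about each atom's
  ensemble mean.  The reference for the fluctuation is the mean (not
  frame 1) — the conventional choice, made explicit here.  The default
  divisor is `n`; `unbiased = TRUE` uses `n - 1`, in which case the PCA
  eigenvalue sum equals `sum(rmsf^2)` exactly (the covariance-trace
  identity requires one normalisation on both sides).
* **Radius of gyration**: `Rg = sqrt(sum m_i r_i^2 / sum m_i)` over
  non-hydrogen atoms by default, with `r_i` measured from the selection's
  centre of mass.  Which region enters Rg (whole protein or loop only) is
  an explicit selection argument rather than a hard-coded choice.
* **Probability densities** of scalar series use fixed-width histograms
  (default 0.1 Angstrom bins), which are deterministic and integrate to
  one on the grid; kernel smoothing is a rendering choice left to the
  caller.
* **Helix axes** are the line through the C-alpha atoms of the first and
  last helix residues.  Exported endpoints are elongated by 25% per end
  (50% total) for display only; the stored direction is the unextended
  unit vector.

# Non-covalent contacts

Hydrogen bonds use the geometric criterion on N/O heavy atoms: donor
bears an explicit covalent hydrogen, donor-acceptor distance at most
3.6 Angstrom (boundary inclusive), pseudo-valent angle at the hydrogen
strictly greater than 90 degrees.  Covalently bound pairs are excluded;
sulfur and carbon never act as donor or acceptor.  Occurrence over an
ensemble aggregates all hydrogens of a donor into one (donor, acceptor)
series and keeps pairs present in at least 60% of frames by default; the
per-frame strength maps the distance linearly from 2.6 (strongest) to
3.6 Angstrom (weakest).

Hydrophobic contacts pair residues from
\{ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO\} whose side-chain carbons come
within 4 Angstrom; the set is configurable, glycine can never qualify,
and sequence neighbours (|i-j| < 2) are excluded so that only genuinely
tertiary contacts are reported.  A salt bridge is defined as a hydrogen
bond whose partners are a basic side-chain nitrogen (Arg NE/NH1/NH2,
Lys NZ, His ND1/NE2) and an acidic carboxylate oxygen (Asp OD1/OD2,
Glu OE1/OE2); this geometric definition is the package's own, stated
here because no universal one exists.

# Secondary structure and folding-pattern clustering

Assignment re-implements the Kabsch–Sander scheme: the electrostatic
backbone H-bond energy
`E = 0.084 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) x 332` kcal/mol defines a
bond at `E < -0.5`; two consecutive i to i+4 turns yield H, i to i+3
yields G, i to i+5 yields I, bridge patterns yield E/B, remaining turns
and bends T/S, else C.  Missing amide hydrogens are rebuilt 1.01 Angstrom
from N anti-bisecting the C(prev)-N and CA-N directions; chain breaks
(consecutive C-alpha over 4.5 Angstrom) split the assignment.  The
re-implementation is self-contained by design — no external DSSP binary
is required — and on ideal helices it reproduces a reference DSSP
implementation residue for residue.

The full alphabet is reduced to five letters (none, alpha, three_ten, pi,
strand) with H/G/I/E mapping to the four structured letters and B/T/S/C
to none.  A conformation's folding pattern is the set of
(residue, letter) pairs with letter != none, and dissimilarity between
conformations is the Jaccard distance between those sets (two fully
unstructured conformations are at distance 0).  The set construction is
the package's choice; a position-only variant would ignore helix-type
interconversion, which is exactly the signal of interest for transient
3-10/alpha conversions, so the typed representation is the default and
strand participates like any other letter.  Complete-linkage hierarchical
clustering is cut at every pruning distance 0.05, 0.10, ..., 1.00; the
silhouette score (on the precomputed distances) selects the cut, ties
going to the smallest distance (finest clustering).  If every cut yields
one cluster the silhouette is reported as NA rather than an error.

# Reference-based RMSD clustering

The ensemble-convergence procedure: (i) pick a random remaining frame as
a reference and remove all frames within RMSD cutoff r of it; repeat
until the pool is empty, giving references pairwise more than r apart;
(ii) assign every frame to its nearest reference, leaving frames farther
than r from all references unassigned, which makes coverage an output
(matching the observation that at r = 4 Angstrom a loop typically
clusters at 98-100%, not always 100%).  The random choice takes an
explicit seed, making runs reproducible; nearest-reference assignment
(rather than first-within-r) is used, with ties broken to the lower
reference index.  The operating cutoff defaults to 4 Angstrom and
`cutoff_sweep()` scans 2.4-7.0 Angstrom in 0.2 steps (24 values).
Medoids minimise mean RMSD to cluster members, exhaustively up to 2000
members and on a deterministic subsample above that.

# Collective motions

Cartesian PCA fits frames iteratively to their running average (to
1e-6 Angstrom, at most 10 iterations) and decomposes the centred
frame-by-coordinate matrix by SVD; eigenvalue k is the squared singular
value over `n - 1`.  Two selection presets mirror common usage: backbone
(N, H, CA, C, O) for single-protein analyses and C-alpha-only for
cross-protein merges.  Highly mobile chain termini can be excluded by
selection (a configuration choice, not hard-coded).  Porcupine-style
mode exports scale each atom's mode component by the mode's RMS amplitude
(`sqrt(eigenvalue)`) and flag atoms at or above a 2 Angstrom display
threshold; all atoms are retained internally.

The dynamic cross-correlation map is computed from the trajectory:
`C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` about each atom's mean
after fitting.  An elastic-network variant (correlations of a single
average conformation under a force-field model) is deliberately not
emulated; the trajectory-based map is the one used to interpret
mutation-induced decoupling, and the two agree only in the harmonic
limit.

# Free-energy landscape on principal components

With projections on (PC1, PC2) as reaction coordinates, the relative
Gibbs free energy is `dG = -kB T ln(P / Pmax)` with
`kB = 1.9872e-3 kcal/(mol K)` and T defaulting to 310 K
(`kB T = 0.616 kcal/mol`).  The state probability is a k-nearest-
neighbour estimate, `P(x) proportional to k / (n pi d_k(x)^2)`, evaluated
on a regular grid (default 100 x 100 spanning the projection range plus a
5% margin) and normalised over the grid.  The neighbour count k is not
prescribed anywhere authoritative; the default `k = ceiling(sqrt(n))` is
the standard bias/variance compromise for kNN density estimation and is
configurable.  The landscape minimum is exactly zero by construction, and
doubling T doubles every finite dG.

Wells are extracted by a persistence watershed: grid nodes are flooded in
order of increasing dG, basins grow from local minima, and when two
basins meet the shallower is merged into the deeper if its barrier
(meeting level minus its own minimum) is below `min_barrier`
(default 0.5 kcal/mol).  Wells are labelled W1, W2, ... by increasing
minimum, frames are attributed to the basin of their nearest node, and
per-well composition is the percentage of member frames per source label.
On planted two-well mixtures the recovered depth difference matches the
Boltzmann inversion `kB T ln(p1/p2)` to better than 0.1 kcal/mol at
n = 10^4 (75/25 at 310 K gives 0.677 kcal/mol) — this is the headline
calibration property of the module.

Whether a pooled landscape should use a PCA computed on the merged data
or on the reference protein alone is genuinely ambiguous; merged-data PCA
is implemented because it treats all sources symmetrically, and the
projection step accepts any externally supplied model if the other
convention is wanted.

# Cryptic pockets

Alpha-sphere pocket detectors are replaced by a deterministic grid
detector: a node of a regular grid (default 0.5 Angstrom spacing) is a
cavity node iff it lies outside every atom's van der Waals sphere grown
by a probe radius (1.4 Angstrom) *and* it is buried — at least N = 9 of
M = 14 evenly spread rays (6 axes + 8 cube diagonals) hit protein within
15 Angstrom.  The vdW table is fixed (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Angstrom) and the burial parameters were chosen once so that the
analytic-shell suite (sealed spherical shells of known interior volume)
is reproduced within discretisation error; both are configurable.
Volumes are node counts times the node volume.  Outputs are therefore
comparable in kind — per-frame volumes, ensemble frequency maps at an
isovalue (default 0.5), lining residues — but not numerically identical
to alpha-sphere tools, and no attempt is made to reproduce their internal
druggability or hydrophobicity scores: the lining hydrophobicity reported
here is the mean Kyte–Doolittle hydropathy of the lining residues, with
the scale name recorded in the output.  Arginine orientation uses the
CA-to-CZ vector against the CA-to-pocket-centroid direction.

# Synthetic ensembles: what passing tests do and do not show

The generator plants exactly the statistical structure the analyses
assume: Gaussian mixtures over conformational wells with known
populations (restricted to a mobile region over a rigid scaffold, which
mimics quasi-independent domain dynamics), ideal helices at canonical
dihedrals (alpha -57/-47, 3-10 -49/-26, pi -57/-70 — textbook values,
since no authoritative source builds helices), geometric hydrogen bonds
with planted frame frequencies, and sealed spherical shells whose cavity
volume is known in closed form.  Same seed, same ensemble, bitwise.

These fixtures validate correctness of the estimators, not realism of
proteins: real ensembles have anharmonic, correlated, non-Gaussian wells,
rugged barriers, solvent-mediated contacts and far larger sizes.  Passing
the suite therefore shows that each stage recovers known ground truth
under its own model assumptions and that the pipeline is deterministic
and internally consistent — it does not certify force-field-level
accuracy on experimental systems.

# Numerical choices and problem sizes

Defaults collected in `default_config()`: analysis stride 100 ps, H-bond
3.6 Angstrom / 90 degrees with 0.6 occurrence, hydrophobic 4 Angstrom,
cluster cutoff 4 Angstrom (sweep 2.4-7.0 by 0.2), secondary-structure
pruning sweep 0.05-1.0 by 0.05, T = 310 K, pocket isovalue 0.5 at
0.5 Angstrom spacing with a 1.4 Angstrom probe, porcupine threshold
2 Angstrom.  Degenerate inputs are defined rather than fatal: single
conformations give zero RMSF with a warning, identical folding patterns
give one cluster with an undefined silhouette, flat landscapes give one
well, empty pockets give empty lining lists, and zero-variance atoms get
zeroed correlation rows with unit diagonal.

The shipped test-and-calibration suite runs at deliberately desk-scale
sizes — 3000-frame mixtures for clustering recovery, 10^4 points for
landscape calibration, 300-atom shells for cavity volumes — chosen as the
smallest sizes at which the binomial and kNN error bounds quoted above
are comfortably met.

# Known limitations

* The DSSP re-implementation covers the classic eight states; newer
  extensions (poly-proline II, pi-bulge refinements) and sheet topology
  labelling are out of scope.
* Binary trajectory formats (DCD/XTC/NetCDF) are not read; multi-model
  PDB (or any converter producing it) is the interchange format.
* The reference-based clustering inherits the original procedure's
  dependence on the random reference order; the seed makes it
  reproducible, and on well-separated data the partition is
  seed-independent, but near-degenerate cutoffs can split borderline
  frames differently across seeds.
* kNN densities are biased near sharp ridges; well *depths* converge much
  faster than absolute densities, which is why calibration is stated in
  depth differences.
* The cavity detector's burial criterion can clip shallow surface
  grooves; it is aimed at enclosed (cryptic) cavities, for which the
  analytic error is a few percent at 0.5 Angstrom spacing.
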