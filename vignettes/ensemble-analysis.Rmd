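---
title: "Conformational ensemble analysis with confens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensemble analysis with confens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confens)
```

# Scope

`confens` analyzes conformational ensembles of proteins — multi-model PDB
files or plain multi-frame coordinate files, typically post-processed
molecular-dynamics trajectories. It covers the standard downstream pipeline
for a two-domain hinge protein such as the sperm-surface protease inhibitor
EPPIN, whose WFDC and Kunitz domains are joined by a short hinge and whose
open/closed equilibrium, ligand contacts and membrane anchoring are the
kind of questions this toolchain answers:

1. collective variables (CVs): center-of-mass distances and three-group
   interdomain angles;
2. Gibbs free-energy landscapes (FELs) over two CVs by Boltzmann inversion;
3. GROMOS conformational clustering with central-structure extraction;
4. all-atom elastic-network normal modes (ENM) with
   rotation-translation-block (RTB) reduction;
5. essential-dynamics PCA and mode overlap;
6. per-residue heavy-atom contact prevalence, a hydrogen-bond proxy, and
   water-occupancy grids.

Simulation engines, docking, homology modeling and continuum-energetics
stages are out of scope: the package consumes coordinate ensembles, never
produces them. Because real trajectories of interest are rarely deposited,
the package ships deterministic synthetic-ensemble generators with exact
ground truth; every analysis is validated against planted truth rather than
against an external tool's output.

# Models and conventions

## Ensembles, selections and numbering

An `Ensemble` is a fixed atom topology plus `F` frames of Cartesian
coordinates in Angstrom, with optional strictly increasing times in ps.
Residue identifiers are taken verbatim from the input file — mature-sequence
numbering like Pro22..Pro133 survives untouched, so selections can be
written against the numbering used in the literature. Atom indices, in
contrast, are positions in the atom table and are 1-based, R's native
convention; every selection and geometry operation uses them consistently.

The selection grammar supports `resid A-B[,C-D]`, `resname`/`name` lists,
the keywords `ca`, `backbone`, `heavy` (element not H/D), `protein`,
`water`, `all`, and `not`/`and`/`or` with parentheses. An expression that
matches nothing is an empty selection, not an error; operations that cannot
proceed on an empty set say so themselves.

## Collective variables

Two built-in CV definitions implement the standard hinge reaction
coordinates: `phe63_asnrepeat_distance`, the distance from the CA of
residue 63 to the CA centroid of residues 113–116 (the Asn repeat), and
`interdomain_theta`, the angle at the CA center of mass of residues
120–129 subtended by the CA centers of residues 60–62 + 67–69 and
90–96 + 100–107. The vertex of a three-group angle is the second-listed
group by convention, and it is configurable — reported angle values alone
cannot disambiguate the original choice, so the default is the conventional
ordered-triple reading. The distance CV's reference point for residue 63
is its CA, consistent with the CA phrasing of the other groups; a
whole-residue center of mass is one option away. For CA-only groups mass
and geometric weighting coincide, so the mass table cannot affect these
CVs.

## Free-energy landscape

The FEL is a plain Boltzmann inversion of the binned CV density on a
`bins x bins` grid (default 120) spanning the data range:
`G_ij = -ln(n_ij / n_max)` in kT, so the most populated bin is exactly 0
and the free-energy difference between any two bins is exactly the log of
their count ratio. Empty bins are masked, never imputed — inventing barrier
heights in unsampled regions is worse than admitting ignorance. No kernel
smoothing is applied. Temperature (default 310 K) enters only when
converting to kJ/mol for display (1 kT = 2.577 kJ/mol at 310 K). Basins
are local minima under 4-neighborhood comparison, sorted by depth with
row-major index as the tie-break.

A note on flatness checks: Poisson counting noise sets the resolution of
any histogram-derived landscape. With n samples on B^2 bins the per-bin
relative fluctuation is about `sqrt(B^2 / n)`; a uniform sample reads flat
to 0.1 kT only when bins hold ~10^4 counts, which is why the flatness
validation in the test suite uses a 10 x 10 grid at n = 10^6.

## GROMOS clustering

Clustering operates on the pairwise best-fit RMSD matrix (fit and
deviation on the same selection, default `backbone`; the atoms feeding the
original analyses are not recorded, so this is configurable). The
iteration is the classic neighbor-count loop: the unassigned frame with
the most unassigned neighbors at RMSD strictly below the cutoff (default
4.0 Å, reading "cutoff below 4 Å" literally) becomes a center; it and its
neighbors form a cluster and are removed; ties in neighbor count go to the
lowest frame index. Clusters are reported largest-first as Cl-a, Cl-b, ….
Equilibration removal is not baked in: apply `time_window()` (half-open,
`t_start <= t < t_end`) before clustering, e.g. to discard the first 50 ns.

The F x F matrix is computed in compiled code using the closed-form
weighted Kabsch solution per pair; only the 3 x 3 SVD depends on the pair,
so 2000 frames take seconds. The matrix is held in memory, which is
comfortable to F ≈ 5000; beyond that, compute block rows with
`pairwise_rmsd_matrix` on frame subsets.

## Elastic-network modes and RTB

The ENM Hessian is the standard anisotropic-network form: every atom pair
within the cutoff (default 8 Å) contributes a spring with super-element
`-k (d d^T)/r^2`; diagonal blocks are minus the row sums, so uniform
translations are annihilated exactly. The spring constant is uniform by
default with an optional inverse-r^6 weighting; low-frequency mode shapes
of hinge motions are robust to the k-model details, and all validation is
closed-form or planted-ground-truth based, so no attempt is made to mimic
any particular tool's force constants.

RTB projects the mass-weighted Hessian onto each block's rigid-body
subspace (3 translations + 3 rotations per block, default one residue per
block; rotational axes are dropped for blocks with fewer than 3
non-collinear atoms, which keeps single-atom and collinear blocks
well-posed), diagonalizes the reduced matrix, and back-projects. With
single-atom blocks the reduction is exact — the basis spans the full
space — which the tests exploit as an internal consistency oracle. Reduced
eigenvalues bound the full ones from above (variational property). Mode
numbering counts the six rigid-body modes first, so the softest internal
motion is mode 7.

## PCA and overlap

Essential-dynamics PCA superposes all frames onto an iteratively fitted
average structure (fit to frame 1, average, one re-fit pass), then
eigendecomposes the coordinate covariance with divisor F (population
covariance, matching trajectory-analysis convention). Overlap between a
PCA eigenvector and a normal mode is the uncentered normalized inner
product in [-1, 1]; whether published "correlations" between such vectors
were centered is usually unstated, so the Pearson variant is a flag away.
Superposition itself is a nonlinear filter: a planted displacement
direction is recovered beyond 0.999 only if it is orthogonal to the rigid
modes of the mean structure, which is how the validation constructs it.

## Contacts and occupancy

A residue is "in contact" in a frame when any of its heavy atoms is within
the cutoff (default 3.5 Å, inclusive — boundary ties must be deterministic)
of any heavy atom of the partner group. Prevalence is reported to one
decimal, so `percentage x F / 100` is an integer frame count. Residue-pair
matrices use the same criterion per pair; note the per-residue prevalence
is the frame-union over partners and therefore >= the row maximum of the
matrix, with equality against single-residue partners such as a small
ligand. The chemistry classification is a fixed lookup (hydrophobic
ALA/VAL/LEU/ILE/PRO/PHE/MET/TRP/GLY, polar SER/THR/ASN/GLN/TYR/CYS/HIS,
charged ASP/GLU/LYS/ARG); unknown names go to "other" with a warning.
Membrane contacts reuse the same machinery with the lipid selection as the
partner; polar-head versus apolar-tail restriction comes from the
topology's atom naming.

The hydrogen-bond proxy is purely geometric (N/O heavy-atom distance,
optional donor-H-acceptor angle when hydrogens are present); it stands in
for third-party interaction-type diagrams and makes no energetic claims.

Occupancy grids are binary per frame: a voxel (default 1 Å) is occupied
when at least one selected atom center lies in it; occupancy is the
fraction of occupied frames, so `occupancy x F` is integral and exactly
testable. Whether published occupancy isovalues (0.44 by default here)
were applied to smoothed densities is unknown; the binary definition is
implemented and the threshold is configurable. Grids export to OpenDX for
standard viewers.

# The synthetic generators

`make_hinge_ensemble()` emulates a two-state hinge equilibrium: a closed
state near 85° and an open state near 118°, weighted 0.7/0.3, with 3°
within-state spread, 0.15 Å isotropic coordinate noise, and 10 ps frame
spacing — the regime reported for two-domain protease-inhibitor models of
this size. Angles are drawn per frame; the C-terminal domain is rigidly
rotated about the hinge axis by exactly the drawn angle. Two geometric
choices are deliberate and worth stating honestly:

* **Elongated domains.** The domains are 2 x 2 bead columns (cross spacing
  3.8 Å, layer pitch 6.0 Å) rather than compact blobs. Best-fit RMSD
  absorbs a surprising amount of a hinge swing when one domain is compact:
  with compact domains the RMSD gain is ~0.17 Å/degree, so the 4 Å GROMOS
  neighborhood spans ~22° — wider than the 33° state separation — and the
  greedy center-picker bridges the states. The elongated geometry raises
  the gain to ~0.31 Å/degree, separating the states cleanly. Real hinge
  proteins achieve the same separation with all-atom RMSD over thousands
  of atoms; the pseudo-protein compensates with lever arms.

* **A near-axis hinge strip.** Springs from any atom to a bead exactly on
  the rotation axis are orthogonal to the rotation's displacement field,
  so an on-axis strip would leave each domain's independent rotation as an
  exact zero mode (eight zero modes in total). The strip therefore sits
  0.8 Å off the axis: the relative domain rotation acquires a weak
  restoring force and becomes the softest internal mode — mode 7 — which
  is exactly the planted hinge motion that `hinge_displacement_field()`
  returns for comparison.

What the generator does **not** emulate: force-field energetics, solvent,
anisotropic B-factors, sidechains, realistic secondary structure, or
autocorrelated dynamics (frames are independent draws). Passing tests
therefore demonstrate the correctness of the analysis algebra and its
statistical behavior under a known mixture, not performance on any real
trajectory.

The other generators plant exactly countable signals: a ligand whose
nearest heavy atom sits at the contact distance in exactly
`round(fraction x F)` frames and far beyond the cutoff otherwise (with
placement verified and rejected if any other residue intercepts); a water
occupying one fixed point (hence one fixed voxel) in exactly
`round(occupancy x F)` frames, with the scattered cloud anchored at a
fixed lattice offset so the data-driven grid origin — and therefore the
site's voxel — is reproducible; and a two-leaflet pseudo-lipid slab with
labeled head/tail beads under planted anchor residues, with the 3.5 Å /
5 Å margins checked at build time and per-frame jitter bounded so they
hold in every frame.

All generators run on a private RNG stream seeded per call (default 0)
and restore the caller's stream, so identical seeds give identical
ensembles and surrounding code is unaffected.

# Numerical choices

* Kabsch superposition corrects reflections (determinant +1 enforced) and
  rejects fit sets whose second singular value is below 1e-8 of the first
  (collinear or degenerate).
* The angle CV errors on vertex-arm coincidence below 1e-9 Å rather than
  returning an arbitrary value.
* Rigid-body mode counting uses the threshold `|lambda| < 1e-8 x max`.
* Bin assignment puts a sample lying exactly on the upper range edge into
  the last bin; FEL tie-breaks (several bins at maximal count) leave
  several exact zeros rather than picking one.
* PDB coordinates are written at 3 decimals (format precision 5e-4 Å
  round-trip); the XYZ dialect writes 4 decimals.
* Contact cutoffs compare inclusively (<=), clustering cutoffs strictly
  (<), each following its source's phrasing.

# Problem sizes

The shipped validation exercises the pipeline at desk scale: 2000-frame,
112-atom hinge ensembles for clustering and landscapes (a 2000 x 2000
RMSD matrix takes a few seconds in the compiled path), 200,000-sample
analytic FELs, and 20-60-residue decorated pseudo-proteins for contact,
hydrogen-bond, occupancy and membrane checks. These sizes were chosen so
the entire suite re-runs in well under a coffee break while every
statistical bound tested (binomial state counts, Poisson bin noise,
average-structure convergence) is still comfortably sharp.

# Known limitations

* No periodic-boundary minimum-image handling: inputs are assumed whole
  and unwrapped, as post-processed trajectories are.
* No mmCIF or compressed trajectory formats; no altloc/insertion codes.
* The FEL is a raw histogram inversion: no reweighting (WHAM/MBAR) and no
  smoothing, so barrier heights between well-sampled basins are exact in
  the Boltzmann-inversion sense but unsampled regions are simply masked.
* The hydrogen-bond proxy is geometric only.
* The pairwise RMSD matrix is dense in memory.
* Synthetic ensembles are stylized: conclusions about real trajectories
  require real trajectories.
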