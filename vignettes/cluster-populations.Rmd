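---
title: "Detecting ionic clusters and their population dynamics in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ionic clusters and their population dynamics in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionclust)
```

## The problem

Dilute electrolyte solutions below saturation — the motivating case is a
pair of diastereomeric salts formed by a chiral amine cation and a
camphorsulfonate-type anion — contain transient, pre-nucleation ionic
clusters: short-lived ion pairs, trimers and tetramers that form and
dissolve at equilibrium. Their population statistics carry chemical
information (for instance, a less soluble salt tends to keep a slightly
smaller fraction of free ions), but "cluster" is not a quantity an MD
engine outputs: it needs an operational, geometry-based definition that can
be applied frame by frame to a trajectory.

ionclust implements such a definition and the statistics built on top of
it: per-frame cluster partitions, normalized cluster-size state vectors,
time-averaged size distributions with conservative error bars, differences
between systems, and a principal component analysis of the population
fluctuations.

## The cluster criterion

The guiding idea is that two ions belong to the same cluster when their
closest approach is not obstructed by solvent. Operationally, for each
reference ion in turn:

1. **Best-fitting ellipsoid.** The 3×3 geometric covariance matrix of the
   ion's atom coordinates (unweighted, centred on the centroid, divided by
   the atom count *N*) is diagonalized; eigenvalue $\lambda_i$ gives the
   semiaxis $a_i = 2\sqrt{\lambda_i}$. The population-normalized,
   unweighted second moment is used because the criterion is geometric, not
   mass-weighted, and it leaves the single-atom case well defined (zero,
   then floored — see below).
2. **Concentric shells.** Shells with semiaxes $a(n) = a_i + n\delta$,
   $n = 0, 1, 2, \dots$ are grown around the ellipsoid. The increment
   $\delta$ (default 0.4 nm) corresponds roughly to the diameter of one
   solvent molecule, so one shell is "one solvent layer".
3. **Acceptance by contact.** Shell occupants are counted by atom, but
   candidacy is by molecule: any non-assigned ion with at least one atom in
   the current shell is nominated whole. A candidate is accepted into the
   cluster when the minimum interatomic distance between it and *any*
   already-accepted member (reference included) is at most the contact
   threshold (default 0.3 nm). Acceptance is iterated to a fixed point
   within each shell so contact chains inside one shell resolve.
4. **Termination.** The scan stops when a shell contains solvent but no
   unassigned-ion atoms (the cluster is solvent-bounded), or contains
   unassigned-ion atoms none of which pass the contact test (nearby ions
   belong elsewhere), or the shell cap is reached. A shell holding only
   atoms of already-accepted members does not stop the scan: an accepted
   member may extend outward past the solvent-only region around the
   reference, and its own contacts must still be collected.

Repeating the scan over reference ions — skipping ions already assigned —
partitions the frame. The size distribution is insensitive to the order in
which reference ions are taken; the package uses ascending molecule id by
default (deterministic) and exposes a seeded random order so that the
insensitivity is a testable property rather than an assumption.

### Interpretive choices

Two details of the termination rule are under-determined by a purely verbal
description and were fixed as follows:

* The "in contact with the inner shells" test is evaluated against **all
  accumulated members**, not only ions of the geometrically previous shell.
  This is the connectivity-consistent reading: an ion touching any part of
  the cluster is part of it. The alternative (previous shell only) can
  split a cluster whose chain happens to skip a shell index.
* A shell containing ion atoms that all belong to *other, already assigned*
  clusters terminates the scan like unaccepted candidates do: the region is
  claimed, and growth through it would contradict the exclusion rule.

### Numerical conventions

* **Degenerate ions.** Planar, linear or single-atom ions have one or more
  zero eigenvalues; their semiaxes are floored (default 0.1 nm,
  configurable) so the base ellipsoid always encloses a positive volume.
* **Boundaries.** Ellipsoid membership is inclusive
  ($\sum_i (x_i/s_i)^2 \le 1$), and an atom on a shell boundary belongs to
  the inner shell. Any consistent convention works; inclusivity avoids
  dropping exact-contact configurations.
* **Periodicity.** Only orthorhombic boxes are supported, and every
  inter-molecular displacement goes through the minimum-image convention
  (component-wise wrap into $[-L/2, L/2)$). Molecules are made whole once
  per frame on construction, since an ellipsoid fitted to a molecule broken
  across a box face is meaningless. The shell cap defaults to
  $\lceil \min(L)/2/\delta \rceil$: shells beyond the half-box are not
  meaningful under minimum image.
* **Hydrogens** enter both the ellipsoid fit and the shell counts; a
  heavy-atom-only mode for the fit is available (`shell_spec(heavy_only =
  TRUE)`) for sensitivity checks.

## State vectors and population statistics

For a frame with $N$ ions, let $c_i$ be the number of size-$i$ clusters and
$n_i = c_i / N$. The state vector is

$$v = (n_1,\; 2n_2,\; 3n_3,\; 4n_4, \dots),$$

whose $i$-th component is the fraction of ions residing in size-$i$
clusters, so $\sum_i i\,n_i = 1$ identically. This normalization (fractions
of *ions*, not of *clusters*) is the only one under which the components
sum to one, which is why it is the package's definition. Clusters of equal
size but different charge composition (anion–anion, cation–anion,
cation–cation pairs, and so on) are merged into one cluster class;
`charge_tally()` retains the resolved view so the effect of the merge can
be inspected.

Reports cap the per-size classes at `s_max` (default 4, as larger clusters
are negligibly populated in the dilute systems this method targets), but
the combined weight of larger clusters is kept in an explicit `overflow`
component — never silently dropped — so the normalization stays exact for
every frame.

### The maximum-error bars

Time averages are reported with a deliberately conservative uncertainty:
the series is cut into `n_blocks` contiguous equal-length blocks (default
5; any remainder is folded into the last block) and the error bar is the
largest absolute deviation of a block mean from the global mean. No
distributional assumptions are made; against the standard error of the
mean this estimator over-covers by construction (the test suite checks
≥ 95% coverage on stochastic series). The block count is a documented,
configurable choice, not a claim about an optimal estimator.

Between-system differences (`population_difference()`) subtract means
componentwise, in both fraction and ion-count units, and carry the *sum*
of the two maximum errors as their uncertainty — again conservative and
consistent with the maximum-error semantics. A component is flagged
significant when its absolute difference exceeds that uncertainty.

## PCA of population fluctuations

The covariance of the components $i\,n_i$ over frames is

$$C_{ij} = \frac{1}{N_\mathrm{frames}} \sum_k
  \left(i\,n_{i,k} - \langle i\,n_i \rangle\right)
  \left(j\,n_{j,k} - \langle j\,n_j \rangle\right),$$

with divisor $N_\mathrm{frames}$, not $N_\mathrm{frames}-1$; at MD frame
counts the difference is immaterial, but the package's oracle tests match
the formula exactly. State vectors are truncated to sizes 1–4 *before*
centering and are **not** renormalized afterwards: renormalizing would
redistribute the (small) overflow weight across the retained classes and
distort their fluctuations.

Diagonalization gives the principal modes of population fluctuation.
Because every overflow-free state vector sums to one, deviation vectors
sum to zero, so $C\,\mathbf{1} = 0$: one eigenvalue is exactly zero with
eigenvector $\propto \mathbf{1}$, and the interesting modes live in the
zero-sum subspace. Typical spectra are dominated by two modes:

* a **monomer–dimer anticorrelation** ($v \propto (1, -1, 0, 0)$ up to
  normalization), the association/dissociation of ion pairs, and
* a **small-vs-large redistribution** ($v \propto (1, 1, -1, -1)$),
  monomers and dimers exchanging population with trimers and tetramers.

`mode_report()` labels these sign patterns automatically. Eigenvector signs
are fixed by making the largest-magnitude component positive (magnitude
ties resolved towards the smallest size class) so reports are reproducible
across linear-algebra backends.

## The synthetic generator

All tests run on synthetic data with exact ground truth; no external
trajectories are needed anywhere.

`plant_frame()` builds frames that emulate the composition of the
motivating simulations — 22 cations and 22 anions plus solvent — with a
planted cluster partition: each cluster is a straight contact chain of
rigid 5-atom template ions (consecutive nearest-atom distance 0.25 nm,
safely below the 0.3 nm threshold), distinct clusters are at least 1.2 nm
apart atom-to-atom, solvent atoms stay outside a 0.35 nm skin of every ion,
and one solvent blocker is guaranteed between each pair of clusters. Under
these margins the planted partition is the *only* answer any
contact-based definition can return, which is what makes it an oracle;
every constraint is re-verified by direct distance computation before a
frame is emitted, and generation is bit-reproducible from its seed. The
default bulk solvent density (0.05 nm⁻³) is sparse: synthetic solvent only
needs to occupy shells and obstruct inter-cluster space, not reproduce a
liquid structure.

What the generator deliberately does **not** emulate: real ion geometries,
electrostatics, solvation shells, and ambiguous borderline contacts near
the 0.3 nm threshold. Passing the planted-recovery tests therefore
demonstrates that the implementation realizes the stated definition
exactly, not that the definition is chemically optimal for any particular
real system — the latter is a modelling choice carried by the parameters
δ and the contact threshold.

`plant_series()` generates state-vector series with known covariance
($v_k = \bar v + \sum_m a_m z_{m,k}\, \mathbf{m}_m + \varepsilon_k$, modes
orthogonal to $\mathbf 1$, noise projected onto the zero-sum subspace,
negative draws rejected — a mild truncation that is negligible at the
default scales). `toy_trajectory()` evolves a cluster-size multiset by
Markov detach/join moves and re-plants the geometry each frame, so the
whole detection → populations → PCA chain can be exercised against an
evolving truth; the solvent count is pinned across frames so the emitted
trajectory has a constant atom count, as a real trajectory would.

## Validation problem sizes

The shipped validation suite uses: 100 planted 44-ion frames for exact
recovery against both the planted truth and an independent brute-force
contact-graph reference (built on single-linkage components with solvent
obstruction of the closest-approach segment); 20 fixtures × 50 seeded
reference orders for order insensitivity; 10,000-frame planted two-mode
series for PCA direction recovery within 5°; 40-frame dimer/two-monomer
alternation for the pure $(1,-1)/\sqrt 2$ mode within 1°; and 200
stochastic replicates for maximum-error coverage. These sizes give the
statistical properties room to bind while keeping the suite quick to run.

## Limitations

* Orthorhombic boxes only; triclinic inputs are rejected, not skewed.
* Text formats only (GRO, PDB, extended XYZ); binary XTC/TRR readers are
  out of scope — convert upstream.
* The cluster definition is instantaneous; lifetimes, interconversion
  kinetics and nucleation rates are outside the package's remit.
* Roles come from an explicit map, never guessed from residue names;
  mis-specified maps are the user's responsibility (consistency within a
  molecule is enforced).
* The maximum-error estimator is conservative by design; it is an
  uncertainty band, not a confidence interval with a stated level.
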