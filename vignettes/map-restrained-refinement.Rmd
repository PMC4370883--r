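---
title: "Map-restrained simulated-annealing refinement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-restrained simulated-annealing refinement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densref)
```

## The problem

Solution NMR restrains local geometry well — short-range NOE distance
bounds, hydrogen bonds, secondary-structure restraints — but often leaves
the global arrangement of a molecule underdetermined, especially for
elongated nucleic acids where few long-range contacts exist. Electron
microscopy provides the complementary information: a low-resolution 3-D
density map of the overall shape. `densref` implements the device that
joins the two inside one refinement: a density-map energy term added to the
restraint force field of a simulated-annealing structure calculation.

## The map potential

Let $m_i^{obs}$ be the observed density at voxel $i$ of a grid of $N$
voxels, and $m_i^{calc}$ the density back-calculated from the current
coordinates. The agreement score is the Pearson cross-correlation over the
full grid,

$$
C \;=\; \frac{1}{N}\sum_{i=1}^{N}
\frac{(m_i^{obs}-\overline{m^{obs}})(m_i^{calc}-\overline{m^{calc}})}
     {\sigma^{obs}\,\sigma^{calc}},
$$

with population ($1/N$) means and standard deviations and no masking, and
the energy is

$$ E_{map} \;=\; k_c\,(1 - C), $$

so $E_{map}\ge 0$ with equality exactly at $C=1$. Because $C$ is invariant
under positive affine transforms of either map, the term is insensitive to
the absolute scale or offset of the experimental density — only shape
agreement matters.

The calculated map places an isotropic Gaussian kernel at every selected
atom (default selection: all atoms that are neither pseudo atoms nor named
`H*`, i.e. the heavy atoms that dominate electron scattering), weighted by
atomic number by default, evaluated at voxel centers and truncated beyond
$4\sigma$. "Resolution" is interpreted as the kernel's full width at half
maximum, $\sigma = r / (2\sqrt{2\ln 2}) \approx 0.4247\,r$; this is the
most common convention, and it is configurable because blurring programs
disagree on it. Two numerical details matter:

* the kernel is shifted to reach exactly zero at the truncation radius
  ($G(r)-G(r_{cut})$ inside, $0$ outside). Without the shift the energy is
  discontinuous whenever a voxel crosses an atom's cutoff sphere, which
  wrecks finite-difference verification of the gradient; the shift costs
  $\sim 3\times10^{-4}$ of the peak height and nothing in practice.
* voxel values are kernel evaluations at voxel centers, not voxel
  integrals. The correlation is insensitive to the constant factor between
  the two, and center evaluation keeps the gradient simple.

### The exact gradient

The force on atom $a$ follows the chain rule through the kernel. The only
subtlety is that $\overline{m^{calc}}$ and $\sigma^{calc}$ also depend on
the coordinates. Writing $a_i = m_i^{obs}-\overline{m^{obs}}$ and
$b_i = m_i^{calc}-\overline{m^{calc}}$,

$$
\frac{\partial C}{\partial m_j^{calc}}
 = \frac{1}{N\,\sigma^{obs}\sigma^{calc}}
   \left[ a_j \;-\; C\,\frac{\sigma^{obs}}{\sigma^{calc}}\, b_j \right] .
$$

The first term is the naive ("frozen statistics") derivative; the second
carries the dependence through $\sigma^{calc}$. The dependence through
$\overline{m^{calc}}$ alone cancels because $\sum_i a_i = 0$. The package
uses the exact form; tests verify every component against central finite
differences.

## Restraints and the composite potential

The non-map terms are deliberately plain: harmonic bonds and angles,
flat-bottom distance restraints (zero inside $[d_{lo}, d_{hi}]$, harmonic
outside) for NOE-like, hydrogen-bond and backbone P–P classes, and a soft
quadratic excluded-volume repulsion between non-restrained pairs closer
than 2.5 Å. Class force constants (noe 30, hbond 50, pp 5, bond 500
energy/Å²) are package conventions calibrated on the toy fixtures — the map
term, not the force field, is the point of the package. Base-planarity and
dihedral restraints are represented, where a fixture needs them, as
distance-restraint surrogates; a true improper-dihedral term, RDC and SAXS
terms, and knowledge-based torsion potentials are out of scope.

## Annealing protocol

Refinement is Cartesian velocity-Verlet dynamics under a geometric
temperature ladder (default 3000 K down to 25 K in 200 stages, velocities
resampled from the Maxwell distribution at each stage start), preceded by a
hot equilibration and followed by an L-BFGS-B polish to a projected-gradient
tolerance. Cartesian dynamics with stiff bonds stands in for
internal-coordinate (torsion-angle) dynamics: the map term is
integrator-agnostic, and an internal-coordinate engine would be
disproportionate here. No atom is fixed.

Units are reduced: lengths in Å, masses in amu, energies on a
kcal/mol-like scale with $k_B = 1.9872\times10^{-3}$ energy/K; the
schedule's times (`equil_time`, `stage_time`, `dt`) are in the matching
internal time unit, not picoseconds. The default `dt = 0.002` is
conservative against the stiffest default bond ($k = 500$, $\omega
\approx 9$ per time unit); the packaged studies use `dt = 0.02`, still
well inside stability.

The ensemble protocol repeats the anneal `n_repeats` times (default 128)
with consecutive seeds and keeps `n_select` models (default 20) by the
lowest-energy / smallest-mutual-RMSD rule: rank by polished energy (ties
broken by lower seed), keep the best $2 n_{select}$, then greedily drop the
candidate with the largest mean pairwise RMSD. Identical seeds give
byte-identical ensembles regardless of execution order.

Two efficiency options, both off by default and both documented because
they change only cost, not the model:

* `map_stride` in `composite_potential()` refreshes the map force every
  k-th dynamics step and holds it in between (the polish always uses the
  full potential). The map force varies on the kernel length scale —
  17 Å of $\sigma$ for a 40 Å map — so a stride proportional to the
  resolution is far below the scale on which that force changes.
* the packaged studies build map grids with the tight 3σ kernel margin
  instead of the roomier `2 × resolution` padding default; the truncated
  kernels still fit entirely, and coarse-map grids shrink several-fold.

## What the synthetic fixtures emulate — and what they do not

`build_toy_helix()` produces a regular single-stranded helix (default 40
residues, 4 atoms per residue including a backbone "P" ring at constant
consecutive spacing) — a geometric stand-in with the right length scale and
anisotropy for an RNA-like molecule, not a chemically meaningful model.
`perturb_model()` bends it with a few random low-frequency modes plus
jitter, rescaled so the superposed RMSD hits a target within 2%: a smooth,
global deformation of the kind a misassembled but locally correct structure
shows. `toy_restraints()` derives bonds (consecutive atoms, exact reference
length), backbone P–P restraints (consecutive residues, ±10%), and a seeded
NOE-like sample (default 2 per residue) of non-bonded pairs under 6 Å —
the NOE observability range — with ±10% bounds.

Passing tests on these fixtures demonstrates that the map term steers a
refinement exactly as intended when the map is consistent with the data and
the deformation is smooth. They do not demonstrate robustness to real-data
pathologies: restraint errors and sparse/ambiguous NOE networks, map noise
and B-factor effects, chirality traps, multi-chain packing, or force-field
inaccuracy. The experiment-scale systems those questions require are
outside this package's scope.

## The packaged study

`resolution_study()` is the package's scaled-down version of the canonical
resolution-vs-precision experiment: one perturbed start (8 Å RMSD from the
reference), identical restraints, and one refinement per condition —
restraints only, restraints plus a simulated map at 40/25/15/10 Å, and
restraints plus a cube-shaped control map. Reported per condition: bundle
precision (mean ± sd of pairwise RMSDs, each pair superposed independently
— the NMR-bundle convention) and accuracy (RMSD to the reference), over all
heavy atoms, with sample (n−1) standard deviations and a single pair
reported as sd 0.

Expected behavior, which the acceptance tests assert: precision improves
monotonically as the map resolution improves and beats the no-map
baseline; the 10 Å arm recovers the reference to better than 2 Å; the cube
map — a shape uncorrelated with the molecule — gives accuracy no better
than no map at all, confirming that the term helps only when the density
actually corresponds to the molecule.

Three study parameters deserve explanation:

* **`k_c = 20000` for the studies** (the potential's own default is 10).
  $E_{map}$ is bounded by $k_c$, while the toy system's restraint energies
  reach thousands and its thermal energy at 3000 K is
  $\tfrac{3}{2}N k_B T \approx 1.4\times10^{3}$. A map term bounded by 10
  would be thermodynamically invisible at every stage of the anneal; the
  study value makes the map's pull commensurate with the other terms. The
  force-constant *scale* is system-size dependent by construction — the
  correlation is dimensionless, so $k_c$ carries all of the energy units.
* **problem sizes**: studies run 5–16 repeats selecting 4–5 models on a
  160-atom helix with a 20–25-stage ladder — chosen as the smallest
  protocol in which the qualitative contrasts (resolution trend, cube
  control) are stable across seeds.
* **schedule lengths**: the hot equilibration controls a real trade-off.
  Long hot phases decorrelate the repeats (the no-map bundle spreads to
  ~3–4 Å pairwise RMSD — required for a meaningful precision baseline)
  but let map-restrained repeats wander into sub-basins a little off the
  optimum; very short hot phases converge deepest but make every no-map
  repeat relax into the same nearby minimum, collapsing the baseline
  artificially. The packaged studies use a middle setting (equilibration
  4 time units) for the recovery run and the same hot phase with a lighter
  polish for the resolution trend.

## Degenerate inputs and edge cases

Flat grids (zero standard deviation) are rejected with an error naming the
offending grid — notably a cube map covering the whole grid, or a model
entirely outside the grid (the error tells the caller to recenter).
Non-orthogonal CCP4 cells are unsupported and refused. Superposition
requires ≥ 3 non-collinear scoped atoms and excludes reflections
(determinant +1). Energy ties in ensemble selection break toward the lower
seed, keeping selection deterministic. If dynamics produce a non-finite
energy the anneal retries once from the start at half the time step, then
fails loudly.

## Known limitations

* The correlation runs over the full grid, unmasked; local or masked
  correlation is a non-goal.
* Voxel-center kernel evaluation and the 4σ truncation are conventions,
  not claims about any particular blurring program; only trends across
  resolutions, not absolute resolution numbers, should be compared across
  software.
* Cartesian dynamics with a simple Maxwell-resampling thermostat is not a
  calibrated thermodynamic ensemble; it is an annealing engine.
* The CCP4 reader supports mode-2 orthogonal-cell maps with the
  MAPC/MAPR/MAPS axis permutations; symmetry records are skipped.
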