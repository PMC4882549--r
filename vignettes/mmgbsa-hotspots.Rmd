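---
title: "MM/GBSA binding energetics and hot-spot clustering: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MM/GBSA binding energetics and hot-spot clustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsaHotspots)
```

# Scope

`gbsaHotspots` implements the end stage of a protein–ligand binding-mode
analysis: given snapshot ensembles of a receptor–ligand complex, it computes
MM/GBSA interaction energies, decomposes them per receptor residue, clusters
the residue-energy vectors across a ligand panel to identify shared hot
spots, and interconverts experimental affinities, relative free energies and
potency fold-changes. It does **not** run molecular dynamics; coordinates
arrive as multi-model PDB ensembles or from the package's seeded synthetic
generators.

# The energy model

## Single-trajectory MM/GBSA

The binding free energy of a snapshot is estimated as

$$\Delta G_{bind} = \Delta E_{vdW} + \Delta E_{ele} + \Delta G_{pol} +
\Delta G_{nonpol},$$

under the single-trajectory approximation: complex, free receptor and free
ligand are all evaluated at the complex coordinates, so internal bonded
terms cancel exactly and the gas-phase terms reduce to intermolecular pair
sums. Entropic contributions are not estimated (a common choice when
ranking congeneric ligands, and a stated limitation below).

* **van der Waals**: Lennard-Jones 12-6 with
  $r_{min,ij} = r^{min/2}_i + r^{min/2}_j$ and
  $\epsilon_{ij}=\sqrt{\epsilon_i\epsilon_j}$, no cutoff.
* **Electrostatics**: Coulomb's law with the conversion constant
  332.0636 kcal·Å/(mol·e²) and interior dielectric $\epsilon_{in}=1$.

## Polar solvation: Generalized Born with HCT radii

The polar term uses the canonical GB pairwise form

$$G_{pol} = -\frac{k}{2}\sum_{i,j}\left(\frac{1}{\epsilon_{in}} -
\frac{e^{-\kappa f_{ij}}}{\epsilon_{out}}\right)\frac{q_i q_j}{f_{ij}},
\qquad
f_{ij} = \sqrt{r_{ij}^2 + R_iR_j\,e^{-r_{ij}^2/4R_iR_j}},$$

with $f_{ii}=R_i$. Effective Born radii $R_i$ follow the
Hawkins–Cramer–Truhlar pairwise-descreening scheme: intrinsic radii are
reduced by a 0.09 Å offset, each neighbour descreens through the analytic
spherical-shell integral with its scaled radius $s_j = S_j\tilde\rho_j$,
and the engulfed-atom case adds the closed-form correction. The inverse
radius is clamped at $10^{-3}$ Å$^{-1}$ (with a message) so deeply buried
atoms cannot produce negative radii. Salt enters through the Debye
screening factor $\kappa = 0.329\sqrt{c_{salt}}$ Å$^{-1}$; the default
0.15 M mimics physiological ionic strength. Exterior dielectric defaults
to 80 (water).

Binding polar energy is `complex − receptor − ligand`, with radii
recomputed for each species so desolvation is captured.

## Nonpolar solvation: two SASA evaluators

$\Delta G_{nonpol} = \gamma\,\Delta SASA$ with
$\gamma = 0.0072$ kcal/(mol·Å²) and a 1.4 Å water probe. Two evaluators
are provided:

* `sasaLCPO()` — the analytic Linear Combination of Pairwise Overlaps:
  per-atom weights $P_1\dots P_4$ applied to the inflated sphere area, the
  pairwise buried-cap areas, and the neighbour-of-neighbour overlap sums.
  The weights are force-field parameters: the published regression values
  are supplied in the synthetic generator's atom-class table, and the exact
  two-sphere weights $(1, -1, 0, 0)$ make the formula analytically exact
  when no two neighbours of an atom overlap each other. Atoms with
  non-positive surface radius (hydrogens) are excluded entirely. Used for
  total binding energies, where speed matters.
* `sasaIcosa()` — recursive icosahedral tessellation of each atom sphere
  ($20\cdot4^{d}$ faces at depth $d$, default 3); a face counts as exposed
  if its centroid lies outside every other inflated sphere, and its area is
  the exact spherical-triangle solid angle (Van Oosterom–Strackee). Used
  for the per-residue decomposition, where per-atom areas must be
  attributable. The mesh has a fixed orientation, so areas are exact for
  isolated spheres at any depth but carry a small (≲1%) orientation
  dependence for overlapping clusters.

Both evaluators are validated against a Shrake–Rupley golden-spiral
numerical oracle in the test suite.

## Per-residue decomposition

Each receptor residue receives its pairwise van der Waals and Coulomb sums
with the ligand; its polar term is twice the residue–ligand cross block of
the complex GB pair matrix (the symmetric matrix assigns half of each
cross term to each partner, and the ligand is treated as one unit); its
nonpolar term is $\gamma$ times the residue's SASA change between the
complex and the free receptor. The columns therefore sum over residues to
the corresponding intermolecular totals, which the tests assert to
$10^{-6}$ kcal/mol.

# Ensemble statistics and geometry

Ensemble energies are reported as mean ± SEM with SEM = sd/√n over
snapshots. Geometry monitors include Kabsch superposition RMSD (SVD with
determinant correction), atom-pair distance series, hydrogen-bond
occupancy (donor–acceptor ≤ 3.5 Å and, when a hydrogen is given,
donor–H–acceptor angle ≥ 135°), and pocket residues (any heavy atom within
5.0 Å of a ligand heavy atom, boundary inclusive).

# Hot-spot clustering

Residue-energy vectors across the ligand panel (rows: residues, columns:
ligands) are first filtered to residues with any $|E| \ge$ `eps`
(default 0.005 kcal/mol, dropping exactly-zero rows), then clustered with
Ward's minimum-variance linkage via the Lance–Williams recurrence on
**unsquared Manhattan distances** — the same convention as
`stats::hclust(method = "ward.D")`, against which the implementation is
cross-checked in the tests (the implementation itself is independent).
Ties are broken deterministically by lexicographic smallest-leaf order.
Groups cut from the tree are labelled `A`, `B`, … by descending mean
absolute energy; group `A` may be split into subgroups `A1`/`A2` at its
internal node. Hot spots are residues with $|E| \ge 0.5$ kcal/mol
(inclusive); differential residues between two ligands use the same 0.5
threshold on the per-residue energy difference. Trees export to Newick
through `ape`, with ultrametric leaf heights at half the merge height.

# Thermodynamic conversions

With $R = 1.9872\times10^{-3}$ kcal/(mol·K) and $T = 298.15$ K
($RT = 0.5925$ kcal/mol):

* $\Delta G_{exp} = RT\ln(K_i\,[\mathrm{nM}]\cdot10^{-9})$, and its exact
  inverse;
* $\Delta\Delta G$ against a named reference ligand;
* fold-change of potency $FC = e^{\Delta\Delta G/RT}$ and its inverse;
* a mutation is classified **sensitive** when $\max(FC, 1/FC) \ge 5$
  (inclusive), so five-fold potency gains count as well as losses.

298.15 K is the package default because it is the temperature at which the
standard tabulated conversions are self-consistent; it is exposed in
`solventParams()` and `runConfig()` and can be set to the simulation
temperature when preferred. Rounding for report tables is half-away-from-
zero at two decimals (`roundHalfAway()`), applied only at format time —
all internal arithmetic is double precision.

# Synthetic generators and what they do (and do not) show

Because real trajectories are large and licensed, the package ships seeded
generators so that every stage runs end to end:

* `toyComplex(nPocketResidues, nLigandAtoms, seed)` — a ligand chain near
  the origin with a +1e amine nitrogen, pocket residues (3 heavy atoms
  each) on a 6–10 Å shell, and one aspartate-like carboxylate oxygen
  planted at salt-bridge range. Parameters come from a small physically
  plausible atom-class table (carbon/nitrogen/oxygen LJ, GB and surface
  parameters). Heavy atoms only.
* `jitterEnsemble(system, nFrames, sigma, seed)` — i.i.d. Gaussian
  coordinate noise (default 0.3 Å) around the base frame, standing in for
  an equilibrated snapshot window.
* `plantedMatrix(groupSizes, groupMeans, withinSd, nLigands,
  zeroFraction, seed)` — residue-by-ligand energy matrices with known
  group structure and ground-truth labels, used as the clustering
  recovery oracle.

Passing tests on these generators demonstrates that the estimators,
decomposition bookkeeping and clustering recover planted ground truth at
toy scale (tens of atoms, tens of residues, ≤ 4 ligands). They do **not**
demonstrate agreement with condensed-phase absolute binding free energies:
toy totals are near zero because the salt-bridge Coulomb attraction is
largely cancelled by GB desolvation, and nothing at this scale reproduces
trajectory-scale absolute values or residue counts.

# Worked example

```{r example}
sys <- toyComplex(4, 4, seed = 101)
ens <- jitterEnsemble(sys, nFrames = 5, sigma = 0.1, seed = 201)
st <- ensembleEnergyStats(ens)
st
prof <- ensembleDecomposition(ens, depth = 2L)
hotspotFilter(prof, threshold = 0.5)
```

```{r cluster}
pm <- plantedMatrix(groupSizes = c(6, 6, 8),
                    groupMeans = c(-2.4, -1.0, -0.2),
                    withinSd = 0.05, nLigands = 4, seed = 7)
rep <- bindingModeReport(pm$matrix, k = 3,
                         referenceTotals = c(L1 = -40, L2 = -41,
                                             L3 = -39, L4 = -38))
table(rep$groups)
substr(rep$newick, 1, 60)
```

```{r thermo}
affinityTable(ligand = c("ligA", "ligB"),
              kiNm = c(1.60, 73.00),
              dgCalc = c(-46.05, -37.48), dgCalcSem = c(0.13, 0.12),
              reference = "ligB")
```

# Numerical choices

* No distance cutoffs anywhere: systems of interest are small enough that
  exact pair sums are affordable and cutoff artefacts are avoided.
* The HCT descreening integral is evaluated in closed form (validated
  against a 3-D grid quadrature at 2% in the tests); coincident atoms
  (r < 10⁻⁶ Å) are a hard error rather than a silent singularity.
* Negative LCPO cap areas (numerically possible for nearly-engulfed
  atoms) are clamped to the valid range with a message.
* Ward heights are kept on the unsquared-distance scale so they match the
  `ward.D` convention and remain monotone.

# Limitations

* Single-trajectory approximation: no receptor or ligand reorganisation
  energy, no conformational entropy.
* GB/HCT is an approximation to Poisson–Boltzmann; absolute polar
  energies carry the usual implicit-solvent caveats.
* `sasaIcosa()` is not rotation-invariant (fixed mesh orientation); the
  anisotropy is below 1% at depth 3 and only affects the small nonpolar
  term of the decomposition.
* The synthetic generators exercise correctness, not realism; calibration
  against experiment requires real trajectory ensembles.
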