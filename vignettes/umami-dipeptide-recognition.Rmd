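---
title: "Screening and recognition analytics for umami dipeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and recognition analytics for umami dipeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umamidp)
```

# Scope and model

Umami taste is mediated by the heterodimeric class C GPCR T1R1/T1R3, whose
extracellular Venus-flytrap (VFT) domains close around small acidic
ligands such as the dipeptides Asp-Gly (DG) and Glu-Lys (EK).
Computational studies of this system follow a common arc: enumerate the
candidate dipeptide space, screen it on physicochemical properties and
imported docking/umami-probability scores, then characterise the
receptor-ligand recognition from molecular-dynamics ensembles -- RMSD/RMSF
statistics, conformational clustering, hydrogen-bond occupancy, pocket
solvation, channel geometry, an empirical binding free energy, and
weak-interaction fields.  `umamidp` implements that analysis layer as
reusable, tested R functions.  It deliberately does *not* wrap the
external engines that produce the raw inputs (homology modelling, docking,
MD integration, umami-probability prediction, QM wavefunctions): docking
energies and umami probabilities enter as data, and a synthetic-data
module generates structures, trajectories and score tables with planted
ground truth so every downstream stage is testable without them.

# The dipeptide database

All $20 \times 20 = 400$ ordered pairs of the standard amino acids are
enumerated.  For each sequence the package computes:

* **Molecular weight**: sum of free amino-acid average masses minus one
  water (one peptide bond).
* **Net charge** at pH via the Henderson-Hasselbalch form
  $$ q(\mathrm{pH}) = \sum_{b\,\in\,\text{basic}} \frac{1}{1+10^{\,\mathrm{pH}-pK_a(b)}}
     \;-\; \sum_{a\,\in\,\text{acidic}} \frac{1}{1+10^{\,pK_a(a)-\mathrm{pH}}}, $$
  over the two termini and ionizable side chains (D, E, H, C, Y, K, R).
* **Isoelectric point**: the unique root of $q(\mathrm{pH})$, found by
  bisection to $10^{-3}$ pH; $q$ is strictly decreasing, so the root
  exists and is unique for every dipeptide (both termini are free).
* **Hydrophobicity**: the Kyte-Doolittle hydropathy values summed over the
  two residues.

Screening applies the conventional thresholds -- binding free energy at or
below $-6.5$ kcal mol$^{-1}$ per pocket (scores compared at their 0.1
kcal mol$^{-1}$ input precision) and umami probability at or above 0.85 --
and reports per-pocket, joint and acidic-and-hydrophilic subsets with
counts and fractions over the scored records.

## Parameter-table choices

The upstream property server used for the reference study does not
publish its pKa set, so the package bundles a widely used model table
(N-terminus 8.6, C-terminus 3.6, D 3.9, E 4.1, H 6.5, C 8.5, Y 10.1,
K 10.8, R 12.5), overridable by the user.  Under this table the package
reproduces the two anchors that are reproducible at a desk: pI(EK) = 6.41
and the database-wide minimum net charge at pH 7 of $-2.02$ (attained by
the all-acidic dipeptides; DD/EE/DE all round to $-2.02$).  The reported
pI for DG is internally inconsistent in the source material (3.71 as a
single value, but 3.75 as the database-wide minimum, which DG attains);
the default table yields 3.75, and we treat the two readings as agreeing
within 0.05 pH.

The hydrophobicity scale is a genuinely open choice: no published residue
scale reproduces the reported extreme values (AA $\approx 4.45$, EE
$\approx -4.1$), and under Kyte-Doolittle the database extremes are II and
RR.  We keep Kyte-Doolittle -- the field's default -- as the bundled
scale, contract only the *sign* convention (positive = hydrophobic) and
the documented per-residue values, and let users supply any other scale
as a named vector.

```{r pi}
isoelectric_point("EK")
isoelectric_point("DG")
```

# Structures, trajectories and superposition

Structures are plain atom tables (`structure_model`); trajectories add a
frame array, optional times and per-frame potential energies.  Multi-MODEL
PDB files round-trip through `read_pdb()`/`write_pdb()` at the format's
$10^{-3}$ Å precision.  Superposition uses the Kabsch SVD solution
constrained to proper rotations, and RMSD is the mass-unweighted
$\sqrt{\tfrac1N \sum_i \delta_i^2}$ over the fitted selection.  Pocket and
ligand sizes are measured by a principal-axis bounding box (extents along
the coordinate-covariance eigenvectors, padded by vdW radii), which makes
the length/width/height/volume measure rotation-invariant -- a stand-in
for tools that report world-axis boxes, contracted only against its own
eigen-decomposition oracle.

# Trajectory metrics

`rmsd_series()` superposes every frame on a reference; `rmsf_profile()`
superposes frames on their mean structure (mean re-estimated, two
iterations) and reports per-atom fluctuations under residue keys;
`flexibility_correlation()` returns the Pearson R and OLS slope k between
two profiles over their shared residues.  One numerical caveat is worth
knowing: fitting 6 rigid degrees of freedom to pure isotropic noise
absorbs roughly $2/N$ of the displacement variance for an $N$-atom
selection, so the closed-form RMSF of an isotropic Gaussian ensemble
($\sigma\sqrt3$ per atom) is recovered to better than 1% only for
selections of $\gtrsim 100$ atoms.  Receptor-scale Cα selections are far
above that; tiny toy systems are not, and tests use clouds of 100+
pseudo-atoms for quantitative recovery.

Clustering implements the pairwise criterion -- two conformations share a
cluster when their Cα RMSD after superposition is at or below the
threshold (default 0.5 nm, converted internally to Å) -- with greedy
leader grouping in frame order: the criterion alone does not define a
partition, and the leader algorithm is deterministic, $O(nk)$, and makes
the seed-frame linkage explicit.  Each cluster's representative is its
lowest-potential-energy frame, ties broken by frame index; trajectories
without energies fall back to uniform energies, so the representative is
the seed frame.  `snapshot_count()` reproduces the sampling arithmetic
(200 ns saved every 5000 steps of 2 fs = 20,000 snapshots).

# Interactions and solvation

Hydrogen bonds use the geometric criteria: donor-acceptor distance below
3.5 Å and donor-hydrogen-acceptor angle above 135 degrees, with the
hydrogen at the angle vertex, exactly as the criteria are worded (the
distance is donor-acceptor, not hydrogen-acceptor).  Occupancy is the
fraction of frames a donor-acceptor pair satisfies both; the default
retention filter keeps pairs at or above 45%.  Contact fingerprints list
receptor residues with any heavy atom within 4.0 Å of the ligand
(a conventional cutoff; the source states none) and class them
hydrogen-bonding, hydrophobic (all contacts carbon/sulfur on both sides),
or polar.

SASA is Shrake-Rupley with a deterministic golden-spiral point set (960
points, probe 1.4 Å), validated against the analytic sphere and
two-sphere spherical-cap forms.  Pocket hydrophobicity is defined here as
the SASA-weighted mean hydropathy of the pocket residues: only its sign
(+ hydrophobic / − hydrophilic) and ordering between pockets are
contracted, never the magnitudes printed by proprietary tools.  Pocket
waters are counted as water oxygens within 5.0 Å of pocket heavy atoms,
with a tail mean over the final 25% of frames standing in for the
"converged" count.

# Channel profiling

`profile_channel()` follows the HOLE idea along a user-supplied axis: at
stations spaced 0.25 Å, the largest sphere that fits without overlapping
any atom's vdW sphere is found by maximising
$r(\mathbf c) = \min_i (\lVert\mathbf c-\mathbf x_i\rVert - R_i)$ over the
station plane (16 seeded multi-starts around the previous centre,
Nelder-Mead refinement), capped at 10 Å where the pore opens to bulk.
The two nearest distinct residues by centre-to-surface distance are the
station's contacts.  A fixed axis -- rather than the original tool's
self-finding axis -- keeps the operation deterministic; a plane-grid
brute-force oracle (0.05 Å) ships in the package for verification.
`channel_acidity()` averages model pKas (or imported per-residue values,
e.g. from an external electrostatics code) over the unique titratable
contact residues and classes the channel basic above mean pKa 7.

# Solvated interaction energy

The SIE score is
$$ \Delta G_\mathrm{bind} = \alpha\,[E_c(D_\mathrm{in}) + \Delta G_R(\rho, D_\mathrm{in})
   + E_\mathrm{vdw} + \gamma\,\Delta\mathrm{MSA}(\rho)] + C $$
with the calibrated constants $\alpha = 0.1048$, $D_\mathrm{in} = 2.25$,
$\rho = 1.1$, $\gamma = 0.0129$ kcal mol$^{-1}$ Å$^{-2}$, $C = -2.89$
kcal mol$^{-1}$.  Two published renderings of the bracket exist; we
implement the original convention (α multiplying the whole interaction
bracket), under which the constants were fitted, and expose the
α-on-Coulomb-only variant behind `alpha_ec_only = TRUE`.  The terms are
intermolecular receptor-ligand quantities -- what a binding free energy
requires -- even where source descriptions say "intramolecular":

* $E_c$: screened Coulomb sum $k_e q_i q_j / (D_\mathrm{in} r_{ij})$,
  $k_e = 332.0636$ kcal mol$^{-1}$ Å e$^{-2}$.
* $E_\mathrm{vdw}$: 12-6 Lennard-Jones with Lorentz-Berthelot combination
  of a bundled element-class table.
* $\Delta G_R$: the reaction-field change on binding.  The original
  boundary-element solver is replaced by a generalized-Born model
  (solvent dielectric 78.5, solute dielectric $D_\mathrm{in}$,
  pairwise-descreening effective Born radii on ρ-scaled atomic radii).
  This approximation is exact for a single ion (the Born formula, tested
  to $10^{-6}$) and additive at separation, which is what the score's
  difference construction needs.
* $\Delta$MSA: SASA-based surface change with ρ-scaled radii, negative
  for any bound complex.

`ensemble_sie()` averages the score over frames sampled at a fixed
interval across the equilibrated window (default: the second half of the
trajectory, 100 samples, mirroring 100 conformations at 1 ns over a
100-200 ns production run), scaling the window down with a warning on
shorter inputs.

# Reduced density gradient fields

Weak interactions are located by the reduced density gradient
$$ \mathrm{RDG}(\mathbf r) = \frac{|\nabla\rho(\mathbf r)|}
   {2\,(3\pi^2)^{1/3}\,\rho(\mathbf r)^{4/3}} $$
on a promolecular density.  Because the original MP2 wavefunctions are
not reproducible here, $\rho$ is a superposition of spherically averaged
free-atom shell densities built from Slater's screening rules (H-Kr).
This construction is derivable in code from published rules alone, each
atomic density integrates exactly to the element's electron count, and
hydrogen's density is a pure exponential with decay length 0.5 bohr --
which gives the package a closed-form RDG fixture.  Gradients and
Hessians use central finite differences (4th-order stencils in the grid
interior, one-sided at the boundary; boundary voxels are excluded from
classification), and the NCI classes follow common practice on
$\mathrm{sign}(\lambda_2)\,\rho$: below $-0.01$ a.u. hydrogen bonding,
above $+0.01$ steric repulsion, between them van der Waals, among voxels
with RDG < 0.5 and $\rho$ < 0.05 a.u.  All cutoffs are arguments.  Grids
export as Gaussian cube files (Bohr units, z-fastest ordering).

# The synthetic-data module

The generators state a world once and the analytics must recover it:

* `make_dipeptide_structure()`: idealised all-atom dipeptides from
  internal-coordinate templates (standard bond lengths, deterministic
  side-chain paths, free termini, coarse neutralised charges).  Only
  topology, composition and approximate shape matter downstream; no
  force-field minimisation is attempted.
* `make_trajectory()`: reference plus isotropic Gaussian displacements of
  prescribed per-atom σ, optionally wrapped in random rigid motions to
  exercise superposition; per-frame energies are seeded Gaussians so
  representative selection is deterministic.  Gaussian noise (not
  correlated dynamics) suffices because only time-averaged statistics
  are analysed.
* `make_channel_structure()`: rings of carbon pseudo-atoms at 0.25 Å
  stations whose inscribed-sphere radius equals the prescribed profile by
  construction.  On sloping profiles neighbouring rings can undercut a
  station's nominal radius by $\sqrt{(R-\Delta)^2+s^2}-R$-type terms, so
  planted V-profiles use gentle slopes ($\le 0.2$ Å/Å), keeping the
  discrepancy below the 0.1 Å recovery tolerance.
* `make_hbond_trajectory()`: a donor-H-acceptor triad bonded
  (2.88 Å, ~165°) in exactly `round(occupancy * n_frames)` seeded frames
  and broken (6 Å) otherwise, so detected occupancy equals the planted
  fraction exactly.
* `make_score_table()`: docking energies and umami probabilities with
  exact planted pass counts at the $-6.5$ / 0.85 thresholds, including a
  prescribed T1R1-and-T1R3 overlap.

Identical spec and seed give identical output; different seeds change
noise realisations, never planted truths.  What a green test establishes
is therefore recovery of stated parameters under idealised noise -- not
agreement with any particular receptor's 200 ns ensemble, whose H-bond
counts, water plateaus, channel radii and cluster structure depend on an
unpublished model and are explicitly out of scope.

# Defaults that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| energy threshold | $-6.5$ | kcal mol$^{-1}$ | dissociation constant $\sim 10^{-5}$ M |
| umami threshold | 0.85 | fraction | prediction-confidence cutoff |
| clustering threshold | 0.5 | nm | matches receptor-scale RMSD convergence |
| H-bond distance / angle | 3.5 / 135 | Å / degrees | geometric criteria, vertex at H |
| occupancy filter | 0.45 | fraction | stable-bond convention |
| station spacing | 0.25 | Å | channel-profile resolution |
| contact cutoff | 4.0 | Å | package choice (source silent) |
| pocket-water cutoff | 5.0 | Å | package choice (source silent) |
| SASA probe / points | 1.4 / 960 | Å / count | water probe; <1% sphere error |
| SIE constants | 0.1048, 2.25, 1.1, 0.0129, $-2.89$ | mixed | calibrated set |
| RDG isovalue / ρ cutoff | 0.5 / 0.05 | - / a.u. | common NCI practice |

# Known limitations

* Dipeptide geometries are idealised templates, not minimised conformers;
  they carry correct composition and rough shape only.
* The GB reaction field and SASA-based ΔMSA are documented stand-ins for
  boundary-element and molecular-surface algorithms; absolute SIE values
  for real complexes are not contracted.
* Pocket hydrophobicity and the bounding-box measure are contracted for
  sign/ordering, not for magnitudes printed by proprietary tools.
* The promolecular density has no relaxation or charge transfer; NCI
  classes near strong polar contacts are qualitative.
* Greedy leader clustering depends on frame order by design; partitions
  are order-stable only when groups are separated by more than twice the
  threshold.

```{r example}
st <- make_score_table(33, 30 / 33, 22 / 33,
                       fraction_pass_energy_t1r3 = 16 / 33,
                       overlap = 15 / 33, seed = 1)
db <- dipeptide_database(scores = st$table)
screen_dipeptides(db)$summary
```
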