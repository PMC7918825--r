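---
title: "Methods: conformational-ensemble analysis with trajscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-ensemble analysis with trajscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscape)
```

trajscape dissects conformational ensembles of the APC armadillo-repeat
(ARM) domain — and, with user-supplied selections, of any protein whose
state can be summarized by a distance-like and an angle-like coordinate —
from C-alpha-resolution trajectories.  This vignette is the package's own
account of the models it implements, the tunable parameters that matter,
and the design choices made where more than one reasonable convention
exists.

## Collective variables

Two geometric collective variables (CVs) summarize a frame:

* **pocket perimeter** *x* (Å): the perimeter of the triangle formed by
  the C-alpha atoms of the three hydrophobic-pocket residues F458, R463
  and F510 — the sum of the three pairwise distances;
* **bend angle** *y* (degrees): the angle of the R549 side chain between
  the guanidino carbon (PDB atom `CZ`) and the C-alpha, measured at the
  C-gamma vertex.

Both are invariant under rigid motion of the frame.  The vertex choice
follows the listing-order convention for three-atom angles (the middle
atom is the vertex); "guanidino carbon" maps to the arginine `CZ` atom.
Together the CVs separate the *axial* (y near 170°) and *equatorial*
(y near 110°) arginine conformers while tracking pocket breathing.

## Free-energy landscape

The joint density of (x, y) is histogrammed on a regular grid (default
200 bins per axis, read as per-axis binning of the conventional
"200-bin" landscape; the data range is padded by 2% per side) and
normalized to a probability g(x, y).  The relative free energy is the
Boltzmann inversion

$$\Delta G(x,y) = -k_B T \ln g(x,y),$$

min-shifted so the most probable bin sits at zero, with empty bins
masked (`NA`) rather than given an arbitrary energy.  The minus sign is
the conventional inversion: probable states must be energy *minima* for
"energy basin" to mean what it says.  Defaults are $k_B = 3.30\times
10^{-4}$ kcal mol$^{-1}$ K$^{-1}$ (treated as a molar constant) and $T =
300$ K, so $k_B T = 0.099$ kcal/mol; both are arguments of `pmf()`.

### Basin detection

`find_basins()` works on a lightly smoothed copy of the count field
(Gaussian, `smooth_sigma = 2` bins) because a finely binned histogram of
finitely many frames carries Poisson shot noise that turns one physical
basin into many spurious local minima; the raw `g` and `dG` surfaces are
never altered.  Local minima (8-neighborhood) within `depth_cut` (0.2
kcal/mol, about 2 $k_B T$) of the global minimum are candidate basins.
Candidates are merged, deeper absorbing shallower, when any of three
criteria holds:

1. closer than `min_separation` (20) bins (Chebyshev distance);
2. closer than `merge_widths` (0.75 Å, 20°) on both axes — two minima
   inside one membership rectangle could never be assigned separately;
3. no free-energy barrier of at least `barrier_cut` (0.05 kcal/mol,
   about $k_B T/2$) separates them along the straight grid path — minima
   rippling across one noisy plateau belong to one basin, while genuine
   conformers keep a real barrier between their wells.  Empty bins along
   the path do not raise the barrier: absence of sampling is not
   evidence of a wall.

Binning should follow sampling: 200 bins per axis resolves ensembles of
a few tens of thousands of frames; for short runs (a few thousand
frames) 80–120 bins keeps several counts per occupied bin and basin
detection stable.  The landscape targets in `scripts/acceptance.R` use
40,000 frames at 200 bins.

### Occupancy and representatives

`assign_frames()` uses axis-aligned rectangles (default half-widths 0.75
Å and 20°) around basin centers; overlap ties go to the deeper basin,
frames outside every rectangle are `unassigned`, and fractions sum to
one.  The rectangle is a declared convention — published occupancy
percentages depend on a basin boundary that is rarely stated, so here
they are treated strictly as generator-recovery targets.

`representative_frame()` follows the hierarchical-agglomeration recipe:
average-linkage clustering of the basin's member frames (evenly
subsampled to at most 500) on the pairwise best-fit C-alpha RMSD matrix,
then the frame of the largest cluster minimizing summed RMSD to its
co-members, ties to the lowest frame index.

## RMSD, RMSF, and the analysis window

Superposition is the Kabsch SVD solution with the determinant correction
(proper rotations only); a quaternion-eigenvalue implementation serves
as an independent oracle in the tests, never as the production path.
`rmsd_series()` reports per-frame best-fit RMSD to the starting frame
over the analysis selection (all C-alpha by default — whether published
traces fit on all C-alpha or a subset is usually unstated, and all-CA is
assumed here).

Window statistics discard the first `equil_frac = 12.5%` of frames, the
fraction a 200 ns production run loses when its first 25 ns are treated
as equilibration.  `mean_rmsd()` returns the arithmetic mean and the
population (denominator *n*) standard deviation.

`rmsf()` superposes the window frames onto their iteratively refined
mean structure (two refinement passes) and reports
$\mathrm{RMSF}_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}$.
The mean structure, not frame one, is the fluctuation reference:
referencing a single frame would fold slow drift into the per-residue
amplitudes.

## Dynamic cross-correlation matrix

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
{\sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}}$$

with displacements about the window-mean structure and the ensemble
average written explicitly in the numerator (without it the quantity
would be frame-dependent).  Frames are superposed first (`fit = TRUE`)
so rigid-body motion cannot masquerade as internal correlation;
`fit = FALSE` exists for pre-aligned input and for systems below the
three atoms a superposition needs.  Zero-variance atoms get a zeroed
row/column with unit diagonal and a warning.  `mask_low()` blanks
$|C_{ij}| <$ 0.3 (strictly below; a coupling of exactly 0.3 is kept)
for display only — the data matrix is untouched.  The DCCM window should
be the same post-equilibration window as the RMSF analysis.

## MM/GBSA bookkeeping

`aggregate_gbsa()` forms, per frame,

$$\Delta X = X_\mathrm{complex} - X_\mathrm{receptor} - X_\mathrm{ligand}$$

for each term and chains the end-state identities
$\Delta E_{MM} = \Delta E_{int} + \Delta E_{vdw} + \Delta E_{ele}$,
$\Delta G_{solv} = \Delta G_P + \Delta G_{np}$,
$\Delta G_{binding} = \Delta E_{MM} + \Delta G_{solv}$, reporting means
and population standard deviations.  The solute conformational entropy
($-T\Delta S$) is never computed; the result carries an explicit
"entropy omitted" note, so $\Delta G_{binding}$ is an enthalpy-only
estimate suitable for rank-ordering similar ligands.  The default
protocol is single-trajectory (receptor and ligand coordinates extracted
from complex frames), under which $\Delta E_{int}$ cancels exactly; the
protocol is recorded on the result, and a nonvanishing $\Delta E_{int}$
under the single-trajectory tag raises a warning rather than being
silently zeroed.

Per-residue decomposition (`decompose_gbsa()`) splits each pairwise
receptor–ligand interaction term half to each partner residue — the
common decomposition semantics — and assigns self and per-residue
solvation terms wholly.  The nonpolar intercept *b* is spread equally
over a molecule's residues, a pure bookkeeping convention that makes the
per-molecule partitions sum exactly to the molecular totals; closure
(sum of contributions = total $\Delta G_{binding}$) is enforced to
$10^{-6}$ kcal/mol and violated partitions are rejected with the
residual.

### Toy energy backend

The aggregator and decomposer are engine-agnostic (`load_energy_table()`
ingests any delimited table in kcal/mol).  The bundled toy backend is a
small, fully specified energy function for exercising that machinery on
systems with closed-form answers — it is a test harness, not a force
field:

* Coulomb electrostatics with 332.06 kcal Å mol$^{-1}$ e$^{-2}$;
* 12-6 Lennard-Jones with Lorentz–Berthelot combining;
* Still-form Generalized Born with *fixed input* Born radii (no
  descreening recomputation), interior dielectric 1, water dielectric
  78.5; the single-ion limit reproduces the Born formula exactly;
* $\Delta G_{np} = \gamma \cdot \mathrm{SASA} + b$ with $\gamma =
  0.00542$ kcal mol$^{-1}$ Å$^{-2}$ and $b = 0.92$ kcal/mol, SASA by
  Shrake–Rupley with a deterministic 960-point spiral per sphere and a
  1.4 Å probe.  Note the intercept does not cancel between the three
  molecules: at infinite separation $\Delta G_{np} \to -b$.

The electrostatic constant and dielectrics are declared defaults, not
inferred from any reference calculation; published MM/GBSA tables rarely
state the GB variant, salt treatment or frame-sampling interval, so
externally computed tables are ingested as-is and only the arithmetic
above is applied to them.

## The synthetic ensemble generator

No trajectories are deposited for the study systems, so every
quantitative target in this package is *parameter recovery*: a seeded
generator encodes the published ensemble statistics, and the analysis
stack must recover them.  The generator is first-class, tested code.

A `basin_spec()` is a 2D normal in CV space; an `ensemble_spec()` is a
mixture of them plus per-residue fluctuation amplitudes, optional
block-correlation impositions, and a calibrated mean displacement.
Sampling picks a component per frame by weight and draws (x, y); angles
are **reflected** into (0°, 180°] — a bend drawn past 180° is the same
geometry as its mirror image.  (Clamping, the obvious alternative, piles
a probability atom onto the boundary bin and manufactures a spurious
free-energy minimum at exactly 180°.)

`embed_coordinates()` realizes the CVs geometrically: the pocket
triangle is the template triangle rescaled about its centroid to the
requested perimeter; the arginine `CZ` is rotated about `CG`, in the
CA–CG–CZ plane, to the requested angle.  Every other residue receives
isotropic Gaussian displacements with per-axis standard deviation
$a_i/\sqrt{3}$, so its RMSF converges to the prescribed amplitude
$a_i$.  The CV-defining residues move only rigidly — one shared
translation for the pocket trio (amplitude: the mean of their
prescribed values), one for residue 549 — so recomputing the CVs from
coordinates reproduces the requested series to numerical precision.

Correlation blocks use one latent-factor model: residues of a block pair
share (or, for sign −1, negate) a common latent displacement carrying a
fraction `corr_strength` (default 0.85) of their variance.  The raw
inter-block correlation equals that fraction; global superposition then
absorbs part of the coherent motion, leaving DCCM entries near ±0.6 —
the minimal mechanism that makes the DCCM testable without building a
full covariance model.  CV residues are excluded from blocks so the
round-trip guarantee survives.

The mean displacement from the starting structure is set by a fixed
random drift field, shared within each CV residue group, ramped in over
the equilibration fraction (so RMSD traces rise and then plateau, as
equilibrating simulations do) and scaled by a short calibration pass — a
quadrature initial guess refined by one secant step against a 400-frame
subsample — so the post-window mean RMSD lands on `mean_rmsd_target`.
The calibration targets the *mean* of the RMSD series; its variance is
whatever the fluctuation amplitudes imply, and is much smaller than the
frame-to-frame variance of a real trajectory.

### Presets

`apc_presets()` encodes the four simulated systems:

| preset | basins (Å, °) | weights | mean RMSD (Å) |
|---|---|---|---|
| `apo` | M1 (23.5, 170), M2 (24.5, 110), background (24 ± 3, 140) | 0.1264 / 0.3752 / 0.4984 | 3.45 |
| `apc108` | (24, 170), broad perimeter (σ 1.2 Å) | 1 | 2.43 |
| `apcasef` | (24, 113), narrow | 1 | 2.49 |
| `apcdasef` | (24, 110), broad | 1 | 3.41 |

Published sources state basin centers and populations but not basin
*widths*; the presets use σ = 0.25 Å / 5° for the two apo conformers —
narrow enough that the default assignment rectangles capture >99.6% of
each basin's own samples, so recovered occupancies are limited by
binomial sampling error, not by the boundary convention.  The sporadic
non-basin density is described only as flanking the basins on both
sides of the perimeter axis; it is emulated as a single wide component
(σ 0.8 Å, 35°) whose `split_perimeter = 3` Å places its two lobes at
21 and 27 Å.  A unimodal background centered between the basins would
leak several percent of its mass into the assignment rectangles and
make the published occupancies unrecoverable under any boundary — the
bimodal shape is both the more faithful reading and the testable one.
Per-residue amplitudes for the apo and MAI-108 systems follow the
published per-residue values (R549 1.10/0.73, F458 1.31/1.08, R463
1.06/1.17, F510 1.16/0.79 Å) with 1.0/0.85 Å elsewhere; the peptide
systems' per-residue values are not printed and are set qualitatively
(Asef globally lower, the truncated peptide higher, F510 highest
there).

### What the generator does and does not emulate

It emulates: a multi-basin CV density with prescribed occupancies;
per-residue fluctuation amplitudes; block-correlated and
anti-correlated motions; equilibration followed by a stationary
displaced regime.  It does not emulate: chain connectivity or sterics,
force-field physics, kinetics (frames are independent draws, so no
autocorrelation), realistic RMSD variance, or any real APC geometry
beyond the atom labels the CVs need.  Passing recovery tests therefore
demonstrates that the *analysis* stack measures what it claims on data
with known truth — not that the generator reproduces molecular
dynamics.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear atoms; collinear input is an
  error, not a silent pseudo-inverse.
* PDB coordinates round-trip at the format's 0.001 Å precision;
  inconsistent atom counts across models and unparseable coordinate
  fields fail with the model number / line number.
* Selection grammar: `and` binds tighter than `or`; empty selections
  warn rather than fail, except where an operation cannot proceed.
* Histogram padding is 2% per side; a degenerate (constant) axis is
  padded by 1% of its magnitude so a one-point cloud still bins.
* Representative-frame clustering subsamples evenly above 500 members,
  trading metric fidelity for a hard quadratic-cost bound.
* All randomness flows from the `seed` in the spec or config; identical
  config and seed give byte-identical outputs.

## Problem sizes

The bundled acceptance computations use 40,000 CV frames for occupancy
and landscape-minimum recovery and a 20,000-frame, 160-residue embedded
trajectory for RMSD/RMSF recovery; unit tests use 2,000–20,000-frame
ensembles.  These sizes put binomial error well inside the published
precision while the whole battery runs in minutes on one CPU core.

## Known limitations

* Basin membership is rectangular; no watershed or density-cluster
  assignment.
* The straight-path barrier test can under-merge basins connected only
  through a curved valley; for the landscapes here (near-separable
  Gaussian mixtures) the straight path is adequate.
* The toy GB backend uses fixed Born radii; it is not a substitute for
  a real MM engine and is not intended to reproduce published energy
  tables from coordinates — those enter via `load_energy_table()`.
* No reweighting (WHAM), kinetic modeling, or error bars from block
  averaging.
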