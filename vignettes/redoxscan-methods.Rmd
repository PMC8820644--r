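---
title: "Proximity-based detection of redox-labile disulfide bonds: models and design"
author: "redoxscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity-based detection of redox-labile disulfide bonds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxscan)
```

## The scientific problem

A subset of protein disulfide bonds are *labile*: they are preferentially
reduced by small reducing agents or thiol oxidoreductases, and their
cleavage can switch protein conformation and function (allosteric
disulfides). Predicting which of a protein's disulfides is the labile one
is valuable — for coagulation factors such as FVIII it informs both
mechanism and protein engineering — but assays are slow and structures
alone are only weakly predictive.

The approach implemented here reasons from dynamics: simulate the protein
in the presence of a large excess of a reducing probe (TCEP or DTT, at a
100:1 probe:protein ratio) and ask *which disulfide the probes actually
reach*. Reduction requires physical proximity of the probe's reactive
centre to the S–S bond, so probe-to-bond proximity over an ensemble of
trajectories is a direct, physics-based proxy for lability — one that
captures not just static solvent exposure but also specific
probe–surface interactions.

## Models and statistics

### Proximity statistics and the reduction criteria

For each saved frame the mass-weighted centre of mass (COM) of every
probe molecule is compared with the COM of each disulfide (by default the
two sulfur atoms; a whole-cystine mode exists for sensitivity analysis).
Three candidate per-bond statistics are computed: the mean COM–COM
distance over probes, the minimum distance, and the number of probes
within the contact cutoff. The hard count discriminates best in practice:
mean distance is dominated by bulk probes, and minimum distance saturates
near the excluded-volume contact limit for every exposed bond. A smooth
companion, the coordination number
$\mathrm{CN}=\sum_i\sum_j \frac{1-(r_{ij}/r_0)^n}{1-(r_{ij}/r_0)^m}$
(defaults $r_0 = 3$ nm, $n = 6$, $m = 12$; the removable singularity at
$r = r_0$ is evaluated as its limit $n/m$), is provided for use as a
collective variable or soft count.

The **distance criterion** calls a bond reduced at the first frame where
any probe COM comes within the cutoff — 0.8 nm for TCEP, 0.6 nm for the
smaller DTT, scaled to the probes' radii of gyration (≈ 0.37 nm and
≈ 0.26 nm respectively). Events are necessarily evaluated at saved-frame
resolution; "as soon as" means the first saved frame with a contact. Ties
within a frame resolve by smallest distance, then bond order, making the
scan a pure function of the trajectory. One call is made per trajectory:
the physical protocol stops a simulation at the reduction event, and the
companion simulator mirrors that with its `stopWithin` option.

The **distance+energy criterion** additionally requires the reduction to
be energetically favourable: the candidate disulfide is cleaved in the
event-frame structure (the S–S bonded term removed and each sulfur capped
with a hydrogen at 0.134 nm along the former bond axis), both forms are
steepest-descent minimised, and the call is accepted only if the cleaved
form ends strictly lower, $E_{fin} < E_{in}$. A failed contact becomes
refractory for 100 ps (the literature is silent on whether the same
contact is retried; a refractory window avoids re-testing the identical
geometry) and the scan continues.

Per-trajectory calls aggregate by simple proportion into per-bond
lability probabilities plus a no-call fraction, which sum to one.

### The energy backend

The reference workflow minimises with a full biomolecular force field
inside the MD engine. Re-implementing that machinery is neither practical
nor the point: what the criterion contributes is the *comparison logic*.
The built-in backend is therefore a deliberately small vacuum potential —
harmonic bonds (keyed by element pairs) and angles, Lennard-Jones with
Lorentz–Berthelot combination, and Coulomb truncated at 1.2 nm, the
conventional nonbonded cutoff — with covalent topology inferred from
covalent radii. The backend is pluggable: `energyCheck()` accepts any
function returning $(E_{in}, E_{fin})$, so engine-computed energies can be
injected for replication studies, and an always-accepting backend turns
the combined criterion into the pure distance criterion (an equivalence
the tests verify exactly). Two caveats are documented loudly: solvent is
ignored (vacuum minimisation), and in vacuum with zero partial charges
cleavage usually *is* energetically downhill — rejections in practice
come from injected backends that know about solvent and packing.

### Static disulfide geometry

Per bond: solvent accessibility (sum of the two sulfurs' Shrake–Rupley
areas; probe radius 1.4 Å, 960 sphere points by default, deterministic
golden-spiral quadrature), the Cα–Cα distance in Å, the five χ dihedrals
(χ1 = N-Cα-Cβ-SG, χ2 = Cα-Cβ-SG-SG′, χ3 = Cβ-SG-SG′-Cβ′, mirrored χ2′,
χ1′; IUPAC signs, degrees), and the 20-class conformation label. The
sign-vector → label mapping ships as an auditable CSV
(`inst/extdata/disulfide_conformations.csv`): handedness follows the sign
of χ3; the shape is Spiral when χ2 and χ2′ both agree in sign with χ3,
Staple when both oppose it, Hook otherwise; prefixes come from χ1/χ1′,
with the mixed prefix of the symmetric Spiral/Staple shapes merged to
`+/-`, giving exactly 20 labels over the 32 sign vectors. Labile bonds
tend to combine high sulfur accessibility (> 30 Å²) with a short Cα–Cα
distance (< 5 Å) and the −RHStaple / ±RHHook conformations.

### Conformational analytics

Trajectory series of the mass-weighted radius of gyration, intramolecular
hydrogen bonds (donor–acceptor ≤ 0.35 nm and H-D-A angle ≤ 30°, the
standard trajectory-tool geometric criterion, which no primary source
specifies further), total SASA, and backbone RMSD after Kabsch
superposition (N–Cα–C atoms). Frames are clustered with the greedy
neighbour-count (Daura) algorithm at a 0.2 nm backbone-RMSD cutoff; ties
break deterministically to the lowest frame index, so cluster 1 is always
the largest and permuting frames relabels nothing. The representative
conformation is the centroid of the largest cluster after discarding a
configurable equilibration window. Conformational change between two
representative structures is reported as per-residue Cα displacement
after whole-structure or per-domain superposition — the numeric
counterpart of structure-similarity colouring in molecular-graphics
tools, whose exact similarity parameter is visualization-specific; a
displacement map carries the same information with explicit units.

### MS quantitation

The % reduction of a cysteine is the mean over control peptides of the
ratio-of-ratios of precursor areas (target sample vs fully-reduced
reference), × 100. Control normalisation cancels any common per-sample
loading factor, which the tests verify as an exact invariance. Biological
and technical replicates are pooled into one mean ± sample SD (the
reference analyses report a single mean ± SD per cysteine; no hierarchy
is specified). Values above 100% are reported with a warning rather than
clipped — noise can exceed the fully-reduced reference, and clipping
would bias means. MS residue numbering that includes a signal peptide is
handled by an explicit offset (e.g. +19), never silently.

## The synthetic-data generator

The simulator exists to give every criterion a known answer. It emulates
the study conditions — a cubic box (7.9 nm default), 100 probe beads per
protein, frames 10 ps apart, 1000 frames by default — with overdamped
dynamics: probes are single COM beads (the criteria only ever see probe
COMs; a three-bead mimic exists for COM-code testing) performing seeded
Gaussian random walks (step 0.12 nm/frame) with periodic wrapping,
hard-core rejection within 0.45 nm of any protein atom, and an optional
Metropolis bias toward one bond's COM
($U(r) = -k\,s(r)$ with $s$ the switching function at 2 nm range;
$k = 4\,k_BT$ default). Probes start in bulk solvent, at least 2 nm from
every bond COM. The toy protein is a two-shell globule whose cystines are
placed at designed burial: buried pairs end below 5 Å² sulfur
accessibility, surface pairs above 30 Å², which the tests confirm by
computation rather than assumption.

What this deliberately does **not** capture: real kinetics (no inertia,
hydrodynamics or solvent structure), probe shape and orientation,
protein flexibility (the protein is static), and chemistry (contact is a
proxy, not a reaction). Passing the recovery tests therefore shows the
*analysis machinery* is correct and sensitive — that first-passage calls
aggregate to the designed ground truth — not that any particular real
protein's lability is predicted; for real systems the trajectories must
come from an MD engine, and the pipeline accepts such trajectories
unchanged.

Default problem sizes used by the test suite (20 trajectories × ≤ 300
frames × 100 probes, 50 repetitions for the recovery rate; 40-frame
clustering oracles; 960-point SASA on ~250-atom structures) were chosen
so the whole suite runs on a single CPU in minutes while keeping every
statistical check comfortably powered.

## Numerical choices and degenerate inputs

- Internal length unit is nm; PDB files convert at the boundary, SASA and
  Cα distances are reported in Å as structure tables conventionally do.
- Orthorhombic boxes only; triclinic input is rejected with a clear error
  (every targeted system is cubic). Minimum-image arithmetic is exact for
  orthorhombic cells and validated against 27-image enumeration.
- COM of a boundary-straddling molecule uses reference-atom unwrapping
  (shift each atom to the image nearest the first atom), matching common
  trajectory-tool behaviour.
- Disulfide detection pairs SG atoms greedily nearest-first at a 0.25 nm
  cutoff (the S–S bond is ~0.205 nm); an SG within the cutoff of two
  partners warns and takes the nearest. Detection is invariant to atom
  order and output is sorted by residue id.
- The switching function evaluates its removable singularity as the limit
  $n/m$ within $10^{-9}$ of $r_0$.
- The steepest-descent minimiser uses step doubling/halving (×1.2 on
  accept, ×0.5 on reject) and declares convergence on the maximum atomic
  force; its accepted-energy trace is non-increasing by construction.
- A χ dihedral of exactly 0° makes the conformation class undefined; the
  label `unclassifiable` is returned rather than an arbitrary sign.
- Probe conformer generation (for probe-size benchmarks) uses OpenBabel's
  stochastic 3D builder, which cannot be seeded from R; size estimates
  therefore average an ensemble of conformers rather than trusting one.

## Known limitations

- The default energy backend is a desk-scale vacuum potential: adequate
  for criterion logic and toy systems, not for quantitative energetics of
  real proteins — use the backend hook with engine-computed energies.
- XTC/TRR trajectory formats have no reader in this R stack; multi-model
  PDB and DCD are supported, and conversion is left to standard tools.
- One reduction call per trajectory is assumed. Ensemble probabilities
  over bonds therefore sum (with the no-call fraction) to one; protocols
  allowing multiple reductions per trajectory would need the scan loop
  relaxed.
- Hydrogen-bond counting requires explicit hydrogens; heavy-atom-only
  models should disable that series.
- The Shrake–Rupley quadrature is deterministic but finite: rotation
  invariance holds to ~0.5% at 960 points, and per-bond SASA of real
  structures is best interpreted by ranking and thresholds rather than to
  fractions of an Å².
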