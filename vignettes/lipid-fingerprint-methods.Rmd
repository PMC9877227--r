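---
title: "Methods: lipid fingerprint analysis of protein-membrane trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid fingerprint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidprint)
```

# The problem

When a peripheral membrane protein such as MLKL binds a complex bilayer, it
does not see an average membrane: it recruits some lipid species (anionic
phosphoinositides, cholesterol) and displaces others (bulk
phosphatidylcholine), changing the local surface charge, the lateral
packing, and the height profile of the leaflet it binds. This package
quantifies that "lipid fingerprint" from MD trajectories through a set of
per-frame geometric estimators with block-averaged uncertainties, plus a
synthetic generator that plants every signal the estimators are supposed to
find.

This vignette documents the models and conventions behind each estimator,
the tunable parameters and their defaults, what the synthetic generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

# Data model and geometric conventions

A `membrane_system` holds an atom table (residue identity, protein / lipid /
solvent / ion segment, element, per-atom radius), per-frame coordinates in
Angstrom, per-frame orthorhombic box lengths, time stamps in nanoseconds, a
species registry, and a protein domain table. Boxes are strictly
orthorhombic; triclinic input is rejected rather than silently mistreated,
which keeps the minimal-image distance exact and trivial
(`d_k -= L_k * round(d_k / L_k)` per axis). GRO files (nm) are converted to
Angstrom on load.

Each lipid is represented laterally by a single **marker atom**: the
phosphorus for phospholipids and the hydroxyl oxygen O3 for sterols. The
species configuration (YAML or `species_config()`) declares, per species,
its residue names, the marker, the hydrophilic and hydrophobic atom-name
sets, the formal headgroup charge in elementary units, and the nominal mole
fraction. The default registry is the five-species plasma-membrane model at
40:32:20:4:4 mol% with charges 0/0/0/−3/−5 e. Formal charges are
configuration, not constants, because published charge maps rarely state
whether full partial charges or formal headgroup charges were used; the
formal-charge-at-marker convention is this package's default.

**Leaflets** are assigned per frame: the midplane is the mean z of all
marker atoms, and a lipid is "upper" when its marker z is at or above the
midplane. Flips are possible and are simply reported, not smoothed — at
nanosecond frame spacing genuine flip-flop is rare, and smoothing would hide
generator or input errors. The **binding leaflet** is decided at the first
frame in which any protein Cα comes within the contact cutoff (12 Å,
inclusive) of any marker atom, by majority vote among the markers inside the
cutoff at that frame. The majority-vote rule is an operational choice: the
underlying notion ("the leaflet the protein touches") has no unique
definition when both leaflets' images are nearby, and the vote makes the
decision deterministic.

The protein **domain table** maps residue-id ranges to labels. For MLKL the
canonical table is `mlkl_domains()`: the four-helical bundle (1–121), the
brace helices (133–175), and the pseudo-kinase domain (193–459). The
residues in the gaps (122–132, 176–192) are labelled "linker" and excluded
from per-domain metrics — the ranges come with gaps, and inventing a
membership for the inter-domain residues would bias per-domain counts.

# Estimators

## Contacts, depth, RMSD

All contact criteria are inclusive (`distance <= cutoff`), stated explicitly
so tests can be exact. Two contact definitions coexist deliberately:
per-residue contact frequency uses the residue's **Cα** against
binding-leaflet markers, while domain × species contact counts use **all
protein heavy atoms** against the species' markers. These mirror the two
conventions commonly used for residue-level footprints versus domain-level
contact heatmaps, and unifying them would change both quantities.

The domain–membrane distance is the absolute z-separation between the
domain's Cα center of mass and the mean marker z of the binding leaflet — a
z-plane convention rather than a 3D COM–COM distance, chosen because bound
domains plateau near zero under it. Insertion depth is signed positive past
the marker plane toward the bilayer core; the deepest residue is the argmax
of the window-mean depth with ties broken by lowest residue id
(determinism). Only residues that ever enter the contact cutoff are
profiled, so the profile is not polluted by solvent-facing residues.

RMSD and RMSF superpose Cα coordinates onto the reference frame by
rigid-body least squares (bio3d's Kabsch-type fit) before measuring; RMSF is
taken about the window-mean fitted structure. A rigidly translated or
rotated trajectory therefore scores exactly zero.

Uncertainties on window means are **block-averaged standard errors**: the
window is split into 5 equal contiguous blocks (configurable) and the SE is
`sd(block means)/sqrt(blocks)`. Five blocks is the coarsest split that still
gives a usable variance estimate on the ~50–500-frame windows the package
targets; per-frame SEs would be badly anticonservative under serial
correlation.

## Hydrogen bonds

The criterion is geometric: donor–acceptor heavy-atom distance ≤ 3.2 Å
(donor-to-acceptor, not hydrogen-to-acceptor) and a D–H⋯A angle within 30°
of linearity, i.e. the angle at the hydrogen is ≥ 150°. "Cutoff angle of
30°" without a stated vertex is read as deviation-from-linearity, the
convention of the common trajectory-analysis tools. Donors are N/O atoms
with a bonded hydrogen — inferred covalently (< 1.2 Å) for the protein,
declared by name-pairing in the species configuration for lipids; acceptors
are all N/O atoms. Only protein↔lipid pairs are reported (intra-protein
bonding is out of scope), and donor and acceptor must belong to different
residues. Counts are per-frame detections with no occupancy smoothing;
because one donor can carry two hydrogens, both the (D,H,A)-triple count and
the unique (D,A)-pair count are reported.

## Surface maps

Density, height and charge maps share one accumulation engine: one sample
per selected marker per frame, binned in **fractional (box-relative)
coordinates** with half-open bins. Fractional binning is what preserves the
conservation identity `sum(cells) = N_selected × frames` exactly under a
fluctuating (semi-isotropically coupled) box; physical cell areas are quoted
with the window-mean box. The default grid is 100 × 100 (~1.7 Å cells at the
full 173 Å box), and the default sampling interval is the frame interval —
one nanosecond in the generator's defaults, matching the cumulative-plot
convention of accumulating coordinates in one-nanosecond intervals.

Height maps use z_f = z − z_o with z_o the mean z of the selection in the
*first frame of the window*, so a rigid z-shift of the whole trajectory
cancels; cells never sampled are `NA` ("white patches" — absence of
headgroup atoms). Charge maps deposit each species' formal charge at its
marker position; with all-neutral species the map is identically zero.

The protein mask covers every grid cell whose center lies inside the
xy-projected vdW disk of any protein heavy atom; window masks are unions
over frames. Projected area is covered cells × cell area.

## Packing defects

The original image-based method renders the leaflet top-down, colors
hydrophobic atoms and headgroups differently, and runs contour detection on
the pixels. This package performs the same computation without a graphics
stack: every lipid heavy atom of the leaflet is rasterized as a vdW disk
onto a 1 Å grid (configurable — the cell size plays the role of pixel size),
and within each cell the atom with the highest z as seen from the water side
wins (the lower leaflet is handled by z-mirroring). Ties in z are broken in
favour of hydrophilic cover, so a headgroup is never hidden by a tail bead
at exactly its own height. Atoms more than 10 Å below the leaflet's marker
plane do not count as cover; uncovered cells are "empty" and are merged into
the hydrophobic-exposure class for defect purposes (in a periodic bilayer
the footprint spans the whole box, so a hole in headgroup cover *is*
exposure of the interior).

Defect components are connected sets of exposure cells under wrap-aware 8-
connectivity (4-connectivity available); components below 5 Å² (default,
configurable to 0) are discarded as single-cell speckle. Components are
ordered by decreasing area with centroid tie-breaks, and centroids are
computed circularly so boundary-straddling defects report sensible centers.
The local defect percentage is
`100 × (defect area inside the protein mask) / (mask area)`, and defect
statistics report per-leaflet counts and total areas per frame with block
SEs, plus the local-percentage series in fixed-width frame bins (default
100 frames, mirroring 100-ns bars at 1 ns/frame).

Absolute areas are validated against planted fixtures (below), not against
any published absolute magnitudes: the pixel-to-area calibration of the
original image pipeline is not recoverable, so the grid resolution here is a
stated parameter rather than a fitted one.

## RDFs and the fingerprint

`rdf()` is the standard shell-normalized pair-distance estimator:
minimal-image distances histogrammed at `dr` (default 0.1 Å), normalized per
frame by `4 π r² dr` at the bin center and by the target's number density in
the box, averaged over the window, with `r_max` capped at half the smallest
box length. Protein-anchored RDFs default to the Cα of the deepest inserted
residue as computed by `insertion_depth()`, overridable by residue id (so a
specific residue choice can be reproduced). Lipid–lipid RDFs restrict both
selections to one leaflet's markers and exclude self-pairs. Because a
leaflet-restricted, in-plane analysis is ambiguous between 2D and 3D
normalization, the default is the 3D estimator and a `lateral = TRUE` flag
switches to 2D ring normalization (`2 π r dr`, area density); the ideal-gas
and lattice tests cover both.

`local_composition()` counts binding-leaflet markers inside a region — the
window-union protein mask ("underneath the protein", matching the projection
language of the mapping analyses) or a lateral radius about the protein axis
(default 15 Å at test scale) — per frame and per species, reporting mean
counts, regional mole fractions, all pairwise ratios, and each species'
**enrichment index** (regional mole fraction / bulk leaflet mole fraction)
with block SEs. `fingerprint_delta()` is pure bookkeeping over two reports
with identical region definitions and species sets. At the full-scale
composition the whole-leaflet report reproduces the exact initial ratios
DOPE:PIP₂ = 5 and DOPC:PIP₂ = 10 by construction of the composition
arithmetic.

# The synthetic generator

The generator emulates the study conditions every estimator targets, with
controllable ground truth:

- **Composition and scale.** Defaults are the full-scale study conditions:
  600 lipids per leaflet at 40:32:20:4:4 mol% in a 173 × 173 Å lateral box
  (≈50 Å²/lipid). Species counts use largest-remainder rounding of
  `n × mole fraction` (ties broken in species order), so per-species counts
  are exact, documented test targets: 240/192/120/24/24 at n = 600.
  `test_config()` is the same generator at 64 lipids per leaflet in a
  56.6 Å box for fast tests; the vignette- and test-scale problem sizes
  (64–150 lipids/leaflet, 60–500 frames) were chosen as the smallest systems
  that keep every geometric property of the full-scale configuration.
- **Geometry.** Lipids are coarse bead clusters on a jittered rectangular
  lattice: phospholipid = marker P + two hydrophilic headgroup beads + four
  tail beads; cholesterol = O3 marker (seated 1 Å below the phosphate plane,
  as sterol hydroxyls sit slightly below the phosphates) + three ring/tail
  beads. Bead radii are *effective* coarse radii (4.5–6 Å heads, 2.5 Å
  tails) chosen so an intact leaflet's headgroup disks tile its surface
  completely — the property the defect detector's negative control needs —
  not literal atomic vdW radii. The analyses only read roles, radii and
  coordinates, so this coarseness is invisible to them.
- **Dynamics.** Lipids take independent per-frame 2D Gaussian steps of
  variance `2 D Δt` per axis with periodic wrapping (D defaults to
  1 Å²/ns ≈ 10⁻⁷ cm²/s, a realistic lateral lipid diffusion coefficient;
  Δt = 1 ns), plus small non-cumulative z noise (σ = 0.2 Å) so leaflets
  never drift apart. The ensemble MSD follows 4 D t, which the tests verify
  seed-averaged to 15%.
- **Binding and recruitment.** A rigid pseudo-protein disk (sunflower layout
  of residues, each with a Cα, a donor N–H pointing membrane-ward, and an
  acceptor O) descends linearly to its bound height at the configured
  binding frame, then stays put. After binding, species with a nonzero bias
  drift kinematically toward the protein axis (default PIP₂ at 0.5 Å/ns
  inside a 30 Å capture radius, never closer than 5 Å). Recruitment is
  kinematic rather than energetic on purpose: the steady-state enrichment
  must be *controlled* ground truth, not an emergent property to be
  estimated twice. The generator records the realized enrichment in the
  15 Å analysis region over the final 10% of frames, from its own
  coordinates, as the recovery target.
- **Plantable signals.** `plant_hbond_geometry()` repositions n lipid
  acceptor beads to exact 2.9 Å / 180° geometries under distinct donors
  (120° negative control available) and pushes every incidental
  protein–lipid donor–acceptor pair beyond 3.4 Å, so the detector's expected
  count is exactly n. `plant_defect_patch()` clears a circular disk of
  headgroup cover: the displaced headgroup beads are re-seated uniformly on
  a rim circle whose distance is solved numerically so the uncovered area
  equals π r² exactly (the rim disks scallop the boundary; solving for the
  uncovered area rather than placing disks tangentially is what makes the
  planted area accurate to a few percent at 1 Å cells), and the tails of
  in-patch lipids are raised to just below the head region. Patches may
  cross the periodic boundary.

What the generator does **not** emulate: conformational protein dynamics,
bilayer undulations and thickness fluctuations, water and ions, correlated
lipid motion, realistic lipid shapes, or any force field. Passing tests
therefore demonstrate that the estimators measure what they claim on data
with known structure — conservation identities, oracle equivalence, planted
signal recovery — not that the package's numbers on real trajectories carry
the generator's accuracy. On real data the estimators inherit the usual MD
caveats (sampling, force-field realism, box artifacts).

# Numerical choices and degenerate inputs

- Contact and hydrogen-bond cutoffs are closed intervals; boundary geometry
  counts.
- When all markers share one z, leaflet assignment puts everything "upper"
  (the ≥ rule) and warns rather than failing.
- A leaflet with zero lipids classifies as all-empty with a warning.
- Deepest-residue and defect-ordering ties break deterministically (lowest
  residue id; largest area then centroid).
- `block_se()` returns `NA` when the window is shorter than the block count
  instead of fabricating a variance.
- The lattice factorization of `lipids_per_leaflet` must be near-square
  (aspect ≤ 3); prime counts are rejected with advice rather than silently
  building a degenerate strip.
- The DCD writer emits CHARMM-style Fortran records with per-frame crystal
  records; round-trips are verified against an independent reader. XTC is
  not supported in this stack; DCD or multi-model PDB are the trajectory
  inputs.
- End-to-end pipeline runs are bit-reproducible for a fixed seed and config;
  the manifest records a parameter hash, stage status and notices (e.g.
  "protein never bound", in which case binding-dependent stages are skipped
  explicitly rather than producing vacuous output).

# Known limitations

- Leaflet assignment by instantaneous midplane mis-labels lipids during
  large undulations; acceptable at these box sizes, wrong for buckled
  membranes.
- The binding-leaflet majority vote is undefined-by-tie in principle; the
  first-listed leaflet wins a tie.
- Surface classification uses a hard 10 Å depth window below the marker
  plane; deeply splayed tails below that window are invisible to the defect
  detector.
- The RDF estimator normalizes with the shell approximation `4 π r² dr` at
  bin centers (exact in the dr → 0 limit); at the default 0.1 Å bins the
  bias is far below the estimator's noise.
- Charge maps use formal headgroup charges at the marker atom, not partial
  charges integrated over the headgroup.
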