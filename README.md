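# lipidprint

Quantifying the **lipid fingerprint** of a peripheral membrane protein: how a
bound protein reshapes the local lipid composition, hydrogen bonding, surface
charge, packing and topology of a complex bilayer in molecular dynamics
trajectories.

The package was written for the analysis of MLKL — the pseudokinase that
executes necroptosis by binding and permeabilizing the plasma membrane — on a
five-species inner-leaflet plasma-membrane model
(DOPC:Chol:DOPE:PIP:PIP₂ at 40:32:20:4:4 mol%), but every routine is generic
over a user-supplied species configuration.

## What it computes

For a structure + trajectory (PDB/GRO + DCD or multi-model PDB) with a
species configuration mapping residue names to lipid species, marker atoms
(P for phospholipids, O3 for cholesterol), hydrophobicity classes and formal
charges:

- **Leaflet assignment and binding detection** — per-frame marker-z vs. the
  instantaneous midplane; the binding leaflet and first-contact frame from
  the 12 Å Cα–phosphate contact criterion.
- **Contacts and insertion** (`residue_contact_frequency`,
  `domain_species_contacts`, `insertion_depth`, `domain_com_distance`,
  `rmsd_series`, `rmsf`) — per-residue % contact time, per-domain ×
  per-species contact counts, signed insertion depth past the phosphate
  plane and the deepest inserted residue, with block-averaged standard
  errors.
- **Hydrogen bonds** (`detect_hbonds`, `count_hbonds_by_species`) — the
  geometric criterion (donor–acceptor ≤ 3.2 Å, D–H⋯A within 30° of linear),
  counted per lipid species and compared between analysis windows.
- **Surface maps** (`density_map`, `height_map`, `charge_map`,
  `protein_mask`) — cumulative 2D histograms of marker positions per leaflet;
  relative height z_f = z − z_o; formal-charge deposition; vdW-disk protein
  projections.
- **Packing defects** (`classify_surface`, `find_defects`,
  `local_defect_percent`, `defect_stats`) — grid rasterization of the
  leaflet surface, wrap-aware connected components of hydrophobic exposure,
  and the local defect percentage
  `% = 100 · local defect area / projected protein area`.
- **RDFs and the fingerprint** (`rdf`, `lipid_lipid_rdf`,
  `local_composition`, `fingerprint_delta`) — shell-normalized g(r) anchored
  at protein atoms (conventionally the deepest inserted residue's Cα) or
  between lipid species, and regional composition reports: counts, mole
  fractions, pairwise ratios (e.g. DOPE:PIP₂, DOPC:PIP₂) and enrichment
  indices relative to the bulk leaflet.
- **Pipeline** (`run_pipeline`, `validate_config`) — the full analysis from
  one config, with CSV/JSON artifacts, a manifest and a summary.

A **synthetic trajectory generator** (`synthetic_config`, `build_bilayer`,
`simulate_trajectory`, `plant_hbond_geometry`, `plant_defect_patch`)
produces coarse-bead bilayer + pseudo-protein trajectories with known ground
truth — exact species counts, Brownian lateral diffusion, controlled
recruitment toward the protein, plantable hydrogen-bond geometries and
hydrophobic-exposure patches — so every analysis stage is testable without
multi-microsecond trajectories.

## Worked example

A test-scale synthetic run — 64 lipids per leaflet, 300 frames at 1 ns, the
protein binding at ~50 ns, PIP₂ recruited at 0.5 Å/ns inside a 25 Å capture
radius:

```r
library(lipidprint)

cfg <- test_config(n_frames = 300L, binding_frame = 50L,
                   bias = c(PIP2 = 0.5), seed = 7L)
sys <- simulate_trajectory(build_bilayer(cfg), cfg)

bl <- detect_binding_leaflet(sys)
#> binding leaflet: upper   first-contact frame: 39

fp_final <- local_composition(sys, 251:300, leaflet = bl$leaflet)
print(fp_final)
#> fingerprint_report — radius 15.0 A about protein axis — upper leaflet, frames 251 to 300
#>  species mean_count        se mole_fraction enrichment
#>     DOPC       5.48 0.2267157        0.3374      0.831
#>     CHOL       4.02 0.3072458        0.2475      0.792
#>     DOPE       4.02 0.2576820        0.2475      1.219
#>      PIP       1.34 0.1720465        0.0825      1.760
#>     PIP2       1.38 0.2332381        0.0850      2.719
#> key ratios: DOPE:PIP2 = 2.913 ; DOPC:PIP2 = 3.971
```

The protein first touches the upper leaflet at frame 39 (the descent reaches
the 12 Å contact shell slightly before the configured bound frame). In the
final 50 ns the biased species is strongly enriched under the protein:
PIP₂'s regional mole fraction is 2.7× its bulk leaflet fraction, and the
DOPE:PIP₂ ratio has dropped from 5:1 (the composition's exact initial value)
to ~2.9:1 — the generator's controlled analogue of binding-site lipid
recruitment. Comparing windows directly:

```r
fp_init <- local_composition(sys, 1:50, leaflet = bl$leaflet)
fingerprint_delta(fp_init, fp_final)
#>   species ... enrichment_initial enrichment_final delta_enrichment
#> 5    PIP2 ...          0.0000000        2.7192118        2.7192118
```

The full pipeline version of the same run:

```r
bundle <- run_pipeline(list(
  synthetic = list(lipids_per_leaflet = 64L, box = c(56.6, 56.6, 100),
                   protein_residues = 16L, protein_radius = 12,
                   n_frames = 300L, binding_frame = 50L),
  initial_ns = 50, final_ns = 50, seed = 7, out_dir = "run_out"))
```

writes `residue_contacts.csv`, `domain_species_contacts.csv`,
`depth_profile.csv`, `hbonds_by_species.csv`, density/height/charge maps,
`defect_stats.csv`, `local_percent.csv`, per-species `rdf_*.csv`,
`fingerprint.csv`, `fingerprint_delta.csv`, plus `summary.json` and
`manifest.json`. A thin CLI wrapper lives at `inst/cli/lipidprint.R`.

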