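# ltpmob

Ligand calling and lipidome statistics for systematic lipid transfer
protein (LTP) screens.

LTPs solubilize lipids by extracting them from membranes into a
hydrophobic pocket; large-scale screens characterize which lipids each LTP
mobilizes by purifying LTP–lipid complexes over size-exclusion
chromatography (SEC) and reading the lipid content of the fractions by
mass spectrometry. `ltpmob` implements the downstream computational chain
of such a screen as a tested, reusable R package:

* **Co-elution ligand calling** (`call_ligands`): a lipid is called a
  candidate ligand of an LTP when at least a fraction *f* of its SEC
  signal lies in protein-containing fractions (presence rule, default
  *f* = 0.5) and its elution profile correlates with the protein's
  (Pearson *r* ≥ τ, default τ = 0.8). `merge_assays` combines in cellulo,
  in vitro and HPTLC evidence, keeping HPTLC only where no MS evidence
  exists.
* **Lipid nomenclature** (`parse_lipid_name`): shorthand names such as
  `PC(16:0/18:1)`, `SM(d18:1/16:0)`, `Cer(DH24:0/24:0)`, `PI(38:4)`,
  `PC-O(34:1)` are parsed into species records (class / subclass / chains
  / ether and sphingoid flags), and `lipid_volume` assigns a
  group-contribution molecular volume
  V = V_head + Σ_chains (n_C·V_CH2 + V_term − n_db·V_db).
* **Pocket volumes and the fit benchmark** (`pocket_volume`,
  `fit_ratio`, `buffer_zone_threshold`): interior cavity volume of a
  structure by voxelization and 6-connected flood fill from the exterior
  (probe-inflated van der Waals radii), lipid/pocket volume ratios, and
  the "buffer zone" threshold — the maximal ratio observed among known
  LTP–ligand pairs.
* **Gain-of-function statistics** (`welch_species_tests`,
  `paired_species_tests`, `perturb_screen`, `subclass_affected`,
  `fisher_enrichment`): per-species Welch (or paired) two-sided t-tests
  of induced vs control replicates on log2 intensities, Bonferroni
  correction over the full screen family, 1/k multiplicity down-weighting
  of species affected by k LTPs, subclass-level "affected" calls (a
  subclass is affected if any member species is), and Fisher exact
  enrichment of ligand subsets among affected pairs.
* **Lipid-pair co-regulation and co-localization**
  (`coregulation_score`, `manders_overlap`, `pair_enrichment`):
  mean directional agreement over joint-significant perturbations
  (+1 = perfect co-regulation, −1 = mutual exclusion), the Manders
  overlap coefficient Σaᵢbᵢ/√(Σaᵢ²·Σbᵢ²) over pixel or organelle
  intensities, and enrichment of co-mobilized pairs against random-pair
  nulls (Fisher + permutation).
* **Mobilized-lipidome profiling** (`chain_profile`, `compare_profiles`,
  `subclass_max_normalize`): min–max-scaled intensity distributions over
  total chain length and unsaturation, and signed shifts of the
  intensity-weighted mean (mobilized − reference).
* **Synthetic data with planted truth** (`gen_sec_run`, `gen_oe_panel`,
  `gen_coloc_maps`, `gen_cavity_fixture`, `gen_lipidome_pair`): every
  stage is testable end to end without external data, including an
  analytic hollow-sphere PDB fixture for the cavity-volume grid.

## Worked example

```r
library(ltpmob)

## a synthetic SEC run: 5 planted ligands among 100 background lipids
truth <- sec_sim_truth("STARD10", sprintf("lig%02d", 1:5),
                       sprintf("bg%03d", 1:100), noise_sd = 0.05)
run   <- gen_sec_run(truth, seed = 1)
call_ligands(run$protein, run$lipids)
#> <ligand_calls> STARD10 (in_cellulo): 5/105 lipids accepted
#>    ltp_id lipid_id      assay similarity presence normalized_intensity accepted
#> 1 STARD10    lig01 in_cellulo      0.993    0.856                0.111     TRUE
#> 2 STARD10    lig03 in_cellulo      0.991    0.826                0.292     TRUE
#> ...
```

All five planted ligands are accepted (similarity ≥ 0.8 against the
protein profile, ≥ 50% of their signal in protein-containing fractions);
all 100 background lipids are rejected.

```r
## cavity volume against the analytic hollow-sphere oracle
pdb <- tempfile(fileext = ".pdb")
fx  <- gen_cavity_fixture(pdb, shell_radius = 10, atom_radius = 1.5, seed = 1)
pm  <- pocket_volume(pdb, probe_radius = 0, grid_spacing = 0.5, radii = c(C = 1.5))
pm
#> <pocket_model> ?: 2606.8 A^3 (computed_grid, grid 0.5 A, probe 0 A)
fx$expected_cavity_volume        # (4/3)*pi*(10 - 1.5)^3
#> [1] 2572.441

## a lipid/pocket fit record
lv <- lipid_volume("PC(16:0/18:1)")
lv
#> <lipid_volume> PC(16:0/18:1): 1268.2 A^3
fit_ratio(lv, pm)$ratio
#> [1] 0.4865062
```

The grid estimate is within 1.4% of the closed form; the
palmitoyl-oleoyl-PC volume fills about 49% of this synthetic pocket, so
against a known-pair threshold of, say, 0.425 the pair would sit in the
pocket's buffer zone.

`run_pipeline(default_config(seed = 42), out_dir)` chains every stage on
synthetic data and writes TSV/JSON results plus a config snapshot; rerun
with the same config, it reproduces identical files.

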