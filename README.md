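# tmbundle

Comparative analysis of the heptahelical transmembrane (7TM) bundle of
class A G protein-coupled receptors, as a tested R package plus an
analysis workflow.

GPCR crystal structures differ in sequence, numbering and crystal
frame, yet share a seven-helix core.  `tmbundle` makes that core
directly comparable:

* **A fixed 200-residue bundle** in Ballesteros–Weinstein (BW)
  coordinates — helix I 1.35–1.59 (25 aa), II 2.38–2.67 (30),
  III 3.22–3.55 (34), IV 4.39–4.63 (25), V 5.36–5.65 (30),
  VI 6.29–6.60 (32), VII 7.32–7.55 (24).  Each receptor needs only its
  seven h.50 anchor residues (`author = anchor + (index − 50)`); anchor
  maps ship as plain-text configs.
* **SSM superposition**: helices are matched as secondary-structure
  elements (principal-axis anchors), then an iterated trimmed
  least-squares (Kabsch) refinement converges on the matched core.
  RMSD is always reported over all 200 Cα positions.
* **The comparative statistics**: pairwise RMSD / sequence-identity
  grids averaged by receptor pair, per-position averaged Cα deviation
  profiles, five membrane-slab sectional RMSDs, isolated-helix
  rigid-body comparison, ionic-lock census (Arg 3.50 – acidic 6.30,
  4.0 Å N–O cutoff), regional outlier screening, and Kabsch–Sander
  hydrogen-bond helix assignment with kink angles.
* **A synthetic bundle generator** (ideal helices, rigid whole-helix
  perturbations, seeded noise, truth tables) so every stage is testable
  offline, with known ground truth.

For whom: structural bioinformaticians comparing receptor families,
and anyone needing statistical constraints on per-residue backbone
variability for modelling or simulation of rhodopsin-like receptors.

## Worked example

Inject a known 2 Å rigid displacement of helix III into a synthetic
bundle (plus 0.2 Å coordinate noise) and recover it:

```r
library(tmbundle)
b   <- build_bundle()                       # chain + anchor map
ref <- extract_bundle(b$chain, b$map)
ch  <- perturb(b$chain, b$map, helix = 3, translation = c(2, 0, 0),
               sigma = 0.2, seed = 7)
moved <- extract_bundle(ch, b$map)

ssm_fit(moved, ref)
#> Superposition: rmsd 0.871 A over 166 matched positions

isolated_helix_comparison(list(moved), 3, ref, "ssm")
#>       id receptor_id bundle_frame_dev rigid_disp isolated_rmsd
#> 1 SYN1-A         syn             1.96       1.94         0.327
```

Reading the output: the trimmed SSM fit anchors the frame on the 166
undisplaced positions (the displaced helix III is excluded from the
matched set), so the whole-bundle RMSD of 0.871 Å decomposes into a
helix III that sits ~2 Å away in the bundle frame
(`bundle_frame_dev = 1.96`, `rigid_disp = 1.94` — the injected 2 Å,
recovered) while its internal shape is unchanged
(`isolated_rmsd = 0.33`, the noise floor).  High in-bundle deviation
with a near-zero isolated fit is the rigid-body displacement
signature.

Per-position deviations in the common frame localise the effect:

```r
d <- per_position_deviation(transform_bundle(moved, ssm_fit(moved, ref)), ref)
round(d[c("3.22", "3.35", "3.50", "4.50")], 2)
#> 3.22 3.35 3.50 4.50
#> 2.03 2.22 1.90 0.16
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline on a
synthetic chain census (50 chains, 10 receptors, with the per-receptor
chain counts of the crystallographic census) and write tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate the 50-chain census with known injected structure |
| `02_screen_outliers.R` | flag the 7 regionally deviating chains of one receptor |
| `03_grid_and_profile.R` | 43 kept chains → 903 pairwise RMSDs → 53 receptor-pair averages; deviation profile |
| `04_helix3_rigid_body.R` | recover injected helix III displacements (0.5–4 Å) |
| `05_secstruct_ionic_lock.R` | helix assignment, kink angles, ionic-lock rules |
| `06_real_structures.R` | the same statistics on the real representative PDB entries (network required) |

`run_pipeline()` exposes the same end-to-end flow as one call on any
directory of structures + ledger + maps, with TSV/JSON outputs and a
stage-count log; reruns are byte-identical for a fixed config.

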