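---
title: "Comparing GPCR 7TM bundles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing GPCR 7TM bundles: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmbundle)
```

## The problem

Class A G protein-coupled receptors share a heptahelical transmembrane
(7TM) core whose geometry is remarkably conserved across receptors with
very different ligands.  Comparing that core across crystal structures
requires (i) a common residue coordinate system, (ii) a common spatial
frame, and (iii) statistics that separate conserved from variable
regions.  `tmbundle` implements all three as a tested pipeline:

* a fixed 200-residue bundle defined in Ballesteros–Weinstein (BW)
  coordinates — helix I 1.35–1.59 (25 aa), II 2.38–2.67 (30),
  III 3.22–3.55 (34), IV 4.39–4.63 (25), V 5.36–5.65 (30),
  VI 6.29–6.60 (32), VII 7.32–7.55 (24);
* rigid superposition of bundles onto a common reference by a
  secondary-structure-matching (SSM) fit;
* pairwise RMSD and sequence-identity grids averaged by receptor pair,
  per-position Cα deviation profiles, five membrane-slab sectional
  RMSDs, isolated-helix rigid-body comparison, an ionic-lock census,
  and hydrogen-bond-based helix assignment.

## Residue coordinates: anchors and offsets

All seven helix ranges of the bundle are contiguous in BW space, so a
receptor's mapping from BW positions to author (PDB) residue numbers is
fully determined by the seven h.50 anchor residues:
`author = anchor + (index - 50)`.  Anchor maps are shipped as plain-text
configs (`inst/extdata/maps/`), one per receptor.  For bovine rhodopsin
the internal consistency is easy to verify: with 3.50 = Arg135 the
offset rule puts the retinal counterion Glu113 at 3.28, and with
7.50 = 303 the Schiff-base lysine Lys296 falls at 7.43.

Anchors for the remaining receptors are curated from the standard BW
literature; each map carries a `note =` line saying which anchors were
cross-checked and which should be verified against the structure before
quantitative use.  Two caveats are flagged in the map notes: sequence vs
structure alignment is known to be ambiguous around helix II of CXCR4
and squid rhodopsin and at the extracellular side of helix IV, so a pure
anchor-offset map may be shifted by a residue there.  Insertion codes
inside helices are not representable in an offset map; such chains need
an explicit per-position table.

A chain missing a Cα at any of the 200 mapped positions is rejected
whole (`extract_bundle` lists the missing BW positions).  Partial
bundles are never analysed — this is how short chains drop out of the
census rather than biasing the statistics.

## The SSM superposition

`ssm_fit` is a two-stage rigid fit.  Stage 1 matches the seven helices
as secondary-structure elements: each helix is summarised by its
centroid and its principal-axis end points (axis = first principal
component of the helix Cα set, oriented N→C — robust and
parameter-free), and a Kabsch fit of these 21 anchor points gives the
starting transform.  Stage 2 iterates least-squares refinement on
matched Cα pairs, discarding outlying pairs each round until the
matched set is stable (at most 20 rounds; a period-2 oscillation of the
matched set also counts as converged since the two fits are then
equivalent to numerical precision).

The per-round rejection threshold is
`min(cutoff, max(median(d) + 2 * mad(d), 0.25))` with `cutoff = 3.0`
ångström.  The hard 3.0 Å ceiling is the conventional SSM-style cutoff
and is what takes effect on genuinely different receptor pairs, where
distances are broadly spread.  The robust `median + 2·MAD` term matters
in the near-identical regime: with a fixed 3.0 Å cutoff, a helix
displaced rigidly by ~1–2 Å is *inside* the cutoff, drags the
least-squares fit toward itself round after round, and the injected
displacement is recovered at only ~60–80 % of its magnitude.  The
robust threshold tightens automatically when the bulk of the bundle
agrees closely, so a single displaced helix is excluded from the frame
and its displacement is measured at full size (the package's
parameter-recovery tests inject 0.5–4 Å translations at 0.2 Å
coordinate noise and require recovery within 0.15 Å).  The floor of
0.25 Å prevents the threshold collapsing to zero on identical inputs.
All three constants are arguments of `ssm_fit`.

Reported RMSDs always cover all 200 positions in the converged frame;
`n_matched` records the converged matched count separately.  This makes
grid cells well defined and method-comparable — the alternative
(RMSD over the matched subset only) would conflate fit quality with
coverage.

Deviation profiles are computed, by default, with every bundle fitted
once onto the common reference and distances measured in that shared
frame (`frame = "common_reference"`); fresh per-pair fits are available
via `frame = "pairwise"`.  On synthetic ensembles the profile changes
by well under 0.3 Å per position when the reference is swapped, which
is the package's reference-robustness guarantee.

## Membrane sections

The bundle is cut into five slabs along the membrane normal, five
residues of helix IV per slab (~7.5 Å each).  The default
`section_definition` is constructed geometrically from a reference
bundle: the helix IV principal axis is taken as the membrane normal
(helix IV is nearly perpendicular to the membrane plane and is
canonically α-helical throughout its 25 bundle residues), helix IV is
cut into five consecutive 5-residue blocks, and every other position
joins the section whose helix IV block is nearest along that axis.
Section 1 is the extracellular surface layer (helix IV's C-terminal
block, 4.59–4.63), section 5 the cytoplasmic one (4.39–4.43); the
D/ERY arginine 3.50 therefore lands in section 5.  The construction is
deterministic given the reference; an explicit 200-line table
(`read_section_config`) overrides it.

Sectional RMSDs are computed in the whole-bundle fitted frame with no
per-section refit, so the exact identity
`rmsd_total² = Σ n_s · rmsd_s² / 200` holds and is asserted in the
tests.

## Rigid-body helix displacement

A helix whose internal shape is conserved but whose placement within
the bundle differs shows a characteristic contrast:
`isolated_helix_comparison` reports (a) the mean Cα deviation of the
helix in the whole-bundle common frame (high), (b) the norm of the
vector-mean displacement (`rigid_disp`, a noise-robust estimate of the
rigid shift), and (c) the RMSD after fitting the helix alone onto the
reference helix (near the noise floor).  High (a) with low (c) is the
rigid-body signature; helix regularity can be confirmed independently
with `kink_angle` (window 7, per-position angle between the principal
axes of the flanking windows; "no obvious kink" is operationalised as
max angle < 15°, a documented package default — no numeric criterion
exists in the comparative literature).

## Ionic lock and chain classification

`ionic_lock_state` calls a chain locked iff the residue at 6.30 is Glu
or Asp and the minimum distance from the Arg 3.50 guanidinium nitrogens
(NE, NH1, NH2) to the carboxylate oxygens is ≤ 4.0 Å — the
conventional salt-bridge threshold, configurable.  Chains with a
non-acidic 6.30 are `no_acidic_partner`; unresolved side chains give
`indeterminate`; a non-arginine 3.50 is reported unlocked with a
warning (the motif is conserved but not universal).

Chains are classified `inactivated` (antagonist or inverse-agonist
bound) or `activated` (agonist bound or ligand free) purely from the
ligand annotation in the chain ledger; unknown classes abort rather
than defaulting.

## Secondary structure

The hydrogen-bond machinery follows the Kabsch–Sander electrostatic
model: amide hydrogens (absent from crystal structures) are placed
1.0 Å from N opposing the preceding carbonyl; the bond energy is
`0.084 · 332 · (1/d(ON) + 1/d(CH) − 1/d(OH) − 1/d(CN))` kcal/mol with
bonds called below −0.5 kcal/mol and clashes capped at −9.9.  Two
consecutive i→i+4 turns start a minimal α-helix; i→i+3 and i→i+5
patterns yield 3₁₀ (G) and π (I) labels, single turns T.  Only the
α-helix depth is required by the analyses here (helix regularity);
β-ladder bookkeeping and solvent accessibility are out of scope.  No
hydrogen is reconstructed across a chain break (N–C distance > 2.5 Å)
or for prolines.

## The synthetic generator

`build_bundle` emulates what the analyses need from a receptor chain,
not any receptor's true packing: seven ideal helices with the bundle
lengths, centroids on a 12 Å circle, axes alternating up/down, author
numbering `100·helix + BW index` so every h.50 anchor is `100h + 50`.
Cα-only helices use the canonical parametric curve (rise 1.5 Å/residue,
twist 100°/residue, Cα radius 2.3 Å); full backbones are built by
internal-coordinate chain extension at φ = −57°, ψ = −47° with standard
bond geometry — so hydrogen-bond energies are physically right — and
then rigidly aligned to the requested axis, origin and phase.
`perturb` applies whole-helix rigid translations/rotations plus
seeded i.i.d. Gaussian coordinate noise per atom; `make_ensemble`
writes PDB files, the ledger, the maps and a truth table of injected
displacements.

Study conditions emulated by the workflow scripts (`analysis/`): 50
inactivated chains over 10 receptors with per-receptor counts
(11, 5, 5, 12, 6, 5, 2, 1, 1, 2); 0.1 Å per-atom noise as
within-receptor crystallographic scatter; one receptor-specific helix
offset of 0.8 Å as between-receptor divergence; and 3 Å regional
displacements on seven chains of one receptor (four at the helix I
N-terminus, three at helix VI) reproducing the kind of deviation that
warrants exclusion before grid averaging.  Deviation-profile and
reference-swap checks use 9-chain ensembles (36 pairs).  These sizes
keep every stage exercised at full combinatorial structure (1225 → 903
pairwise values, 53 receptor-pair groups) while the whole suite runs in
well under a minute.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: receptor-specific helix packing, kinks and
bulges, loops, side chains beyond explicitly placed ionic-lock
pseudo-atoms, correlated (B-factor-like) displacement structure, and
alignment ambiguity between sequence and structure.  Conclusions about
real receptors require the real structures (`analysis/06_real_structures.R`,
network needed), with the shipped anchor maps verified against them.

## Numerical choices and degenerate inputs

* Kabsch fit: SVD with determinant correction; < 3 points or collinear
  configurations are errors (rotation underdetermined).
* Altloc resolution: highest occupancy, ties prefer altloc "A", then
  blank — the dominant convention; the comparative analyses are
  insensitive to it at 200-residue scale.
* Only model 1 of multi-model files is used; MSE reads as MET, other
  nonstandard residues become "X".
* Grid averages are arithmetic means of pair RMSDs (not pooled-square
  means); display rounding is 2 decimals for RMSD and deviations,
  1 decimal for identity.
* Sequence identity is computed over the 200 aligned bundle positions
  (the BW positions are the alignment); whether published identity
  percentages are bundle-restricted or full-sequence is ambiguous, and
  this package takes the bundle-restricted reading.
* The outlier screen compares each chain to its receptor's medoid chain
  within a stated BW region (default threshold 2.0 Å mean deviation);
  threshold 0 degenerately flags every non-medoid chain, which is
  documented rather than special-cased.
* Pipeline reruns with the same config and seed are byte-identical.

## Known limitations

Anchor maps for receptors other than bovine rhodopsin and β2 are
best-effort literature curations that could not be re-validated against
structures in this build; the map files say so.  The GPCRDB-style
multiple alignment used historically for bundle definition is replaced
by the anchor-offset construction, which is exact where helices are
regular and may differ by one position where they are not.  Activated
chains are supported end to end (classification, extraction,
superposition onto an inactivated reference) but no mechanistic
interpretation is computed.  Ligand-cavity geometry and molecular
graphics are out of scope.
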