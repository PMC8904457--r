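---
title: "Systematic loop-deletion scanning for trypsin-like serine proteases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systematic loop-deletion scanning for trypsin-like serine proteases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LoopScanR)
```

## The method

Trypsin-like serine proteases carry their functional diversity largely in
surface-exposed loops on a conserved double beta-barrel fold. Loop length
varies in discrete steps across the family, which suggests a scanning
strategy: instead of point mutations, slide deletion windows of increasing
size through a loop and characterise every resulting variant, structurally
(by ensemble loop modelling) and functionally (by enzyme kinetics).
LoopScanR implements this workflow for the 170 loop of coagulation factor
VIIa as the packaged example, and generalises to any loop given a
`LoopDefinition`.

The pipeline has four stages:

1. **Enumerate.** One variant per (window size, start position) inside the
   scan span, canonically ordered by ascending size then N-to-C start and
   indexed from 1. With the FVIIa fixture (scan span 313-321, sequence
   `QSRKVGDSP`, sizes 1-6) this yields the 39-variant library, and the
   canonical index reproduces the variant numbers used throughout the
   functional analysis (e.g. no. 12 = 2-residue deletion at 315, no. 36 =
   6-residue deletion at 313).
2. **Simulate or ingest.** Loop-conformer ensembles come either from
   external modelling output (multi-model PDB plus a `tag`/`reu` score
   table) or from the package's synthetic generator.
3. **Analyze.** Per-variant ensemble statistics: mean structure and RMSF,
   score/RMSD funnels, hydrogen-bond distance classification,
   polar-contact frequencies, slot-residue resolution and the TF-helix
   tilt angle.
4. **Fit and report.** Michaelis-Menten, competitive-inhibition, binding
   and initial-rate fits, assembled into a reference-normalised activity
   table in the heatmap layout (rows sorted by remaining loop length and
   deletion position).

## Dual numbering

Serine-protease positions are conventionally compared in chymotrypsin
template numbering with insertion letters; full-length numbering is what a
construct carries. `NumberingMap` is a strict bijection between the two,
so every analysis can be addressed in either scheme:

```{r}
m <- fviiaNumberingMap()
toChymotrypsin(m, c(313, 315, 321, 372))
```

## Variant enumeration choices

* **Window sizes default to 1-6.** The packaged scan span has 9 eligible
  positions, so sizes 1-6 give $\sum_{k=1}^{6}(9-k+1) = 39$ windows, the
  library size that matches the canonical variant numbering (no. 12, 24,
  35, 36 all land on their quoted windows under size-then-start
  ordering). Larger windows are one argument away
  (`enumerateDeletions(ld, 1:7)` gives 42).
* **Loop span 308-321.** Loop-length accounting uses a 14-residue loop
  ending at P321, so a size-$k$ deletion leaves $14-k$ residues; variant
  no. 36 (size 6) has remaining length 8.
* **Deduplication is off by default.** Deletion scanning of
  repeat-containing sequences can produce identical proteins from
  different windows, and the fixture genuinely contains one such pair:
  the size-6 windows at 314 (deleting `SRKVGD`) and 315 (deleting
  `RKVGDS`) both leave loop `QSP`. The enumerated library keeps both
  windows — they are distinct DNA-level constructs and both carry their
  canonical numbers — while `dedupeIdentical()` collapses them (39 to 38)
  for workflows that care about unique protein sequences.

## Ensemble statistics

Ensembles are N poses sharing one atom table; coordinates sit in a fixed
template frame because loops are rebuilt on a rigid protease body, so
**no re-superposition** is applied before RMSF or RMSD
(`superposePoses()` exists for foreign ensembles). Choices that matter:

* The "mean structure" is the per-atom arithmetic mean of coordinates; a
  true geometric median is out of scope.
* RMSF is $\sqrt{\langle |x - \bar x|^2\rangle}$ per atom, averaged over
  the selection (default: heavy atoms of the rebuilt span).
* The funnel reference is the lowest-scoring pose, ties broken by lowest
  pose index; its RMSD row is exactly zero. Whether funnel RMSD should be
  all-atom or heavy-atom is not fixed by convention; the package uses
  heavy atoms over the rebuilt span (hydrogens are dropped at read time
  throughout, since all distance criteria are heavy-atom).
* Hydrogen bonds are classified by heavy-atom donor-acceptor distance
  only — no angle term. The stability flag keys on the *mean* of the
  per-pose distance lying in the 2.5-3.8 Å window; the population SD is
  reported but not thresholded. Histograms use fixed 0.1 Å bins over
  2.5-4.0 Å.
* Polar-contact frequency uses a strict `< 3.5` Å cutoff, so a distance
  of exactly 3.5 Å is not a contact.
* **Slot resolution.** After a deletion, residues C-terminal of the
  window shift N-ward, so "residue 315 or the residue in its place" needs
  a rule. The package counts the slot as an ordinal from the N-terminal
  loop anchor: the residue at that ordinal in the truncated loop occupies
  the slot (deleting 315-316 puts 317 in the 315 slot; the 6-residue
  deletion at 313 puts D319 into the 313 slot, where it can reach the
  protease body). If the truncated loop is shorter than the ordinal the
  C-terminal anchor is returned with a warning. This ordinal rule is the
  simplest deterministic reading; a nearest-atom-to-template resolver
  was considered and rejected because it depends on the modelled
  coordinates rather than on the construct.
* **RMSD groupings** for representative selection use equal-width bins
  over the RMSD-to-reference axis (the simplest reading of "RMSD
  groupings"), with the lowest-scoring poses per bin returned and empty
  bins reported rather than topped up.
* **Helix tilt angle** is the angle between the first principal component
  of the helix C-alpha set (oriented N to C) and the vector between two
  reference centroids (loop bottom to helix outer side). The reference
  selections are configuration (`fviiaHelixBaseSelection()`), shipped as
  nominal defaults: proper calibration requires the reference crystal
  structures (FVIIa:sTF and the trypsin-loop variant), which must be
  supplied locally; the machinery itself is verified against constructed
  geometries with exactly known angles.

## The synthetic generator

The generator exists so that every stage is testable without external
modelling output. It emulates the *statistical shape* of loop-modelling
ensembles, not their physics:

* An **ideal-geometry backbone** (N, CA, C, O per residue; bond lengths
  1.458 / 1.525 / 1.329 / 1.231 Å, standard angles, planar peptide
  bonds) is grown from the N-side anchor frame. Poses are backbone-only:
  every distance statistic in scope is a backbone N···O distance, so side
  chains would be decoration.
* **Cyclic coordinate descent** (CCD) closes the chain onto the fixed
  C-side anchor: sweeping the phi/psi bonds, each bond receives the
  closed-form rotation minimising the anchor deviation. Rotations are
  rigid, so internal geometry is preserved exactly (the tests check bond
  lengths to 1e-9 Å). CCD is deliberately *not* a reimplementation of
  kinematic-closure protocols — it is a simple, well-defined sampler that
  produces valid closed ensembles with known ground truth.
* Each pose is a Gaussian torsion perturbation (default SD 20 degrees per
  torsion, chosen so that the 250-pose default produces RMSF and RMSD
  spreads of a few Å, the scale seen in flexible-loop ensembles) of the
  closed native, re-closed to 0.1 Å.
* **Pseudo-energies** follow `score = offset + slope * RMSD_to_native +
  N(0, sigma)`, defaults slope 1 REU/Å, sigma 0.2 REU, offset -300 REU,
  which guarantees funnel-shaped score/RMSD plots with Spearman
  correlation above 0.9 at N = 250.
* **Planted contacts** draw a Bernoulli(f) subset of poses and move the
  body-side atom along the pair axis to < 3.4 Å (others to > 4.5 Å),
  recording the realised draw so frequency estimators can be checked
  exactly.
* The scaffold carries a helical N-side anchor segment (306-310), the
  C-side anchor (322) and the fixed body stretch Q366/G372/H373/F374 so
  that contact and helix-angle statistics have real targets.

What the generator does **not** emulate: sterics (poses can clash),
side-chain packing, Ramachandran statistics, solvent, or any physical
energy function. Passing tests therefore demonstrate the correctness of
the *statistics and estimators*, not the realism of any particular
modelled ensemble.

Kinetic data follow the four assay models (substrate titration 0-12.5 mM
in two-fold steps, competitive inhibition at fixed 1 mM substrate,
co-factor titration 0-3 uM, linear progress curves read over the first 5
minutes) with multiplicative Gaussian noise (default 2%, the scale of
plate-reader duplicates). Default true parameters (KM 7.2 mM, kcat 0.3
s^-1, Ki 2 mM, Kd 0.09 uM) are magnitudes representative of published
free-FVIIa measurements.

## Kinetics fitting choices

Fits are unweighted nonlinear least squares with positivity enforced by
log-parameterising the constants, Levenberg-Marquardt steps, and starting
values from linearisations (Hanes-Woolf for Michaelis-Menten). Standard
errors for log-parameterised constants are delta-method transforms.
Replicates are averaged before fitting (measurements are typically
reported as means of duplicates); per-replicate fitting is a caller-side
loop. The binding model defaults to the hyperbola, valid when titrant
concentrations far exceed enzyme (uM vs nM-pM); a tight-binding quadratic
variant is available via `tightBinding = TRUE`.

Percentage columns follow the heatmap conventions: catalytic efficiency
as `100 * (kcat/KM) / (kcat/KM)_ref`, and inhibition as "percentage Ki of
the reference" (`100 * Ki / Ki_ref`, so tighter-binding variants read
below 100%). Because the direction of that ratio is ambiguous in prose,
both directions are emitted (`pct_Ki`, `pct_Ki_inv`); the default
documented direction is variant-over-reference. Percentages are invariant
to rescaling all rates by a common factor.

## Determinism and numerical conventions

* Every generator takes a single seed; the pipeline derives per-variant
  seeds from the master seed, records the seed in the manifest, and
  reruns reproduce every output file byte for byte (md5 checksums in the
  manifest).
* Intervals are inclusive on both ends, all coordinates 1-based
  full-length numbering; deletion variants keep original numbering with
  gaps so cross-variant atom addressing stays in one frame.
* Score tables are whitespace-delimited text with header columns `tag`
  and `reu`, joined strictly on tag; a missing tag is an error, a missing
  table leaves scores at zero with a warning.
* The multi-model PDB reader validates atom correspondence across models
  before parsing and names the first offending atom; altloc records other
  than blank/"A" are dropped with a count.

## Problem sizes used by the tests

The unit tests run the generator at 5-60 poses and the pipeline at 9
variants x 6-8 poses, sizes chosen to exercise every code path in
seconds. The acceptance-level checks use the full study conditions: 250
poses for funnel and contact statistics, 100 seeded closure attempts, 200
planted-contact replicates, 500 kinetic-recovery replicates, and one
complete 39-variant x 250-pose pipeline run (which finishes in well under
a minute per run on one core).

## Known limitations

* The synthetic sampler has no sterics; planted contact distances, not
  excluded volume, are the ground truth for contact statistics.
* Helix-angle reference selections ship uncalibrated against real crystal
  structures (see above); angles on synthetic scaffolds are internally
  consistent but not comparable to published absolute values.
* REU is consumed, never computed: the package scores nothing.
* Replicate-level error models (weighting, outlier handling) are out of
  scope; fits are unweighted.
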