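# LoopScanR

Systematic loop-deletion scanning and conformer-ensemble statistics for
trypsin-like serine proteases, packaged around the 170 loop of
coagulation factor VIIa.

## What problem this solves

Surface-exposed loops carry much of the functional specificity of
trypsin-like serine proteases, and loop *length* varies in discrete steps
across the family. Deletion scanning probes this directly: slide deletion
windows of size 1..k through a loop, build every variant, and
characterise each one structurally (ensembles of rebuilt loop
conformations) and functionally (enzyme kinetics). This package gives a
protein engineer or structural bioinformatician the full desk-side
workflow:

* **Variant enumeration** under dual numbering (full-length and
  chymotrypsin template labels with insertion codes, e.g. 313 = 170A),
  with the deterministic size-then-start indexing used to refer to
  variants by number. The FVIIa fixture (scan span 313–321, sequence
  `QSRKVGDSP`, window sizes 1–6) yields the canonical 39-variant library.
* **Ensemble I/O**: multi-model PDB reading/writing with strict
  atom-correspondence validation and per-pose score tables
  (`tag`/`reu`).
* **Ensemble statistics**: mean structure, RMSF (around the per-atom
  mean, no re-superposition: poses share the rigid template frame),
  score/RMSD funnels (reference = lowest-scoring pose), lowest-energy
  and RMSD-group representative selection, hydrogen-bond distance
  classification (stable if the mean lies in 2.5–3.8 Å), polar-contact
  frequencies (strict < 3.5 Å), deletion "slot" residue resolution, and
  TF-helix tilt angles.
* **Kinetics**: Michaelis–Menten (K_M, k_cat), competitive inhibition
  (K_i at fixed substrate), hyperbolic co-factor binding (K_d),
  initial-rate fitting over a 5-minute linear window, and
  reference-normalised percentage tables (`100·(k_cat/K_M)/(k_cat/K_M)_WT`
  etc.) in the heatmap layout.
* **Synthetic data with known ground truth**: closed loop ensembles
  (ideal-geometry backbone + cyclic-coordinate-descent closure,
  pseudo-energies `score = offset + slope·RMSD_to_native + ε`), planted
  contact fractions, and noisy kinetic datasets — so every stage is
  testable without any external modelling software or downloads.

## Worked example

```r
library(LoopScanR)

lib <- enumerateDeletions(fviiaLoopDefinition())
lib
#> VariantLibrary: 39 deletion variants, window sizes {1,2,3,4,5,6}, scan 313-321
variantIndex(lib, start = 313, size = 6)     # the 6-residue deletion at 170A
#> [1] 36

# synthetic 250-pose ensemble for variant no. 36 (residues keep full-length
# numbering with gaps; anchors and protease-body stretch are fixed)
ens <- sampleLoopEnsemble(fviiaLoopGeometry(start = 313, size = 6),
                          syntheticEnsembleSpec(nPoses = 250), seed = 17)
ens
#> ConformerEnsemble: 250 pose(s), 60 atoms, residues 306-374
#>   rebuilt span: 311-321
#>   scores (REU): -300.32 .. -297.03

# which residue now sits in the 313{170A} slot? (the deletion shifts D319 in)
slot <- resolveSlotResidue(fviiaLoopDefinition(), 313, start = 313, size = 6)
slot
#> [1] 319

# plant a known contact fraction and recover it exactly
ensP <- plantContactFraction(ens, atomSpec(slot, "N"), atomSpec(374, "N"),
                             f = 0.72, seed = 17)
d <- atomDistanceSeries(ensP, atomSpec(slot, "N"), atomSpec(374, "N"))
contactFrequency(d)                           # fraction of poses < 3.5 A
#> [1] 0.736
ensP@metadata$plantedContact$realizedFraction # the recorded Bernoulli draw
#> [1] 0.736

# funnel statistics on the wild-type-length ensemble
ensWT <- sampleLoopEnsemble(fviiaLoopGeometry(),
                            syntheticEnsembleSpec(nPoses = 250), seed = 17)
fun <- funnelTable(ensWT)
cor(fun$score, fun$rmsd, method = "spearman")
#> [1] 0.961

# kinetics: generate a noisy substrate titration and refit it
k <- genKinetics(syntheticKineticsSpec(noiseSigma = 0.02), seed = 17)
m <- averageReplicates(k$mm)
fitMichaelisMenten(m$conc, m$rate, enzymeConc = 10)
#> Michaelis-Menten fit: KM = 7.314 mM (SE 0.15), Vmax = 3.075, kcat = 0.3075 /s
```

The contact frequency equals the recorded draw exactly (the estimator is
checked for unbiasedness over replicates in the tests); the refitted K_M
lands within ~2% of the generating 7.2 mM at 2% noise.

The whole pipeline (enumerate → simulate → analyze → fit → report) runs
as one call and writes a deterministic, checksummed report bundle:

```r
res <- runPipeline(pipelineConfig(nPoses = 250, seed = 1), "out/")
```

A thin command-line wrapper is installed at
`inst/scripts/loopscan.R` (`enumerate`, `simulate`, `validate-ensemble`,
`fit-kinetics`, `run`).

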