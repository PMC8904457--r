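test_that("ideal backbone construction has exact internal geometry", {
  g <- idealGeometry()
  # 1-residue chain: 4 atoms, ideal N-CA bond
  bb1 <- buildIdealBackbone("A")
  expect_equal(nrow(bb1$xyz), 4L)
  expect_equal(sqrt(sum((bb1$xyz[1, ] - bb1$xyz[2, ])^2)), g$bNCA,
               tolerance = 1e-9)
  # 11-residue chain (rebuilt-span length): 44 backbone atoms
  bb <- buildIdealBackbone("LQQSRKVGDSP", resnos = 311:321)
  expect_equal(nrow(bb$xyz), 44L)
  expect_equal(unique(bb$atoms$resno), 311:321)
  # every constructed bond matches its spec value to 1e-6
  bl <- backboneBondLengths(bb$xyz, 11)
  want <- rep(c(g$bNCA, g$bCAC, g$bCO, g$bCN), 11)[seq_along(bl)]
  expect_equal(bl, want, tolerance = 1e-6)
  expect_error(buildIdealBackbone(""), "empty")
})

test_that("CCD closure converges and is a pure torsion move", {
  set.seed(50)
  loop <- fviiaLoopGeometry()
  scaffold <- LoopScanR:::.buildScaffold(loop)
  ext <- buildIdealBackbone(loop$sequence, loop$resnos,
                            startFrame = scaffold$frame)
  virt <- buildIdealBackbone("N", 322, startFrame = ext$xyz[41:43, ])
  xyz0 <- rbind(ext$xyz, virt$xyz[1:3, ])
  tIdx <- 45:47

  # target equal to the current anchor: converges with zero sweeps
  res0 <- ccdClose(xyz0, ext$bonds, tIdx, xyz0[tIdx, ], tol = 0.1)
  expect_true(res0$converged)
  expect_equal(res0$iterations, 0L)

  # 100 seeded random perturbations (the generator's default 20-degree
  # spread) of a closed loop re-close at 0.1 A
  nat <- ccdClose(xyz0, ext$bonds, tIdx, scaffold$target, maxIter = 2000,
                  tol = 0.05)
  expect_true(nat$converged)
  ok <- 0L
  for (i in 1:100) {
    delta <- rnorm(nrow(ext$bonds), 0, 20)
    X <- applyTorsions(nat$xyz, ext$bonds, delta)
    cl <- ccdClose(X, ext$bonds, tIdx, scaffold$target, tol = 0.1)
    if (cl$converged) {
      ok <- ok + 1L
      # bond geometry untouched to 1e-9 (rigid rotations only)
      expect_equal(backboneBondLengths(cl$xyz[1:44, ], 11),
                   backboneBondLengths(xyz0[1:44, ], 11), tolerance = 1e-9)
    }
  }
  expect_gte(ok, 95L)
})

test_that("sampled ensembles honour their spec and validate structurally", {
  ens <- smallEnsemble(nPoses = 40, seed = 60)
  expect_s4_class(ens, "ConformerEnsemble")
  expect_true(validObject(ens))
  expect_equal(nPoses(ens), 40L)
  # all closure anchors were hit
  expect_lt(ens@metadata$truth$closureFailRate, 0.5)
  # zero perturbation: every pose is the native, all RMSD zero
  ens0 <- smallEnsemble(nPoses = 5, seed = 61, sigmaTorsion = 0)
  expect_equal(max(ens0@metadata$truth$rmsdToNative), 0, tolerance = 1e-9)
  expect_equal(max(apply(ens0@xyz, 2, function(x) diff(range(x)))), 0,
               tolerance = 1e-9)
  # deletion variants carry gapped numbering and shorter loops
  ensV <- smallEnsemble(nPoses = 5, seed = 62, start = 313, size = 6)
  expect_false(any(313:318 %in% atomTable(ensV)$resno))
  expect_true(all(c(306:312, 319:322, 366, 372, 373, 374) %in%
                    atomTable(ensV)$resno))
})

test_that("ensemble generation is byte-identical under a fixed seed", {
  e1 <- smallEnsemble(nPoses = 12, seed = 70)
  e2 <- smallEnsemble(nPoses = 12, seed = 70)
  e3 <- smallEnsemble(nPoses = 12, seed = 71)
  expect_identical(e1@xyz, e2@xyz)
  expect_identical(e1@scores, e2@scores)
  expect_false(identical(e1@xyz, e3@xyz))
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeMultiModelPDB(e1, f1); writeMultiModelPDB(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pseudo-energies follow the planted linear RMSD model", {
  ens <- sampleLoopEnsemble(fviiaLoopGeometry(),
                            syntheticEnsembleSpec(nPoses = 150,
                                                  energySlope = 2,
                                                  energySigma = 1e-9,
                                                  energyOffset = -50),
                            seed = 80)
  tr <- ens@metadata$truth
  expect_equal(poseScores(ens), -50 + 2 * tr$rmsdToNative, tolerance = 1e-6)
  # the planted minimum-RMSD pose is found first by low-energy selection
  expect_equal(selectLowEnergy(ens, 1), which.min(tr$rmsdToNative))
})

test_that("planted contact fractions are exact at the extremes", {
  ens <- smallEnsemble(nPoses = 30, seed = 81)
  a <- atomSpec(315, "N"); b <- atomSpec(372, "O")
  e1 <- plantContactFraction(ens, a, b, f = 1, seed = 1)
  expect_equal(contactFrequency(atomDistanceSeries(e1, a, b)), 1)
  expect_true(all(atomDistanceSeries(e1, a, b) < 3.4))
  e0 <- plantContactFraction(ens, a, b, f = 0, seed = 1)
  expect_equal(contactFrequency(atomDistanceSeries(e0, a, b)), 0)
  expect_true(all(atomDistanceSeries(e0, a, b) > 4.5))
  # only the targeted atom moves
  moved <- which(colSums(abs(e1@xyz - ens@xyz)) > 0)
  ib <- which(atomTable(ens)$resno == 372 & atomTable(ens)$elety == "O")
  expect_true(all(moved %in% (3 * ib - 2):(3 * ib)))
})

test_that("closure failure reporting triggers on infeasible settings", {
  # anchors too far for a 2-residue loop: the native build itself fails
  tiny <- loopGeometrySpec("GA", resnos = 1:2, anchorSep = 30)
  expect_error(sampleLoopEnsemble(tiny, syntheticEnsembleSpec(nPoses = 2)),
               "closed native loop")
})
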