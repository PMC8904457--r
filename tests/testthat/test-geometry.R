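# Ensemble statistics against independent brute-force oracles.

test_that("mean structure equals the per-atom brute-force average", {
  set.seed(9)
  nat <- 8; np <- 50
  poses <- lapply(seq_len(np), function(i) matrix(rnorm(nat * 3), nat))
  ens <- toyEnsemble(poses, atoms = toyAtoms(1:2))
  m <- geometricMeanStructure(ens, selection = seq_len(nat))
  # oracle: explicit loop over atoms and poses
  oracle <- matrix(0, nat, 3)
  for (a in seq_len(nat)) for (d in 1:3)
    oracle[a, d] <- mean(vapply(poses, function(p) p[a, d], numeric(1)))
  expect_equal(unclass(m), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  # idempotence: identical poses give back the pose
  ens2 <- toyEnsemble(rep(poses[1], 4), atoms = toyAtoms(1:2))
  expect_equal(unclass(geometricMeanStructure(ens2, seq_len(nat))),
               poses[[1]], ignore_attr = TRUE)
  # two poses: coordinate midpoint
  ens3 <- toyEnsemble(poses[1:2], atoms = toyAtoms(1:2))
  expect_equal(unclass(geometricMeanStructure(ens3, seq_len(nat))),
               (poses[[1]] + poses[[2]]) / 2, ignore_attr = TRUE)
})

test_that("RMSF matches brute-force recomputation and closed forms", {
  set.seed(10)
  nat <- 8; np <- 40
  poses <- lapply(seq_len(np), function(i) matrix(rnorm(nat * 3), nat))
  ens <- toyEnsemble(poses, atoms = toyAtoms(1:2))
  prof <- rmsfProfile(ens, selection = seq_len(nat))
  # oracle: per atom, sqrt(mean squared deviation from the mean position)
  oracle <- vapply(seq_len(nat), function(a) {
    X <- t(vapply(poses, function(p) p[a, ], numeric(3)))
    mu <- colMeans(X)
    sqrt(mean(rowSums(sweep(X, 2, mu)^2)))
  }, numeric(1))
  expect_equal(prof$rmsf, oracle, tolerance = 1e-9)
  expect_equal(attr(prof, "average"), mean(oracle), tolerance = 1e-9)

  # identical poses: all zero
  ensI <- toyEnsemble(rep(poses[1], 3), atoms = toyAtoms(1:2))
  expect_true(all(rmsfProfile(ensI, seq_len(nat))$rmsf == 0))

  # two poses, one atom displaced by d: that atom's RMSF is d/2
  p1 <- matrix(0, 4, 3); p2 <- p1; p2[2, 1] <- 3
  ens2 <- toyEnsemble(list(p1, p2), atoms = toyAtoms(1, c("N", "CA", "C", "O")))
  expect_equal(rmsfProfile(ens2, 1:4)$rmsf, c(0, 1.5, 0, 0))

  # isotropic Gaussian spread sigma per axis: average RMSF ~ sigma * sqrt(3)
  sigma <- 0.8
  posesG <- lapply(1:250, function(i) matrix(rnorm(4 * 3, 0, sigma), 4))
  ensG <- toyEnsemble(posesG, atoms = toyAtoms(1, c("N", "CA", "C", "O")))
  expect_equal(attr(rmsfProfile(ensG, 1:4), "average"), sigma * sqrt(3),
               tolerance = 0.05)
})

test_that("pairwise pose RMSD matches its closed form and brute force", {
  M <- 16
  p1 <- matrix(rnorm(M * 3), M); p2 <- p1; p2[5, ] <- p2[5, ] + c(3, 0, 0)
  ens <- toyEnsemble(list(p1, p2, matrix(rnorm(M * 3), M)),
                     atoms = toyAtoms(1:4))
  expect_equal(poseRMSD(ens, 1, 1, seq_len(M)), 0)
  expect_equal(poseRMSD(ens, 1, 2, seq_len(M)), 3 / sqrt(M))
  # brute force on a random pair
  p3 <- matrix(ens@xyz[3, ], ncol = 3, byrow = TRUE)
  expect_equal(poseRMSD(ens, 1, 3, seq_len(M)),
               sqrt(sum((p1 - p3)^2) / M), tolerance = 1e-12)
})

test_that("funnel reference is the lowest-scoring pose with zero RMSD", {
  ens <- smallEnsemble(nPoses = 30)
  fun <- funnelTable(ens)
  ref <- attr(fun, "reference")
  expect_equal(ref, which.min(poseScores(ens)))
  expect_equal(fun$rmsd[ref], 0)
  expect_true(all(fun$rmsd >= 0))
  expect_equal(nrow(fun), 30L)
  # all-equal scores: valid, reference pose 1, message
  ensE <- initialize(ens, scores = rep(1, 30))
  expect_message(funE <- funnelTable(ensE), "pose 1")
  expect_equal(attr(funE, "reference"), 1L)
})

test_that("planted-energy ensembles show a strong score/RMSD funnel", {
  # generator ground truth: score = offset + 1 * RMSD_to_native + N(0, 0.2)
  ens <- sampleLoopEnsemble(fviiaLoopGeometry(),
                            syntheticEnsembleSpec(nPoses = 250,
                                                  energySlope = 1,
                                                  energySigma = 0.2),
                            seed = 101)
  fun <- funnelTable(ens)
  expect_gte(cor(fun$score, fun$rmsd, method = "spearman"), 0.9)
})

test_that("low-energy selection is stable and complete", {
  set.seed(3)
  scores <- rnorm(250)
  scores[77] <- -10          # planted minimum
  poses <- lapply(1:250, function(i) matrix(rnorm(12), 4))
  ens <- toyEnsemble(poses, atoms = toyAtoms(1, c("N", "CA", "C", "O")),
                     scores = scores)
  ids <- selectLowEnergy(ens, 10)
  expect_length(ids, 10L)
  expect_equal(ids[1], 77L)
  expect_equal(sort(selectLowEnergy(ens, 250)), 1:250)
  expect_error(selectLowEnergy(ens, 251), "exceeds")
  # ties break by pose index
  ensT <- initialize(ens, scores = rep(0, 250))
  expect_equal(selectLowEnergy(ensT, 3), 1:3)
})

test_that("RMSD-group representatives find one cluster per planted mode", {
  # trimodal RMSD structure: reference at 0, clusters near 2, 6 and 10 A
  set.seed(4)
  base <- matrix(0, 4, 3)
  shift <- function(d) base + cbind(rep(d, 4), 0, 0)
  poses <- c(list(base),
             lapply(1:20, function(i) shift(2 + runif(1, -0.2, 0.2))),
             lapply(1:20, function(i) shift(6 + runif(1, -0.2, 0.2))),
             lapply(1:20, function(i) shift(10 + runif(1, -0.2, 0.2))))
  scores <- c(-5, rnorm(60))
  ens <- toyEnsemble(poses, atoms = toyAtoms(1, c("N", "CA", "C", "O")),
                     scores = scores)
  rep3 <- rmsdGroupRepresentatives(ens, nGroups = 3, perGroup = 5,
                                   selection = 1:4)
  expect_length(unlist(rep3$groups), 15L)
  fun <- rep3$funnel
  modes <- vapply(rep3$groups, function(g) mean(fun$rmsd[g]), numeric(1))
  expect_true(all(abs(modes - c(2, 6, 10)) < 1))
  # 1 group x N returns everything
  repAll <- rmsdGroupRepresentatives(ens, 1, 61, selection = 1:4)
  expect_equal(sort(repAll$groups[[1]]), 1:61)
  # degenerate (all identical) collapses to one group with a warning
  ensI <- toyEnsemble(rep(list(base), 10),
                      atoms = toyAtoms(1, c("N", "CA", "C", "O")))
  expect_warning(rmsdGroupRepresentatives(ensI, 3, 2, selection = 1:4),
                 "degenerate")
})

test_that("distance series and planted contacts agree with ground truth", {
  # two fixed atoms 4 A apart
  p <- matrix(c(0, 0, 0, 0, 0, 4), 2, byrow = TRUE)
  ens <- toyEnsemble(rep(list(p), 3), atoms = toyAtoms(1:2, "CA")[1:2, ])
  s <- atomDistanceSeries(ens, atomSpec(1, "CA"), atomSpec(2, "CA"))
  expect_equal(unname(as.vector(s)), rep(4, 3))
  expect_error(atomDistanceSeries(ens, atomSpec(1, "CA"), atomSpec(9, "CA")),
               "residue 9")
  # synthetic planted-contact ensemble matches the recorded draw exactly
  ensL <- smallEnsemble(nPoses = 60, seed = 8)
  ensP <- plantContactFraction(ensL, atomSpec(315, "N"), atomSpec(372, "O"),
                               f = 0.4, seed = 21)
  truth <- ensP@metadata$plantedContact
  sp <- atomDistanceSeries(ensP, atomSpec(315, "N"), atomSpec(372, "O"))
  expect_equal(contactFrequency(sp), truth$realizedFraction)
  expect_identical(unname(sp < 3.5), truth$isContact)
})

test_that("hydrogen-bond classification follows the distance windows", {
  hb <- hbondSummary(rep(3.0, 100))
  expect_equal(hb$mean, 3.0)
  expect_equal(hb$sd, 0)
  expect_true(hb$stable)
  expect_equal(hb$inRangeFrequency, 1)

  hb5 <- hbondSummary(rep(5.0, 100))
  expect_false(hb5$stable)
  expect_equal(hb5$inRangeFrequency, 0)

  # mean of 3.9 is outside the 2.5-3.8 stability window but inside the
  # 2.5-4.0 histogram range
  hb39 <- hbondSummary(rep(3.9, 50))
  expect_false(hb39$stable)
  expect_equal(hb39$inRangeFrequency, 1)

  # mean/SD consistent with an independent recomputation
  set.seed(5)
  x <- runif(200, 2, 6)
  hbx <- hbondSummary(x)
  expect_equal(hbx$mean, mean(x))
  expect_equal(hbx$sd, sqrt(mean((x - mean(x))^2)))
  expect_equal(hbx$inRangeFrequency, mean(x >= 2.5 & x <= 4.0))
  expect_equal(sum(hbx$histogram$count), sum(x >= 2.5 & x <= 4.0))
})

test_that("contact frequency uses a strict cutoff", {
  expect_equal(contactFrequency(rep(3.0, 10)), 1)
  expect_equal(contactFrequency(rep(3.5, 10)), 0)   # boundary convention
  expect_equal(contactFrequency(c(3.0, 4.0)), 0.5)
  expect_error(contactFrequency(numeric(0)), "empty")
})

test_that("contact estimator is unbiased over many planted replicates", {
  ensL <- smallEnsemble(nPoses = 250, seed = 12)
  f <- 0.4
  est <- vapply(1:200, function(r) {
    e <- plantContactFraction(ensL, atomSpec(315, "N"), atomSpec(372, "O"),
                              f = f, seed = 1000 + r)
    contactFrequency(atomDistanceSeries(e, atomSpec(315, "N"),
                                        atomSpec(372, "O")))
  }, numeric(1))
  expect_lt(abs(mean(est) - f), 0.01)
})

test_that("slot-residue resolution follows the N-anchor ordinal rule", {
  ld <- fviiaLoopDefinition()
  # identity with no deletion
  expect_equal(resolveSlotResidue(ld, 315), 315L)
  # deletion of 315-316: residue 317 shifts into the 315 slot
  expect_equal(resolveSlotResidue(ld, 315, start = 315, size = 2), 317L)
  # variant 36 (deletes 313-318): D319 moves into the 313 slot
  expect_equal(resolveSlotResidue(ld, 313, start = 313, size = 6), 319L)
  # window entirely C-terminal of the slot: identity (property over cases)
  for (slot in 308:314) for (start in 315:319)
    expect_equal(resolveSlotResidue(ld, slot, start = start, size = 2),
                 as.integer(slot))
  # brute-force oracle: renumber the truncated loop explicitly
  bruteSlot <- function(slot, start, size) {
    loop <- 308:321
    rem <- setdiff(loop, start:(start + size - 1))
    ord <- slot - 308 + 1
    if (ord > length(rem)) 322L else rem[ord]
  }
  set.seed(6)
  for (i in 1:25) {
    size <- sample(1:6, 1)
    start <- sample(313:(321 - size + 1), 1)
    slot <- sample(308:321, 1)
    expect_equal(
      suppressWarnings(resolveSlotResidue(ld, slot, start, size)),
      bruteSlot(slot, start, size))
  }
  # truncation shorter than the ordinal falls back to the C anchor
  expect_warning(r <- resolveSlotResidue(ld, 321, start = 313, size = 6),
                 "C-terminal anchor")
  expect_equal(r, 322L)
  expect_error(resolveSlotResidue(ld, 300), "outside the loop span")
})

test_that("helix tilt angle recovers constructed geometries exactly", {
  # helix CA atoms along +z, base selections giving parallel/orthogonal vectors
  mkens <- function(baseFrom, baseTo) {
    atoms <- data.frame(eleno = 1:7, elety = "CA", resid = "ALA",
                        chain = "A", resno = c(1:5, 10L, 11L))
    xyz <- rbind(cbind(0.005 * sin(1:5), 0.005 * cos(1:5), 1:5),
                 baseFrom, baseTo)
    ConformerEnsemble(atoms, matrix(as.vector(t(xyz)), 1))
  }
  hel <- list(resno = c(1L, 5L), elety = "CA")
  base <- list(from = list(resno = 10L, elety = "CA"),
               to = list(resno = 11L, elety = "CA"))
  # base vector along +z: parallel, 0 degrees
  e0 <- mkens(c(0, 0, 0), c(0, 0, 7))
  expect_equal(helixAngle(e0, 1, hel, base)$angle, 0, tolerance = 0.5)
  # base vector along +x: orthogonal, 90 degrees
  e90 <- mkens(c(0, 0, 0), c(7, 0, 0))
  expect_equal(helixAngle(e90, 1, hel, base)$angle, 90, tolerance = 0.5)
  # anti-parallel: 180 degrees (axis is N->C oriented)
  e180 <- mkens(c(0, 0, 7), c(0, 0, 0))
  expect_equal(helixAngle(e180, 1, hel, base)$angle, 180, tolerance = 0.5)
  # 45-degree construction
  e45 <- mkens(c(0, 0, 0), c(5, 0, 5))
  expect_equal(helixAngle(e45, 1, hel, base)$angle, 45, tolerance = 0.5)
  # degenerate selections error
  expect_error(helixAngle(e0, 1, list(resno = c(10L, 11L), elety = "CA"),
                          base), ">= 3")
})

test_that("summaries are invariant to pose order apart from ids", {
  ens <- smallEnsemble(nPoses = 20, seed = 14)
  perm <- sample(20)
  ensP <- initialize(ens, xyz = ens@xyz[perm, , drop = FALSE],
                     scores = ens@scores[perm],
                     tags = ens@tags[perm])
  expect_equal(attr(rmsfProfile(ensP), "average"),
               attr(rmsfProfile(ens), "average"), tolerance = 1e-12)
  expect_equal(unclass(geometricMeanStructure(ensP)),
               unclass(geometricMeanStructure(ens)),
               ignore_attr = TRUE, tolerance = 1e-12)
  f1 <- funnelTable(ens); f2 <- funnelTable(ensP)
  expect_equal(sort(f1$rmsd), sort(f2$rmsd), tolerance = 1e-12)
  s1 <- atomDistanceSeries(ens, atomSpec(315, "N"), atomSpec(372, "O"))
  s2 <- atomDistanceSeries(ensP, atomSpec(315, "N"), atomSpec(372, "O"))
  expect_equal(contactFrequency(s1), contactFrequency(s2))
})
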