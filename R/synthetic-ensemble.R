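## Synthetic closed-loop ensemble generator: an ideal-geometry backbone
## builder (NeRF internal-to-Cartesian), cyclic-coordinate-descent loop
## closure onto fixed anchors, and pseudo-energies correlated with
## distance-to-native. This is a well-defined desk-scale sampler for
## producing valid closed ensembles with known ground truth; it is not a
## reimplementation of any fragment- or kinematic-closure protocol.

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

#' Ideal backbone geometry constants
#'
#' Standard internal-coordinate values (bond lengths in Angstrom, angles in
#' degrees) used by the backbone builder: N-CA 1.458, CA-C 1.525, C-N
#' 1.329, C=O 1.231, with standard backbone bond angles.
#'
#' @return Named list of geometry constants.
#' @export
idealGeometry <- function() {
  list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
       aNCAC = 111.2, aCACN = 116.2, aCNCA = 121.7, aCACO = 120.8)
}

.cross <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

.unit <- function(v) v / sqrt(sum(v^2))

## NeRF atom placement: D bonded to c, bond length r, bond angle theta
## (b-c-D, degrees), torsion phi (a-b-c-D, degrees)
.placeAtom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- cbind(bc, .cross(n, bc), n)
  d <- c(-r * cos(th), r * cos(ph) * sin(th), r * sin(ph) * sin(th))
  c(c + m %*% d)
}

## canonical N/CA/C frame for chains built without an explicit anchor
.canonicalFrame <- function(geom = idealGeometry()) {
  th <- geom$aNCAC * pi / 180
  ca <- c(geom$bNCA, 0, 0)
  rbind(N = c(0, 0, 0), CA = ca,
        C = ca + geom$bCAC * c(-cos(th), -sin(th), 0))
}

#' Build an ideal-geometry extended backbone
#'
#' Places N, CA, C, O for each residue with ideal bond lengths and angles
#' (see [idealGeometry()]), planar peptide bonds (omega 180 degrees) and
#' the supplied phi/psi torsions (recycled; defaults give an extended
#' chain). When \code{startFrame} (the N/CA/C coordinates of the preceding
#' anchor residue) is given the chain grows from that frame; otherwise a
#' canonical frame at the origin is used.
#'
#' @param sequence 1-letter amino-acid string.
#' @param resnos residue numbers (default \code{1:n}); gaps are allowed,
#'   as for deletion variants keeping full-length numbering.
#' @param startFrame optional 3 x 3 matrix of N, CA, C anchor coordinates.
#' @param phi,psi backbone torsions in degrees (recycled over residues).
#' @param psiAnchor torsion placing the first N relative to the anchor.
#' @param geom geometry constants from [idealGeometry()].
#' @return List with \code{atoms} (data.frame: eleno, elety, resid, chain,
#'   resno), \code{xyz} (natoms x 3) and \code{bonds} (rotatable phi/psi
#'   bond table for [ccdClose()]).
#' @export
buildIdealBackbone <- function(sequence, resnos = NULL, startFrame = NULL,
                               phi = -120, psi = 135, psiAnchor = 135,
                               geom = idealGeometry()) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  if (!L) stop("empty sequence")
  if (is.null(resnos)) resnos <- seq_len(L)
  stopifnot(length(resnos) == L)
  phi <- rep_len(phi, L); psi <- rep_len(psi, L)
  prev <- if (is.null(startFrame)) .canonicalFrame(geom) else startFrame
  psiPrev <- psiAnchor
  xyz <- matrix(NA_real_, nrow = 4L * L, ncol = 3L)
  for (i in seq_len(L)) {
    N <- .placeAtom(prev[1, ], prev[2, ], prev[3, ], geom$bCN, geom$aCACN,
                    psiPrev)
    CA <- .placeAtom(prev[2, ], prev[3, ], N, geom$bNCA, geom$aCNCA, 180)
    C <- .placeAtom(prev[3, ], N, CA, geom$bCAC, geom$aNCAC, phi[i])
    O <- .placeAtom(N, CA, C, geom$bCO, geom$aCACO, psi[i] - 180)
    xyz[(4L * i - 3L):(4L * i), ] <- rbind(N, CA, C, O)
    prev <- rbind(N, CA, C)
    psiPrev <- psi[i]
  }
  atoms <- data.frame(eleno = seq_len(4L * L),
                      elety = rep(c("N", "CA", "C", "O"), L),
                      resid = rep(unname(.AA3[aa]), each = 4L),
                      chain = "A", resno = rep(as.integer(resnos), each = 4L))
  list(atoms = atoms, xyz = xyz, bonds = .backboneBonds(L))
}

## rotatable phi (N->CA) and psi (CA->C) bonds for L residues stored as
## N,CA,C,O blocks; moveStart = first atom index moved by the rotation
.backboneBonds <- function(L) {
  base <- 4L * (seq_len(L) - 1L)
  data.frame(from = c(rbind(base + 1L, base + 2L)),
             to = c(rbind(base + 2L, base + 3L)),
             moveStart = c(rbind(base + 3L, base + 4L)))
}

#' Close a backbone loop onto anchor targets by cyclic coordinate descent
#'
#' Sweeps the rotatable backbone torsions; at each bond the closed-form
#' angle minimising the squared deviation of the mobile anchor atoms from
#' their fixed targets is applied (Canutescu and Dunbrack, 2003).
#' Rotations are rigid, so bond lengths and angles are preserved exactly.
#' Convergence means the RMSD of the anchor atoms to their targets is
#' below \code{tol}; on non-convergence the best pose found is returned
#' with \code{converged = FALSE}.
#'
#' @param xyz natoms x 3 coordinate matrix.
#' @param bonds rotatable-bond table (\code{from}, \code{to},
#'   \code{moveStart}), e.g. from [buildIdealBackbone()].
#' @param targetIdx indices of the mobile anchor atoms (typically the
#'   N/CA/C triplet grown past the loop).
#' @param target matrix of target coordinates, one row per anchor atom.
#' @param maxIter maximum CCD sweeps.
#' @param tol convergence tolerance on the anchor RMSD (Angstrom).
#' @return List with \code{xyz}, \code{converged}, \code{iterations} and
#'   \code{anchorRMSD}.
#' @export
ccdClose <- function(xyz, bonds, targetIdx, target, maxIter = 500,
                     tol = 0.1) {
  res <- .ccd_close_cpp(xyz, as.integer(bonds$from), as.integer(bonds$to),
                        as.integer(bonds$moveStart), as.integer(targetIdx),
                        target, as.integer(maxIter), tol)
  list(xyz = res$coords, converged = res$converged,
       iterations = res$iterations, anchorRMSD = res$anchor_rmsd)
}

#' Apply torsion increments to a backbone
#'
#' Rotates each rotatable bond by the given increment (degrees), in bond
#' order. Rigid rotations: internal geometry is untouched.
#'
#' @inheritParams ccdClose
#' @param delta increments in degrees, one per bond.
#' @return The perturbed coordinate matrix.
#' @export
applyTorsions <- function(xyz, bonds, delta) {
  stopifnot(length(delta) == nrow(bonds))
  .apply_torsions_cpp(xyz, as.integer(bonds$from), as.integer(bonds$to),
                      as.integer(bonds$moveStart), delta * pi / 180)
}

.rotX <- function(a) { c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, byrow = TRUE) }
.rotZ <- function(a) { c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, byrow = TRUE) }

.transformPose <- function(pose, R, t) {
  pose$xyz <- sweep(pose$xyz %*% t(R), 2L, -t)
  pose
}

#' Loop geometry specification for the synthetic sampler
#'
#' Defines the loop to be sampled: its sequence and residue numbers, the
#' fixed anchor residues on either side, the anchor separation, and the
#' fixed protease-body residues carried along for contact statistics.
#'
#' @param sequence loop 1-letter sequence.
#' @param resnos loop residue numbers (gaps allowed for deletion
#'   variants).
#' @param nAnchor,cAnchor lists with \code{resno} and \code{aa} for the
#'   anchor residue preceding / following the loop.
#' @param anchorSep distance (Angstrom) between the two anchor C-alpha
#'   atoms; must be spannable by the shortest loop sampled.
#' @param body list with \code{sequence} and \code{resnos} of the fixed
#'   body segment, or NULL for none.
#' @param geom geometry constants.
#' @return A list of class \code{loopGeometrySpec}.
#' @export
loopGeometrySpec <- function(sequence, resnos,
                             nAnchor = list(resno = min(resnos) - 1L, aa = "A"),
                             cAnchor = list(resno = max(resnos) + 1L, aa = "A"),
                             anchorSep = 9.5,
                             body = NULL, geom = idealGeometry()) {
  if (!nchar(sequence)) stop("loop sequence must be non-empty")
  if (anchorSep <= 0) stop("anchors must not coincide")
  structure(list(sequence = sequence, resnos = as.integer(resnos),
                 nAnchor = nAnchor, cAnchor = cAnchor,
                 anchorSep = anchorSep, body = body, geom = geom),
            class = "loopGeometrySpec")
}

#' FVIIa 170-loop geometry fixture for the synthetic sampler
#'
#' The rebuilt span 311-321 (sequence LQQSRKVGDSP) anchored on C310 and
#' N322, with the protease-body stretch Q366/G372/H373/F374 (the contact
#' partners of the loop statistics) carried as a fixed rigid segment. A
#' deletion window removes the corresponding residues while keeping
#' full-length numbering with gaps.
#'
#' @param start,size optional deletion window (full-length numbering).
#' @param anchorSep anchor C-alpha separation in Angstrom.
#' @return A \code{loopGeometrySpec}.
#' @export
fviiaLoopGeometry <- function(start = NULL, size = NULL, anchorSep = 9.5) {
  resnos <- 311:321
  seqs <- strsplit("LQQSRKVGDSP", "")[[1]]
  if (!is.null(start)) {
    win <- as.integer(start):(as.integer(start) + as.integer(size) - 1L)
    if (!all(win %in% resnos))
      stop("deletion window must lie inside the rebuilt span 311-321")
    keep <- !resnos %in% win
    resnos <- resnos[keep]; seqs <- seqs[keep]
  }
  loopGeometrySpec(paste(seqs, collapse = ""), resnos,
                   nAnchor = list(resno = 306:310, aa = "MTQDC"),
                   cAnchor = list(resno = 322L, aa = "N"),
                   anchorSep = anchorSep,
                   body = list(sequence = "QGHF",
                               resnos = c(366L, 372L, 373L, 374L)))
}

## fixed scaffold: anchor segment (built with helical torsions so a
## TF-helix-like axis exists when it spans several residues), C-side anchor
## residue and body segment, all in one fixed template frame
.buildScaffold <- function(loop) {
  geom <- loop$geom
  nRes <- nchar(loop$nAnchor$aa)
  nAnchor <- buildIdealBackbone(loop$nAnchor$aa, loop$nAnchor$resno,
                                phi = -57, psi = -47, geom = geom)
  frameCA <- nAnchor$xyz[4L * (nRes - 1L) + 2L, ]
  cAnchor <- buildIdealBackbone(loop$cAnchor$aa, loop$cAnchor$resno,
                                geom = geom)
  ## place the C anchor at anchorSep from the N-side anchor CA, re-oriented
  ## by a fixed rotation so the closure target is generic (not collinear)
  u <- .unit(c(1, 0.35, 0.15))
  cAnchor <- .transformPose(cAnchor, .rotZ(2.4) %*% .rotX(0.6),
                            frameCA + loop$anchorSep * u)
  body <- NULL
  if (!is.null(loop$body)) {
    body <- buildIdealBackbone(loop$body$sequence, loop$body$resnos,
                               geom = geom)
    mid <- (frameCA + cAnchor$xyz[2, ]) / 2
    body <- .transformPose(body, .rotZ(1.2), mid + c(-2.5, -6.5, 1.5))
  }
  list(nAnchor = nAnchor, cAnchor = cAnchor, body = body,
       frame = nAnchor$xyz[(4L * (nRes - 1L) + 1L):(4L * (nRes - 1L) + 3L), ],
       target = cAnchor$xyz[1:3, ])
}

#' Synthetic ensemble specification
#'
#' Generation parameters for [sampleLoopEnsemble()]: ensemble size (the
#' packaged default emulates 250-pose loop-modelling output), the torsion
#' perturbation spread, the closure tolerance, and the pseudo-energy model
#' \code{score = offset + slope * RMSD_to_native + Normal(0, sigma)},
#' which guarantees score/RMSD funnels with known correlation structure.
#'
#' @param nPoses ensemble size (default 250).
#' @param sigmaTorsion per-torsion Gaussian perturbation SD, degrees.
#' @param closureTol anchor-RMSD tolerance for pose closure, Angstrom.
#' @param maxIter maximum CCD sweeps per closure.
#' @param energySlope slope of the pseudo-energy vs RMSD (REU/Angstrom).
#' @param energySigma SD of the pseudo-energy noise (REU).
#' @param energyOffset pseudo-energy baseline (REU).
#' @param seed RNG seed recorded with the output.
#' @return A list of class \code{syntheticEnsembleSpec}.
#' @export
syntheticEnsembleSpec <- function(nPoses = 250, sigmaTorsion = 20,
                                  closureTol = 0.1, maxIter = 200,
                                  energySlope = 1, energySigma = 0.2,
                                  energyOffset = -300, seed = 1) {
  stopifnot(nPoses >= 1, closureTol > 0, sigmaTorsion >= 0)
  structure(list(nPoses = as.integer(nPoses), sigmaTorsion = sigmaTorsion,
                 closureTol = closureTol, maxIter = as.integer(maxIter),
                 energySlope = energySlope, energySigma = energySigma,
                 energyOffset = energyOffset, seed = as.integer(seed)),
            class = "syntheticEnsembleSpec")
}

#' Sample a synthetic closed-loop conformer ensemble
#'
#' Builds a closed native reference loop between the fixed anchors (ideal
#' extended backbone + CCD closure), then generates \code{nPoses}
#' independent conformations by Gaussian torsion perturbation of the
#' native followed by re-closure. Pseudo-energies follow the linear
#' RMSD model configured in \code{spec}. The ground truth (native
#' coordinates, per-pose RMSD, seed,
#' closure failure rate) is stored in the ensemble metadata under
#' \code{truth}. Output is fully deterministic in the seed.
#'
#' @param loop a \code{loopGeometrySpec}, e.g. [fviiaLoopGeometry()].
#' @param spec a \code{syntheticEnsembleSpec}.
#' @param seed RNG seed (defaults to the one in \code{spec}).
#' @return A [ConformerEnsemble-class] whose poses share the fixed
#'   anchor/body atoms.
#' @examples
#' ens <- sampleLoopEnsemble(fviiaLoopGeometry(),
#'                           syntheticEnsembleSpec(nPoses = 5), seed = 7)
#' nPoses(ens)
#' @export
sampleLoopEnsemble <- function(loop, spec = syntheticEnsembleSpec(),
                               seed = spec$seed) {
  set.seed(seed)
  scaffold <- .buildScaffold(loop)
  ext <- buildIdealBackbone(loop$sequence, loop$resnos,
                            startFrame = scaffold$frame,
                            geom = loop$geom)
  nLoopAtoms <- nrow(ext$xyz)
  ## grow the mobile copy of the C-anchor N/CA/C used as closure target
  virt <- buildIdealBackbone(loop$cAnchor$aa,
                             loop$cAnchor$resno,
                             startFrame = ext$xyz[(nLoopAtoms - 3L):
                                                  (nLoopAtoms - 1L), ],
                             geom = loop$geom)
  xyz0 <- rbind(ext$xyz, virt$xyz[1:3, ])
  targetIdx <- nLoopAtoms + 1:3
  nat <- ccdClose(xyz0, ext$bonds, targetIdx, scaffold$target,
                  maxIter = 2000, tol = min(0.05, spec$closureTol))
  if (!nat$converged)
    stop("could not build a closed native loop (anchor RMSD ",
         round(nat$anchorRMSD, 2), " A); increase anchorSep or closureTol")
  native <- nat$xyz
  nb <- nrow(ext$bonds)
  poses <- matrix(NA_real_, nrow = spec$nPoses, ncol = 3L * nLoopAtoms)
  attempts <- 0L; failures <- 0L
  for (p in seq_len(spec$nPoses)) {
    ok <- FALSE
    for (try in 1:20) {
      attempts <- attempts + 1L
      delta <- rnorm(nb, 0, spec$sigmaTorsion)
      X <- applyTorsions(native, ext$bonds, delta)
      cl <- ccdClose(X, ext$bonds, targetIdx, scaffold$target,
                     maxIter = spec$maxIter, tol = spec$closureTol)
      if (cl$converged) { ok <- TRUE; break }
      failures <- failures + 1L
    }
    if (!ok)
      stop("pose ", p, " failed to close after 20 attempts; ",
           "increase closureTol or reduce sigmaTorsion")
    poses[p, ] <- as.vector(t(cl$xyz[seq_len(nLoopAtoms), , drop = FALSE]))
  }
  failRate <- failures / attempts
  if (failRate > 0.5)
    stop("closure failure rate ", round(100 * failRate), "%; ",
         "increase closureTol or reduce sigmaTorsion")
  ## assemble shared atom table: anchors + loop + body, ascending residue
  parts <- list(scaffold$nAnchor,
                list(atoms = ext$atoms, xyz = ext$xyz[seq_len(nLoopAtoms), ]),
                scaffold$cAnchor, scaffold$body)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  fixedMask <- rep(c(TRUE, FALSE, TRUE, TRUE)[seq_along(parts)],
                   vapply(parts, function(p) nrow(p$atoms), integer(1)))
  fixedXYZ <- do.call(rbind, lapply(parts, `[[`, "xyz"))
  natAtoms <- nrow(atoms)
  xyz <- matrix(NA_real_, nrow = spec$nPoses, ncol = 3L * natAtoms)
  fixedCols <- .xyzCols(which(fixedMask))
  loopCols <- .xyzCols(which(!fixedMask))
  for (p in seq_len(spec$nPoses)) {
    xyz[p, fixedCols] <- as.vector(t(fixedXYZ[fixedMask, , drop = FALSE]))
    xyz[p, loopCols] <- poses[p, ]
  }
  atoms$eleno <- seq_len(natAtoms)
  nativeLoop <- matrix(as.vector(t(native[seq_len(nLoopAtoms), ])),
                       nrow = 1L)
  dev2 <- sweep(poses, 2L, nativeLoop[1, ])^2
  rmsd <- sqrt(rowSums(dev2) / nLoopAtoms)
  scores <- spec$energyOffset + spec$energySlope * rmsd +
    rnorm(spec$nPoses, 0, spec$energySigma)
  ConformerEnsemble(atoms, xyz, scores = scores,
                    rebuildSpan = range(loop$resnos),
                    metadata = list(truth = list(
                      seed = seed, rmsdToNative = rmsd,
                      nativeLoopXYZ = native[seq_len(nLoopAtoms), ],
                      loopAtomIdx = which(!fixedMask),
                      energySlope = spec$energySlope,
                      energySigma = spec$energySigma,
                      closureFailRate = failRate)))
}

#' Plant a known contact fraction into an ensemble
#'
#' For a Bernoulli(\code{f}) subset of poses the geometry of the atom pair
#' is locally adjusted so the pair distance falls below 3.4 Angstrom
#' (uniform in \code{contactRange}); all other poses are pushed beyond 4.5
#' Angstrom (uniform in \code{apartRange}). The second atom is moved along
#' the pair axis. The realised Bernoulli draw is recorded in the metadata
#' under \code{plantedContact} so estimators can be checked against the
#' exact ground truth.
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param a,b atom specs ([atomSpec()]); \code{b} is the atom moved.
#' @param f target contact fraction in \[0, 1\].
#' @param seed RNG seed for the Bernoulli draw and distances.
#' @param contactRange,apartRange distance ranges for contact / no-contact
#'   poses.
#' @return The modified [ConformerEnsemble-class].
#' @export
plantContactFraction <- function(ensemble, a, b, f, seed = 1,
                                 contactRange = c(2.7, 3.3),
                                 apartRange = c(4.6, 6.0)) {
  stopifnot(f >= 0, f <= 1)
  set.seed(seed)
  ia <- .resolveAtom(ensemble, a)
  ib <- .resolveAtom(ensemble, b)
  n <- nPoses(ensemble)
  isContact <- runif(n) < f
  d <- ifelse(isContact, runif(n, contactRange[1], contactRange[2]),
              runif(n, apartRange[1], apartRange[2]))
  xyz <- ensemble@xyz
  ca <- .xyzCols(ia); cb <- .xyzCols(ib)
  for (p in seq_len(n)) {
    v <- xyz[p, cb] - xyz[p, ca]
    nv <- sqrt(sum(v^2))
    u <- if (nv < 1e-6) .unit(rnorm(3)) else v / nv
    xyz[p, cb] <- xyz[p, ca] + d[p] * u
  }
  md <- ensemble@metadata
  md$plantedContact <- list(a = a, b = b, f = f, seed = seed,
                            isContact = isContact,
                            realizedFraction = mean(isContact))
  initialize(ensemble, xyz = xyz, metadata = md)
}
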