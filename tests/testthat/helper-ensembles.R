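# In-code fixtures: small ensembles built directly, plus a scaled-down
# synthetic sampler wrapper. No fixture files.

toyAtoms <- function(resnos = 1:3, elety = c("N", "CA", "C", "O")) {
  n <- length(resnos) * length(elety)
  data.frame(eleno = seq_len(n),
             elety = rep(elety, length(resnos)),
             resid = "ALA", chain = "A",
             resno = rep(as.integer(resnos), each = length(elety)))
}

# poses: list of natoms x 3 matrices
toyEnsemble <- function(poses, atoms = NULL, scores = NULL) {
  if (is.null(atoms)) atoms <- toyAtoms(seq_len(nrow(poses[[1]]) / 4))
  xyz <- do.call(rbind, lapply(poses, function(p) as.vector(t(p))))
  ConformerEnsemble(atoms, xyz, scores = scores)
}

smallEnsemble <- function(nPoses = 25, seed = 42, sigmaTorsion = 20,
                          start = NULL, size = NULL) {
  sampleLoopEnsemble(fviiaLoopGeometry(start, size),
                     syntheticEnsembleSpec(nPoses = nPoses,
                                           sigmaTorsion = sigmaTorsion),
                     seed = seed)
}

# consecutive backbone bond lengths (N-CA, CA-C, C-N) for an N/CA/C/O chain
backboneBondLengths <- function(xyz, nres) {
  idx <- function(r, k) 4 * (r - 1) + k     # k: 1=N 2=CA 3=C 4=O
  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  out <- c()
  for (r in seq_len(nres)) {
    out <- c(out, d(idx(r, 1), idx(r, 2)), d(idx(r, 2), idx(r, 3)),
             d(idx(r, 3), idx(r, 4)))
    if (r < nres) out <- c(out, d(idx(r, 3), idx(r + 1, 1)))
  }
  out
}
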