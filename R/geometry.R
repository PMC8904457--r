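## Ensemble statistics. Poses are assumed to share the fixed protease-body
## frame (loops rebuilt on a rigid template), so no re-superposition is
## performed before RMSD/RMSF; superposePoses() is available for foreign
## ensembles that need a common frame first.

.defaultSelection <- function(ensemble, selection) {
  if (!is.null(selection)) return(selection)
  if (!all(is.na(ensemble@rebuildSpan)))
    selectAtoms(ensemble, resno = ensemble@rebuildSpan)
  else seq_len(nAtoms(ensemble))
}

#' Mean structure of an ensemble
#'
#' Per-atom arithmetic mean of coordinates across poses ("geometric mean"
#' in the sense of the mean geometry; no re-superposition).
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param selection integer atom indices (from [selectAtoms()]); default is
#'   the heavy atoms of the rebuilt span when recorded, else all atoms.
#' @return Matrix \code{length(selection) x 3} of mean coordinates, with
#'   the selected atom table attached as attribute \code{atoms}.
#' @export
geometricMeanStructure <- function(ensemble, selection = NULL) {
  sel <- .defaultSelection(ensemble, selection)
  if (!length(sel)) stop("empty selection")
  m <- colMeans(ensemble@xyz[, .xyzCols(sel), drop = FALSE])
  structure(matrix(m, ncol = 3L, byrow = TRUE),
            atoms = ensemble@atoms[sel, ])
}

#' Root-mean-square fluctuation profile
#'
#' Per-atom RMSF around the ensemble mean structure:
#' \code{sqrt(mean over poses of |x - mean(x)|^2)}, plus its average over
#' the selection. A single-pose ensemble is degenerate and yields zeros
#' with a message.
#'
#' @inheritParams geometricMeanStructure
#' @return data.frame with the selected atoms and their \code{rmsf} (in
#'   Angstrom); the scalar selection average is attached as attribute
#'   \code{average}.
#' @export
rmsfProfile <- function(ensemble, selection = NULL) {
  sel <- .defaultSelection(ensemble, selection)
  X <- ensemble@xyz[, .xyzCols(sel), drop = FALSE]
  if (nrow(X) < 2L) {
    message("single-pose ensemble: RMSF is degenerate (all zero)")
    rmsf <- rep(0, length(sel))
  } else {
    dev2 <- sweep(X, 2L, colMeans(X))^2
    ## sum x,y,z deviations per atom, average over poses
    perAxis <- colMeans(dev2)
    rmsf <- sqrt(perAxis[c(TRUE, FALSE, FALSE)] +
                 perAxis[c(FALSE, TRUE, FALSE)] +
                 perAxis[c(FALSE, FALSE, TRUE)])
  }
  out <- cbind(ensemble@atoms[sel, ], rmsf = unname(rmsf))
  rownames(out) <- NULL
  structure(out, average = mean(rmsf))
}

#' RMSD between two poses
#'
#' Root-mean-square coordinate deviation over a selection, without
#' refitting (poses share the fixed template frame).
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param a,b pose indices.
#' @param selection integer atom indices; see [geometricMeanStructure()].
#' @return RMSD in Angstrom.
#' @export
poseRMSD <- function(ensemble, a, b, selection = NULL) {
  sel <- .defaultSelection(ensemble, selection)
  cols <- .xyzCols(sel)
  d <- ensemble@xyz[a, cols] - ensemble@xyz[b, cols]
  sqrt(sum(d^2) / length(sel))
}

.rmsdToPose <- function(ensemble, ref, selection) {
  cols <- .xyzCols(selection)
  X <- ensemble@xyz[, cols, drop = FALSE]
  d2 <- sweep(X, 2L, X[ref, ])^2
  sqrt(rowSums(d2) / length(selection))
}

#' Score/RMSD funnel table
#'
#' Per-pose score against RMSD to the lowest-scoring pose (ties broken by
#' lowest pose index), the standard view for judging whether an ensemble
#' has a coherent low-energy cluster. RMSD is computed over the rebuilt
#' span's heavy atoms by default.
#'
#' @inheritParams geometricMeanStructure
#' @return data.frame with columns \code{pose}, \code{tag}, \code{score},
#'   \code{rmsd}; the reference pose index is attached as attribute
#'   \code{reference}.
#' @export
funnelTable <- function(ensemble, selection = NULL) {
  if (nPoses(ensemble) < 1L) stop("empty ensemble")
  s <- ensemble@scores
  if (length(unique(s)) == 1L)
    message("all scores equal; using pose 1 as funnel reference")
  ref <- which.min(s)                      # first minimum = lowest index
  sel <- .defaultSelection(ensemble, selection)
  data.frame(pose = seq_len(nPoses(ensemble)), tag = ensemble@tags,
             score = s, rmsd = .rmsdToPose(ensemble, ref, sel)) |>
    structure(reference = ref)
}

#' Lowest-energy pose selection
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param n number of poses to select.
#' @return Integer pose indices of the \code{n} smallest scores, stable
#'   tie-break by pose index.
#' @export
selectLowEnergy <- function(ensemble, n) {
  n <- as.integer(n)
  if (n > nPoses(ensemble))
    stop("n = ", n, " exceeds the ensemble size ", nPoses(ensemble))
  order(ensemble@scores, seq_along(ensemble@scores))[seq_len(n)]
}

#' Representative poses from RMSD groupings
#'
#' Partitions poses into \code{nGroups} equal-width bins over the
#' RMSD-to-reference axis of the funnel and returns, within each bin, the
#' \code{perGroup} lowest-scoring poses. Empty or under-filled bins are
#' reported as-is, not topped up from neighbours. A degenerate RMSD range
#' (all poses equal) collapses to a single group with a warning.
#'
#' @inheritParams geometricMeanStructure
#' @param nGroups number of RMSD bins.
#' @param perGroup representatives per bin.
#' @return List with \code{groups} (list of pose-index vectors, low to
#'   high RMSD), \code{breaks} (bin edges) and \code{funnel} (the funnel
#'   table used).
#' @export
rmsdGroupRepresentatives <- function(ensemble, nGroups = 3, perGroup = 5,
                                     selection = NULL) {
  nGroups <- as.integer(nGroups); perGroup <- as.integer(perGroup)
  if (nGroups * perGroup > nPoses(ensemble))
    stop("nGroups * perGroup exceeds the ensemble size")
  fun <- funnelTable(ensemble, selection)
  r <- range(fun$rmsd)
  if (diff(r) < 1e-9) {
    warning("degenerate RMSD range; returning a single group")
    nGroups <- 1L
  }
  breaks <- seq(r[1], r[2], length.out = nGroups + 1L)
  bin <- pmin(pmax(findInterval(fun$rmsd, breaks, rightmost.closed = TRUE),
                   1L), nGroups)
  groups <- lapply(seq_len(nGroups), function(g) {
    in.g <- which(bin == g)
    in.g[order(fun$score[in.g], in.g)][seq_len(min(perGroup, length(in.g)))]
  })
  nEmpty <- sum(!lengths(groups))
  if (nEmpty) message(nEmpty, " empty RMSD bin(s) reported unfilled")
  list(groups = groups, breaks = breaks, funnel = fun)
}

#' Atom specification helper
#'
#' @param resno residue number (full-length numbering).
#' @param elety atom name (e.g. \code{"N"}, \code{"O"}).
#' @param chain optional chain identifier.
#' @return A list usable as an atom spec in [atomDistanceSeries()].
#' @export
atomSpec <- function(resno, elety, chain = NULL)
  list(resno = as.integer(resno), elety = elety, chain = chain)

.resolveAtom <- function(ensemble, spec) {
  a <- ensemble@atoms
  hit <- a$resno == spec$resno & a$elety == spec$elety
  if (!is.null(spec$chain)) hit <- hit & a$chain == spec$chain
  i <- which(hit)
  if (length(i) != 1L)
    stop("atom ", spec$elety, " of residue ", spec$resno,
         if (length(i)) " is ambiguous" else " not found",
         " in the ensemble")
  i
}

#' Per-pose distance series between two atoms
#'
#' Euclidean distance (Angstrom) between two atoms in every pose. The
#' shared atom table guarantees both atoms resolve identically across
#' poses; an unresolvable atom errors naming it.
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param a,b atom specs from [atomSpec()].
#' @return Numeric vector of length \code{nPoses(ensemble)} with the pair
#'   attached as attribute \code{pair}.
#' @export
atomDistanceSeries <- function(ensemble, a, b) {
  ia <- .resolveAtom(ensemble, a)
  ib <- .resolveAtom(ensemble, b)
  da <- ensemble@xyz[, .xyzCols(ia), drop = FALSE] -
    ensemble@xyz[, .xyzCols(ib), drop = FALSE]
  structure(sqrt(rowSums(da^2)), pair = list(a = a, b = b))
}

#' Hydrogen-bond distance summary
#'
#' Classifies a donor-acceptor heavy-atom distance series: the mean and
#' population SD of the series, a stability flag keyed on the mean lying
#' inside the classification window (default 2.5-3.8 Angstrom), the
#' fraction of poses inside the histogram range (default 2.5-4.0), and a
#' fixed-width histogram (0.1 Angstrom bins) over that range.
#'
#' @param series numeric distance series (Angstrom), e.g. from
#'   [atomDistanceSeries()].
#' @param window classification window for the mean.
#' @param histRange histogram range.
#' @param binWidth histogram bin width.
#' @return List with \code{mean}, \code{sd}, \code{stable},
#'   \code{inRangeFrequency} and \code{histogram} (data.frame of bin
#'   \code{mid} and \code{count}).
#' @export
hbondSummary <- function(series, window = c(2.5, 3.8),
                         histRange = c(2.5, 4.0), binWidth = 0.1) {
  if (!length(series)) stop("empty distance series")
  m <- mean(series)
  sdev <- sqrt(mean((series - m)^2))        # population SD
  inRange <- series >= histRange[1] & series <= histRange[2]
  breaks <- seq(histRange[1], histRange[2], by = binWidth)
  counts <- table(cut(series[inRange], breaks, include.lowest = TRUE))
  list(mean = m, sd = sdev,
       stable = m >= window[1] && m <= window[2],
       inRangeFrequency = mean(inRange),
       histogram = data.frame(mid = head(breaks, -1L) + binWidth / 2,
                              count = as.integer(counts)))
}

#' Polar-contact frequency
#'
#' Fraction of poses with distance strictly below the cutoff.
#'
#' @param series numeric distance series (Angstrom).
#' @param cutoff contact cutoff (default 3.5 Angstrom, strict \code{<}).
#' @return Fraction in \[0, 1\].
#' @export
contactFrequency <- function(series, cutoff = 3.5) {
  if (!length(series)) stop("empty distance series")
  mean(series < cutoff)
}

#' Resolve the residue occupying a loop "slot" in a deletion variant
#'
#' After a deletion the residues C-terminal of the window shift N-ward, so
#' a structural position ("slot") once held by a given residue is occupied
#' by another. The slot is counted as an ordinal from the loop's
#' N-terminal anchor; the residue now at that ordinal in the truncated
#' loop is returned. If the truncated loop is shorter than the ordinal the
#' C-terminal anchor residue is returned with a warning. With no deletion
#' the function is the identity; it is also the identity whenever the
#' window lies entirely C-terminal of the slot.
#'
#' @param loopDef A [LoopDefinition-class].
#' @param slot full-length residue number of the slot (must lie in the
#'   loop span).
#' @param start,size deletion window; \code{NULL} start means no deletion.
#' @return Full-length residue number present in the variant at the slot.
#' @examples
#' ld <- fviiaLoopDefinition()
#' resolveSlotResidue(ld, 315)                       # 315 (wild type)
#' resolveSlotResidue(ld, 315, start = 315, size = 2) # 317
#' @export
resolveSlotResidue <- function(loopDef, slot, start = NULL, size = NULL) {
  loop <- loopDef@loopSpan[1]:loopDef@loopSpan[2]
  slot <- as.integer(slot)
  if (!slot %in% loop)
    stop("slot ", slot, " lies outside the loop span ",
         loopDef@loopSpan[1], "-", loopDef@loopSpan[2])
  remaining <- if (is.null(start)) loop else {
    win <- as.integer(start):(as.integer(start) + as.integer(size) - 1L)
    setdiff(loop, win)
  }
  ordinal <- slot - loopDef@loopSpan[1] + 1L
  if (ordinal > length(remaining)) {
    warning("truncated loop shorter than slot ordinal ", ordinal,
            "; returning the C-terminal anchor")
    return(loopDef@loopSpan[2] + 1L)
  }
  remaining[ordinal]
}

#' Helix tilt angle
#'
#' Angle between (i) the principal axis of a set of helix C-alpha atoms
#' (first principal component, oriented N to C) and (ii) the base vector
#' running between the centroids of two reference atom selections (e.g.
#' the bottom of a loop and the outer side of the helix). Used to compare
#' TF-helix orientations between templates.
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param pose pose index (default 1).
#' @param helixSelection list with \code{resno} (interval) and optional
#'   \code{elety} (default \code{"CA"}); needs >= 3 atoms.
#' @param baseSelection list of two selections (\code{from}, \code{to}),
#'   each as in \code{helixSelection}; the base vector points from the
#'   centroid of \code{from} to the centroid of \code{to}.
#' @return List with \code{angle} (degrees, in \[0, 180\]),
#'   \code{helixAxis}, \code{baseVector} and the selections used.
#' @export
helixAngle <- function(ensemble, pose = 1L,
                       helixSelection = list(resno = c(307L, 312L),
                                             elety = "CA"),
                       baseSelection = fviiaHelixBaseSelection()) {
  X <- poseCoords(ensemble, pose)
  hIdx <- selectAtoms(ensemble, resno = helixSelection$resno,
                      elety = helixSelection$elety %||% "CA")
  if (length(hIdx) < 3L) stop("helix selection needs >= 3 C-alpha atoms")
  H <- X[hIdx, , drop = FALSE]
  pc <- prcomp(H, center = TRUE)
  if (pc$sdev[1] < 1e-9) stop("degenerate helix selection (coincident atoms)")
  axis <- pc$rotation[, 1]
  nc <- H[nrow(H), ] - H[1, ]               # orient N -> C
  if (sum(axis * nc) < 0) axis <- -axis
  centroid <- function(s) {
    i <- selectAtoms(ensemble, resno = s$resno, elety = s$elety)
    colMeans(X[i, , drop = FALSE])
  }
  base <- centroid(baseSelection[[2]]) - centroid(baseSelection[[1]])
  bn <- sqrt(sum(base^2))
  if (bn < 1e-9) stop("degenerate base selection (coincident centroids)")
  cosang <- sum(axis * base) / bn
  list(angle = acos(pmin(pmax(cosang, -1), 1)) * 180 / pi,
       helixAxis = axis, baseVector = base / bn,
       helixSelection = helixSelection, baseSelection = baseSelection)
}

#' Default base selections for the FVIIa TF-helix angle
#'
#' Nominal configuration for the tilt-angle base vector: from the bottom
#' of the 170 loop (C-alpha atoms of 316-318) to the outer, N-terminal
#' side of the TF helix (C-alpha atoms of 306-307). Shipped as config so
#' the selections can be re-calibrated against reference crystal
#' structures when those are available locally.
#'
#' @return List of two selections usable by [helixAngle()].
#' @export
fviiaHelixBaseSelection <- function() {
  list(from = list(resno = c(316L, 318L), elety = "CA"),
       to = list(resno = c(306L, 307L), elety = "CA"))
}

#' Superpose all poses onto a reference pose
#'
#' Kabsch superposition on a selection (default: all atoms), for foreign
#' ensembles whose poses do not share a common rigid frame. Ensembles from
#' loop rebuilding on a fixed template do not need this.
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param reference pose index to superpose onto.
#' @param selection atoms used for the fit (default all).
#' @return A [ConformerEnsemble-class] with superposed coordinates.
#' @export
superposePoses <- function(ensemble, reference = 1L, selection = NULL) {
  sel <- if (is.null(selection)) seq_len(nAtoms(ensemble)) else selection
  fixed <- ensemble@xyz[reference, ]
  xyz <- t(apply(ensemble@xyz, 1L, function(mob)
    bio3d::fit.xyz(fixed, mob, fixed.inds = .xyzCols(sel),
                   mobile.inds = .xyzCols(sel))))
  initialize(ensemble, xyz = xyz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
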