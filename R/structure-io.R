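#' Construct a conformer ensemble
#'
#' @param atoms data.frame with columns \code{eleno}, \code{elety},
#'   \code{resid}, \code{chain}, \code{resno}.
#' @param xyz numeric matrix, one row per pose, x/y/z triplets per atom; a
#'   single pose may be given as an \code{natoms x 3} matrix.
#' @param scores per-pose scores (REU); default all zero.
#' @param tags per-pose tags; default \code{model_1 ... model_N}.
#' @param rebuildSpan optional residue interval that was rebuilt.
#' @param metadata free-form provenance list.
#' @return A [ConformerEnsemble-class].
#' @export
ConformerEnsemble <- function(atoms, xyz, scores = NULL, tags = NULL,
                              rebuildSpan = NA_integer_, metadata = list()) {
  if (ncol(xyz) == 3L && nrow(xyz) == nrow(atoms))
    xyz <- matrix(as.numeric(t(xyz)), nrow = 1L)
  n <- nrow(xyz)
  if (is.null(scores)) scores <- rep(0, n)
  if (is.null(tags)) tags <- paste0("model_", seq_len(n))
  rownames(atoms) <- NULL
  new("ConformerEnsemble", atoms = atoms, xyz = unname(xyz),
      scores = as.numeric(scores), tags = as.character(tags),
      rebuildSpan = as.integer(rebuildSpan), metadata = metadata)
}

#' Accessors for ConformerEnsemble
#'
#' @param object A [ConformerEnsemble-class].
#' @param pose pose index (1-based).
#' @return \code{nPoses}/\code{nAtoms}: integer counts; \code{poseScores}:
#'   numeric scores; \code{poseTags}: character tags; \code{atomTable}: the
#'   shared atom data.frame; \code{poseCoords}: an \code{natoms x 3} matrix.
#' @rdname ConformerEnsemble-accessors
#' @export
setMethod("nPoses", "ConformerEnsemble", function(object) nrow(object@xyz))

#' @rdname ConformerEnsemble-accessors
#' @export
setMethod("nAtoms", "ConformerEnsemble", function(object) nrow(object@atoms))

#' @rdname ConformerEnsemble-accessors
#' @export
setMethod("poseScores", "ConformerEnsemble", function(object) object@scores)

#' @rdname ConformerEnsemble-accessors
#' @export
setMethod("poseTags", "ConformerEnsemble", function(object) object@tags)

#' @rdname ConformerEnsemble-accessors
#' @export
setMethod("atomTable", "ConformerEnsemble", function(object) object@atoms)

#' @rdname ConformerEnsemble-accessors
#' @export
setMethod("poseCoords", "ConformerEnsemble", function(object, pose) {
  pose <- as.integer(pose)
  if (pose < 1L || pose > nPoses(object)) stop("pose index out of range")
  matrix(object@xyz[pose, ], ncol = 3L, byrow = TRUE)
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d pose(s), %d atoms, residues %d-%d\n",
              nPoses(object), nAtoms(object), min(object@atoms$resno),
              max(object@atoms$resno)))
  if (!all(is.na(object@rebuildSpan)))
    cat(sprintf("  rebuilt span: %d-%d\n", object@rebuildSpan[1],
                object@rebuildSpan[2]))
  if (any(object@scores != 0))
    cat(sprintf("  scores (REU): %.2f .. %.2f\n", min(object@scores),
                max(object@scores)))
})

## strict per-model atom-correspondence check on the raw ATOM records,
## after the same hydrogen/altloc filtering the reader applies
.checkModelCorrespondence <- function(lines) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MODEL/ENDMDL structure (", length(starts), " MODEL vs ",
         length(ends), " ENDMDL records)")
  if (!length(starts)) return(invisible(1L))
  keys <- lapply(seq_along(starts), function(m) {
    blk <- lines[(starts[m] + 1L):(ends[m] - 1L)]
    blk <- blk[startsWith(blk, "ATOM")]
    alt <- substr(blk, 17, 17)
    blk <- blk[alt %in% c(" ", "A")]
    elety <- trimws(substr(blk, 13, 16))
    blk <- blk[!.isHydrogen(elety, substr(blk, 77, 78))]
    paste(trimws(substr(blk, 13, 16)), trimws(substr(blk, 23, 27)),
          substr(blk, 22, 22))
  })
  ref <- keys[[1]]
  for (m in seq_along(keys)[-1]) {
    k <- keys[[m]]
    if (length(k) != length(ref)) {
      bad <- min(length(k), length(ref)) + 1L
      offending <- if (length(k) > length(ref)) k[bad] else ref[bad]
      stop("model ", m, " has ", length(k), " atoms but model 1 has ",
           length(ref), " (first unmatched atom: ", offending, ")")
    }
    d <- which(k != ref)
    if (length(d))
      stop("model ", m, " atom ", d[1], " is '", k[d[1]],
           "' but model 1 has '", ref[d[1]], "'")
  }
  invisible(length(starts))
}

.isHydrogen <- function(elety, elesy = NULL) {
  ## standard-residue ATOM records: name with leading digits stripped starts
  ## with H; the element column, when present, overrides the heuristic
  stripped <- sub("^[0-9]+", "", trimws(elety))
  h <- startsWith(stripped, "H")
  if (!is.null(elesy)) {
    sy <- trimws(elesy)
    h <- ifelse(!is.na(sy) & nzchar(sy), sy == "H", h)
  }
  h
}

#' Read a loop-conformer ensemble from a multi-model PDB file
#'
#' Reads MODEL/ENDMDL blocks (a single-model file is treated as N = 1)
#' with strict atom-correspondence validation: every model must carry the
#' same atoms, in the same order, as model 1, or the reader errors naming
#' the first offending atom. Hydrogens are dropped (all distance criteria
#' in the ensemble statistics are heavy-atom) and only altloc " "/"A"
#' records are kept (others counted in a message). Per-pose scores are
#' joined from a whitespace-delimited table with header columns \code{tag}
#' and \code{reu}, keyed strictly on the pose tag; a missing score table
#' leaves all scores zero with a warning.
#'
#' @param pdbPath path to a (multi-model) PDB file.
#' @param scorePath optional path to a score table.
#' @param rebuildSpan optional integer(2) residue interval recorded as the
#'   default analysis selection.
#' @return A [ConformerEnsemble-class].
#' @seealso [writeMultiModelPDB()], [writeScoreTable()]
#' @export
readEnsemble <- function(pdbPath, scorePath = NULL,
                         rebuildSpan = NA_integer_) {
  lines <- readLines(pdbPath)
  .checkModelCorrespondence(lines)
  pdb <- tryCatch(bio3d::read.pdb(pdbPath, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("unparseable PDB file '", pdbPath, "': ",
                         conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM"
  nAlt <- sum(keep & !(at$alt %in% c(NA, "", " ", "A")))
  if (nAlt > 0) {
    message("dropping ", nAlt, " alternate-location atom record(s)")
    keep <- keep & (at$alt %in% c(NA, "", " ", "A"))
  }
  keep <- keep & !.isHydrogen(at$elety, at$elesy)
  idx <- which(keep)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- xyz[, bio3d::atom2xyz(idx), drop = FALSE]
  atoms <- data.frame(eleno = at$eleno[idx], elety = at$elety[idx],
                      resid = at$resid[idx], chain = ifelse(
                        is.na(at$chain[idx]), "A", at$chain[idx]),
                      resno = at$resno[idx])
  tags <- paste0("model_", seq_len(nrow(xyz)))
  scores <- rep(0, nrow(xyz))
  if (!is.null(scorePath)) {
    scores <- .joinScores(tags, scorePath)
  } else {
    warning("no score table supplied; scores set to 0")
  }
  ConformerEnsemble(atoms, xyz, scores = scores, tags = tags,
                    rebuildSpan = rebuildSpan,
                    metadata = list(source = pdbPath))
}

.joinScores <- function(tags, scorePath) {
  tab <- read.table(scorePath, header = TRUE, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("tag", "reu") %in% names(tab)))
    stop("score table must have header columns 'tag' and 'reu'")
  if (anyDuplicated(tab$tag))
    stop("duplicate pose tag in score table: ",
         tab$tag[anyDuplicated(tab$tag)])
  i <- match(tags, tab$tag)
  if (anyNA(i))
    stop("score table is missing tag(s): ",
         paste(tags[is.na(i)][seq_len(min(3, sum(is.na(i))))],
               collapse = ", "))
  as.numeric(tab$reu[i])
}

#' Write an ensemble as a multi-model PDB file
#'
#' Standard fixed-width PDB columns, one MODEL/ENDMDL block per pose,
#' coordinates rounded to 3 decimals. Serialisation is deterministic: the
#' same ensemble always yields byte-identical output.
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMultiModelPDB <- function(ensemble, path) {
  a <- ensemble@atoms
  bio3d::write.pdb(file = path, xyz = round(ensemble@xyz, 3),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain)
  invisible(path)
}

#' Write a per-pose score table
#'
#' Whitespace-delimited text with header columns \code{tag} and \code{reu},
#' one row per pose, joinable back by [readEnsemble()].
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeScoreTable <- function(ensemble, path) {
  write.table(data.frame(tag = ensemble@tags, reu = ensemble@scores),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## canonical intra-residue atom order used by all selections
.atomRank <- function(elety) {
  canon <- c("N", "CA", "C", "O", "CB")
  r <- match(elety, canon)
  ifelse(is.na(r), length(canon) + rank(elety, ties.method = "min") /
           (length(elety) + 1), r)
}

#' Select atoms from an ensemble
#'
#' Returns atom indices in the deterministic analysis order: ascending
#' residue number, then canonical atom-name order (N, CA, C, O, CB, then
#' alphabetical). Hydrogens are already absent from ensembles read by
#' [readEnsemble()].
#'
#' @param ensemble A [ConformerEnsemble-class].
#' @param resno optional residue interval \code{c(lo, hi)} or explicit
#'   residue numbers.
#' @param elety optional atom-name set (e.g. \code{"CA"}).
#' @return Integer atom indices into \code{atomTable(ensemble)}.
#' @examples
#' ## selectAtoms(ens, resno = c(311, 321), elety = "CA")
#' @export
selectAtoms <- function(ensemble, resno = NULL, elety = NULL) {
  a <- ensemble@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resno)) {
    resno <- as.integer(resno)
    keep <- keep & if (length(resno) == 2L)
      a$resno >= resno[1] & a$resno <= resno[2]
    else a$resno %in% resno
  }
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  idx <- which(keep)
  if (!length(idx))
    stop("empty atom selection (resno = ",
         paste(resno, collapse = ".."), ", elety = ",
         paste(elety, collapse = ","), ")")
  idx[order(a$resno[idx], .atomRank(a$elety[idx]))]
}

## xyz column indices for atom indices
.xyzCols <- function(idx) as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
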