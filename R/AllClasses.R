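## Central S4 containers. Result tables (funnels, RMSF profiles, activity
## tables) are plain data.frames, in keeping with how limma/bio3d return
## summary statistics.

#' Bidirectional full-length / chymotrypsin residue numbering
#'
#' Maps full-length residue numbers of a trypsin-like protease onto the
#' conventional chymotrypsin template numbering (integer label plus optional
#' insertion letter, e.g. \code{"170A"}). The map is bijective over its
#' domain, so round trips in either direction are the identity.
#'
#' @slot entries data.frame with columns \code{full} (integer, 1-based
#'   full-length numbering), \code{chym} (character label matching
#'   \code{[0-9]+[A-Z]?}) and \code{aa} (1-letter amino-acid code).
#' @seealso [fviiaNumberingMap()], [toChymotrypsin()], [fromChymotrypsin()]
#' @export
setClass("NumberingMap", representation(entries = "data.frame"))

setValidity("NumberingMap", function(object) {
  e <- object@entries
  msg <- character()
  if (!all(c("full", "chym", "aa") %in% names(e)))
    msg <- c(msg, "entries must have columns full, chym, aa")
  else {
    if (anyDuplicated(e$full) || anyDuplicated(e$chym))
      msg <- c(msg, "map must be bijective: duplicate full numbers or labels")
    if (any(e$full <= 0)) msg <- c(msg, "full numbers must be positive")
    if (!all(grepl("^[0-9]+[A-Z]?$", e$chym)))
      msg <- c(msg, "chym labels must match [0-9]+[A-Z]?")
    if (!all(e$aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
      msg <- c(msg, "aa must be 1-letter amino-acid codes")
  }
  if (length(msg)) msg else TRUE
})

#' Definition of a surface loop and its deletion-scan region
#'
#' Describes the loop in full-length numbering: the interval used for loop
#' length accounting (\code{loopSpan}), the interval that is structurally
#' rebuilt (\code{rebuildSpan}), and the interval eligible for deletion
#' (\code{scanSpan}) with its sequence. A stretch of flanking sequence
#' (\code{sequence}, starting at \code{seqStart}) provides the context in
#' which deletions are applied.
#'
#' @slot loopSpan integer(2), inclusive interval for loop-length accounting.
#' @slot rebuildSpan integer(2), inclusive interval of modelled residues.
#' @slot scanSpan integer(2), inclusive interval eligible for deletion.
#' @slot scanSequence character, sequence of \code{scanSpan}.
#' @slot sequence character, context sequence containing the loop.
#' @slot seqStart integer, full-length number of \code{sequence}'s first
#'   residue.
#' @seealso [fviiaLoopDefinition()], [enumerateDeletions()]
#' @export
setClass("LoopDefinition",
         representation(loopSpan = "integer", rebuildSpan = "integer",
                        scanSpan = "integer", scanSequence = "character",
                        sequence = "character", seqStart = "integer"))

setValidity("LoopDefinition", function(object) {
  msg <- character()
  spans <- list(loopSpan = object@loopSpan, rebuildSpan = object@rebuildSpan,
                scanSpan = object@scanSpan)
  for (nm in names(spans)) {
    s <- spans[[nm]]
    if (length(s) != 2 || any(is.na(s)) || s[1] > s[2])
      msg <- c(msg, sprintf("%s must be an ordered integer pair", nm))
  }
  if (!length(msg)) {
    seqEnd <- object@seqStart + nchar(object@sequence) - 1L
    if (object@scanSpan[1] < object@rebuildSpan[1] ||
        object@scanSpan[2] > object@rebuildSpan[2])
      msg <- c(msg, "scanSpan must lie inside rebuildSpan")
    if (object@rebuildSpan[1] < object@seqStart ||
        object@rebuildSpan[2] > seqEnd)
      msg <- c(msg, "rebuildSpan must lie inside the context sequence")
    want <- diff(object@scanSpan) + 1L
    if (nchar(object@scanSequence) != want)
      msg <- c(msg, "scanSequence length must equal the scanSpan width")
    got <- substr(object@sequence, object@scanSpan[1] - object@seqStart + 1L,
                  object@scanSpan[2] - object@seqStart + 1L)
    if (!identical(got, object@scanSequence))
      msg <- c(msg, "scanSequence does not match the context sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Sliding-window deletion variant library
#'
#' Ordered library of deletion variants over a loop's scan region: one
#' variant per (window size, start position), ordered by ascending window
#' size then ascending start, indexed 1-based. This canonical ordering is
#' the one used to refer to variants by number.
#'
#' @slot loopDef [LoopDefinition-class] the library was enumerated from.
#' @slot sizes integer vector of window sizes.
#' @slot variants data.frame with columns \code{index}, \code{size},
#'   \code{start}, \code{end}, \code{deleted_sequence}, \code{loop_length},
#'   \code{variant_sequence}.
#' @slot removed data.frame of variants dropped by [dedupeIdentical()]
#'   (empty until deduplication is requested).
#' @seealso [enumerateDeletions()], [variantIndex()]
#' @export
setClass("VariantLibrary",
         representation(loopDef = "LoopDefinition", sizes = "integer",
                        variants = "data.frame", removed = "data.frame"))

setValidity("VariantLibrary", function(object) {
  v <- object@variants
  msg <- character()
  need <- c("index", "size", "start", "end", "deleted_sequence",
            "loop_length", "variant_sequence")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variants must have columns:",
                        paste(need, collapse = ", ")))
  else if (nrow(v)) {
    if (!identical(as.integer(v$index), seq_len(nrow(v))))
      msg <- c(msg, "variant indices must be consecutive from 1")
    if (!identical(order(v$size, v$start), seq_len(nrow(v))))
      msg <- c(msg, "variants must be ordered by ascending size then start")
    loopLen <- diff(object@loopDef@loopSpan) + 1L
    if (!all(v$loop_length + v$size == loopLen))
      msg <- c(msg, "loop_length + window size must equal the loop span width")
    scan <- object@loopDef@scanSpan
    if (any(v$start < scan[1]) || any(v$end > scan[2]))
      msg <- c(msg, "every window must lie inside the scan span")
  }
  if (length(msg)) msg else TRUE
})

#' Loop-conformer ensemble with per-pose scores
#'
#' N conformations (poses) of the same molecule sharing one atom table, as
#' produced by ensemble loop-modelling protocols. Coordinates are stored as
#' an N x (3 * natoms) matrix (one row per pose, bio3d trajectory layout),
#' with per-pose scores in Rosetta Energy Units and pose tags used to key
#' external score tables.
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{elety},
#'   \code{resid}, \code{chain}, \code{resno} shared by all poses.
#' @slot xyz numeric matrix, one row per pose, \code{3 * nrow(atoms)}
#'   columns in x,y,z triplets.
#' @slot scores numeric, one score per pose (REU).
#' @slot tags character, one tag per pose.
#' @slot rebuildSpan integer(2), residue interval that was rebuilt (the
#'   default analysis selection), or NA if unknown.
#' @slot metadata list, free-form provenance (synthetic ground truth,
#'   seeds, warnings).
#' @seealso [readEnsemble()], [sampleLoopEnsemble()]
#' @export
setClass("ConformerEnsemble",
         representation(atoms = "data.frame", xyz = "matrix",
                        scores = "numeric", tags = "character",
                        rebuildSpan = "integer", metadata = "list"))

setValidity("ConformerEnsemble", function(object) {
  msg <- character()
  need <- c("eleno", "elety", "resid", "chain", "resno")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (ncol(object@xyz) != 3L * nrow(object@atoms))
    msg <- c(msg, "xyz must have 3 columns per atom")
  if (nrow(object@xyz) != length(object@scores))
    msg <- c(msg, "one score per pose required")
  if (nrow(object@xyz) != length(object@tags))
    msg <- c(msg, "one tag per pose required")
  if (anyDuplicated(object@tags))
    msg <- c(msg, "pose tags must be unique")
  if (any(!is.finite(object@xyz)))
    msg <- c(msg, "coordinates must be finite")
  key <- with(object@atoms, paste(chain, resno, elety))
  if (anyDuplicated(key))
    msg <- c(msg, paste("duplicate atom key:", key[anyDuplicated(key)]))
  if (length(msg)) msg else TRUE
})
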