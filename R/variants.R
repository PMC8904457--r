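#' Construct a loop definition
#'
#' @param loopSpan integer(2), inclusive residue interval used for
#'   loop-length accounting.
#' @param rebuildSpan integer(2), inclusive interval of modelled residues.
#' @param scanSpan integer(2), inclusive interval eligible for deletion.
#' @param sequence context sequence containing the loop.
#' @param seqStart full-length residue number of \code{sequence}'s first
#'   residue.
#' @return A [LoopDefinition-class].
#' @export
LoopDefinition <- function(loopSpan, rebuildSpan, scanSpan, sequence,
                           seqStart) {
  sequence <- as.vector(as.character(sequence))
  scanSequence <- substr(sequence, scanSpan[1] - seqStart + 1L,
                         scanSpan[2] - seqStart + 1L)
  new("LoopDefinition", loopSpan = as.integer(loopSpan),
      rebuildSpan = as.integer(rebuildSpan), scanSpan = as.integer(scanSpan),
      scanSequence = scanSequence, sequence = as.character(sequence),
      seqStart = as.integer(seqStart))
}

#' Packaged FVIIa 170-loop definition
#'
#' The deletion-scan fixture for the 170 loop of coagulation factor VIIa:
#' a 14-residue loop spanning 308-321 in full-length numbering, a rebuild
#' span of 311-321 (chymotrypsin 169-170I) and a scan span of 313-321
#' (170A-170I, sequence QSRKVGDSP), in the 306-374 context of
#' [fviiaRegionSequence()].
#'
#' @return A [LoopDefinition-class].
#' @examples
#' fviiaLoopDefinition()
#' @export
fviiaLoopDefinition <- function() {
  s <- fviiaRegionSequence()
  LoopDefinition(loopSpan = c(308L, 321L), rebuildSpan = c(311L, 321L),
                 scanSpan = c(313L, 321L), sequence = s,
                 seqStart = attr(s, "start"))
}

setMethod("show", "LoopDefinition", function(object) {
  cat(sprintf("LoopDefinition: loop %d-%d (%d aa), rebuild %d-%d, scan %d-%d [%s]\n",
              object@loopSpan[1], object@loopSpan[2],
              diff(object@loopSpan) + 1L,
              object@rebuildSpan[1], object@rebuildSpan[2],
              object@scanSpan[1], object@scanSpan[2], object@scanSequence))
})

#' Enumerate a sliding-window deletion library
#'
#' Generates one deletion variant per (window size, start position) with
#' every window lying inside the loop's scan span, in the canonical order
#' ascending window size then ascending start (N to C), indexed from 1.
#' With the packaged FVIIa fixture and the default sizes 1-6 this yields
#' the 39-variant library; sizes up to the scan-span width are accepted.
#'
#' @param loopDef A [LoopDefinition-class].
#' @param sizes integer vector of deletion-window sizes (default
#'   \code{1:6}).
#' @return A [VariantLibrary-class].
#' @examples
#' lib <- enumerateDeletions(fviiaLoopDefinition())
#' length(lib)                      # 39
#' variantIndex(lib, start = 315, size = 2)
#' @export
enumerateDeletions <- function(loopDef, sizes = 1:6) {
  stopifnot(is(loopDef, "LoopDefinition"))
  sizes <- sort(unique(as.integer(sizes)))
  scan <- loopDef@scanSpan
  scanLen <- diff(scan) + 1L
  if (any(sizes < 1L))
    stop("window sizes must be >= 1")
  if (any(sizes > scanLen))
    stop("window size ", max(sizes), " exceeds the scan span (",
         scanLen, " residues)")
  loopLen <- diff(loopDef@loopSpan) + 1L
  rows <- do.call(rbind, lapply(sizes, function(k) {
    starts <- scan[1]:(scan[2] - k + 1L)
    data.frame(size = k, start = starts, end = starts + k - 1L)
  }))
  rows$index <- seq_len(nrow(rows))
  rows$deleted_sequence <- substr(rep(loopDef@scanSequence, nrow(rows)),
                                  rows$start - scan[1] + 1L,
                                  rows$end - scan[1] + 1L)
  rows$loop_length <- loopLen - rows$size
  rows$variant_sequence <- vapply(seq_len(nrow(rows)), function(i)
    applyDeletion(loopDef@sequence, rows$start[i], rows$size[i],
                  seqStart = loopDef@seqStart), character(1))
  v <- rows[, c("index", "size", "start", "end", "deleted_sequence",
                "loop_length", "variant_sequence")]
  new("VariantLibrary", loopDef = loopDef, sizes = sizes, variants = v,
      removed = v[0, ])
}

#' Excise a deletion window from a sequence
#'
#' @param sequence character scalar; the context sequence.
#' @param start full-length residue number of the window's first residue.
#' @param size window size (>= 1).
#' @param seqStart full-length number of \code{sequence}'s first residue.
#' @return The sequence with the window removed.
#' @examples
#' applyDeletion("LQQSRKVGDSP", start = 313, size = 6, seqStart = 311)
#' @export
applyDeletion <- function(sequence, start, size, seqStart = 1L) {
  size <- as.integer(size)
  if (size < 1L) stop("window size must be >= 1")
  i <- as.integer(start) - as.integer(seqStart) + 1L
  j <- i + size - 1L
  if (i < 1L || j > nchar(sequence))
    stop("deletion window ", start, "..", start + size - 1L,
         " lies outside the sequence")
  paste0(substr(sequence, 1L, i - 1L),
         substr(sequence, j + 1L, nchar(sequence)))
}

#' Accessors for VariantLibrary
#'
#' \code{variants} returns the ordered variant table; \code{length} the
#' number of variants.
#'
#' @param object,x A [VariantLibrary-class].
#' @return \code{variants}: data.frame with one row per deletion variant.
#' @rdname VariantLibrary-accessors
#' @export
setMethod("variants", "VariantLibrary", function(object) object@variants)

#' @rdname VariantLibrary-accessors
#' @export
setMethod("length", "VariantLibrary", function(x) nrow(x@variants))

setMethod("show", "VariantLibrary", function(object) {
  cat(sprintf("VariantLibrary: %d deletion variants, window sizes {%s}, scan %d-%d\n",
              nrow(object@variants),
              paste(object@sizes, collapse = ","),
              object@loopDef@scanSpan[1], object@loopDef@scanSpan[2]))
  if (nrow(object@removed))
    cat(sprintf("  (%d duplicate variant(s) removed)\n", nrow(object@removed)))
})

#' Canonical index of a deletion window
#'
#' Returns the 1-based position of the window under the canonical ordering
#' (ascending size, then ascending start), i.e. the variant number used to
#' refer to library members.
#'
#' @param library A [VariantLibrary-class].
#' @param start window start (full-length numbering).
#' @param size window size.
#' @return Integer index.
#' @rdname variantIndex
#' @export
setMethod("variantIndex", "VariantLibrary", function(library, start, size) {
  v <- library@variants
  i <- which(v$start == as.integer(start) & v$size == as.integer(size))
  if (!length(i))
    stop("no variant with window start ", start, ", size ", size,
         " in the library")
  v$index[i]
})

#' Remove variants with identical mutated sequences
#'
#' In repeat-containing loops different deletion windows can yield the same
#' mutated sequence; this keeps the first occurrence of each sequence
#' (canonical order preserved, indices re-assigned consecutively) and
#' records the removed variants in the \code{removed} slot.
#'
#' @param library A [VariantLibrary-class].
#' @return A deduplicated [VariantLibrary-class].
#' @rdname dedupeIdentical
#' @export
setMethod("dedupeIdentical", "VariantLibrary", function(library) {
  v <- library@variants
  dup <- duplicated(v$variant_sequence)
  removed <- v[dup, ]
  kept <- v[!dup, ]
  if (nrow(kept)) kept$index <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  initialize(library, variants = kept,
             removed = rbind(library@removed, removed))
})

#' Write variant library outputs
#'
#' Writes \code{variants.fasta} (mutated context sequences, headers carrying
#' index, window, deleted sequence and, when a numbering map is given, the
#' chymotrypsin labels of the window) and \code{variants.tsv} (columns
#' index, size, start, end, deleted_sequence, loop_length) into \code{dir}.
#'
#' @param library A [VariantLibrary-class].
#' @param dir output directory (created if absent).
#' @param map optional [NumberingMap-class] for chymotrypsin window labels.
#' @return Invisibly, the paths written.
#' @rdname writeVariantOutputs
#' @export
setMethod("writeVariantOutputs", "VariantLibrary",
          function(library, dir, map = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- library@variants
  hdr <- sprintf("variant_%02d|size=%d|start=%d|end=%d|del=%s|looplen=%d",
                 v$index, v$size, v$start, v$end, v$deleted_sequence,
                 v$loop_length)
  if (!is.null(map))
    hdr <- paste0(hdr, sprintf("|chym=%s-%s", toChymotrypsin(map, v$start),
                               toChymotrypsin(map, v$end)))
  seqs <- Biostrings::AAStringSet(setNames(v$variant_sequence, hdr))
  fastaPath <- file.path(dir, "variants.fasta")
  Biostrings::writeXStringSet(seqs, fastaPath)
  tsvPath <- file.path(dir, "variants.tsv")
  write.table(v[, c("index", "size", "start", "end", "deleted_sequence",
                    "loop_length")],
              tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fastaPath, tsv = tsvPath))
})

#' Read a variant table written by writeVariantOutputs
#'
#' @param path path to a \code{variants.tsv}.
#' @return data.frame with the table's fixed column order.
#' @export
readVariantTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("integer", "integer", "integer", "integer",
                            "character", "integer"))
}
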