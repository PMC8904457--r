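#' Construct a residue numbering map
#'
#' @param full integer vector of full-length residue numbers.
#' @param chym character vector of chymotrypsin labels (e.g. \code{"170A"}).
#' @param aa character vector of 1-letter amino-acid codes.
#' @return A [NumberingMap-class].
#' @examples
#' m <- NumberingMap(311:313, c("169", "170", "170A"), c("L", "Q", "Q"))
#' toChymotrypsin(m, 313)
#' @export
NumberingMap <- function(full, chym, aa) {
  new("NumberingMap",
      entries = data.frame(full = as.integer(full),
                           chym = as.character(chym),
                           aa = as.character(aa)))
}

#' Packaged FVII numbering fixture
#'
#' Numbering map for the 170-loop region of human coagulation factor VII:
#' full-length residues 306-321 (the TF-helix and 170 loop, chymotrypsin
#' 164-170I) plus the protease-body residues referenced by the loop's
#' interaction statistics (C329\{182\}, Q366\{217\}, G372\{223\},
#' H373\{224\}, F374\{225\}).
#'
#' @return A [NumberingMap-class].
#' @examples
#' toChymotrypsin(fviiaNumberingMap(), c(313, 321, 372))
#' @export
fviiaNumberingMap <- function() {
  region <- fviiaRegionSequence()
  full <- c(306:321, 329L, 366L, 372L, 373L, 374L)
  chym <- c(as.character(164:170), paste0("170", LETTERS[1:9]),
            "182", "217", "223", "224", "225")
  aa <- substring(region, full - 305L, full - 305L)
  NumberingMap(full, chym, aa)
}

#' FVII context sequence for the packaged loop fixture
#'
#' Residues 306-374 of mature human factor VII, covering the TF-binding
#' helix, the 170 loop, and the protease-body stretch through F374.
#'
#' @return Character scalar; the full-length number of the first residue is
#'   attached as attribute \code{start}.
#' @export
fviiaRegionSequence <- function() {
  structure(paste0("MTQDCLQQSRKVGDSP", "NITEYMFCAGYSDGSKDSCK",
                   "GDSGGPHATHYRGTWYLTGIVSWGQGCATVGHF"),
            start = 306L)
}

#' Translate between full-length and chymotrypsin numbering
#'
#' \code{toChymotrypsin} maps full-length residue numbers to chymotrypsin
#' labels; \code{fromChymotrypsin} is its inverse. Both are vectorised and
#' error on residues absent from the map, naming the offender.
#'
#' @param map A [NumberingMap-class].
#' @param full integer vector of full-length residue numbers.
#' @param label character vector of chymotrypsin labels.
#' @return Character labels, respectively integer residue numbers.
#' @examples
#' m <- fviiaNumberingMap()
#' toChymotrypsin(m, 313)        # "170A"
#' fromChymotrypsin(m, "223")    # 372
#' @rdname toChymotrypsin
#' @export
setMethod("toChymotrypsin", "NumberingMap", function(map, full) {
  full <- as.integer(full)
  i <- match(full, map@entries$full)
  if (anyNA(i))
    stop("residue number(s) not in map: ",
         paste(full[is.na(i)], collapse = ", "))
  map@entries$chym[i]
})

#' @rdname toChymotrypsin
#' @export
setMethod("fromChymotrypsin", "NumberingMap", function(map, label) {
  i <- match(as.character(label), map@entries$chym)
  if (anyNA(i))
    stop("chymotrypsin label(s) not in map: ",
         paste(label[is.na(i)], collapse = ", "))
  map@entries$full[i]
})

setMethod("show", "NumberingMap", function(object) {
  e <- object@entries
  cat(sprintf("NumberingMap with %d residues (%d..%d)\n",
              nrow(e), min(e$full), max(e$full)))
  cat("  e.g.", paste(sprintf("%d{%s:%s}", head(e$full, 4),
                              head(e$chym, 4), head(e$aa, 4)),
                      collapse = " "), "\n")
})
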