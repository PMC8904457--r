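#' @rdname toChymotrypsin
#' @export
setGeneric("toChymotrypsin", function(map, full) standardGeneric("toChymotrypsin"))

#' @rdname toChymotrypsin
#' @export
setGeneric("fromChymotrypsin", function(map, label) standardGeneric("fromChymotrypsin"))

#' @rdname VariantLibrary-accessors
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))

#' @rdname variantIndex
#' @export
setGeneric("variantIndex", function(library, start, size) standardGeneric("variantIndex"))

#' @rdname dedupeIdentical
#' @export
setGeneric("dedupeIdentical", function(library) standardGeneric("dedupeIdentical"))

#' @rdname writeVariantOutputs
#' @export
setGeneric("writeVariantOutputs",
           function(library, dir, map = NULL) standardGeneric("writeVariantOutputs"))

#' @rdname ConformerEnsemble-accessors
#' @export
setGeneric("nPoses", function(object) standardGeneric("nPoses"))

#' @rdname ConformerEnsemble-accessors
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' @rdname ConformerEnsemble-accessors
#' @export
setGeneric("poseScores", function(object) standardGeneric("poseScores"))

#' @rdname ConformerEnsemble-accessors
#' @export
setGeneric("poseTags", function(object) standardGeneric("poseTags"))

#' @rdname ConformerEnsemble-accessors
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname ConformerEnsemble-accessors
#' @export
setGeneric("poseCoords", function(object, pose) standardGeneric("poseCoords"))
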