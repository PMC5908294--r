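#' @rdname PdbStructure-accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname PdbStructure-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname PdbStructure-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname PdbStructure-accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname PdbStructure-accessors
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))

#' @rdname PdbStructure-accessors
#' @export
setGeneric("ligandResidues", function(x) standardGeneric("ligandResidues"))

#' @rdname CDMModel-accessors
#' @export
setGeneric("scoreLowest", function(object) standardGeneric("scoreLowest"))

#' @rdname CDMModel-accessors
#' @export
setGeneric("scoreHighest", function(object) standardGeneric("scoreHighest"))

#' @rdname CDMModel-accessors
#' @export
setGeneric("scoreRange", function(object) standardGeneric("scoreRange"))

#' @rdname CDMModel-accessors
#' @export
setGeneric("trainingIds", function(object) standardGeneric("trainingIds"))

#' @rdname CDMModel-accessors
#' @export
setGeneric("receptorIds", function(object) standardGeneric("receptorIds"))

#' Accessors for PdbStructure objects
#'
#' @param x a [PdbStructure-class] object.
#' @param frame frame (MODEL) index, 1-based.
#' @return `structureId`: the id string; `nFrames`/`nAtoms`: integers;
#'   `atomData`: the per-atom annotation data.frame; `frameCoords`: an
#'   `nAtoms x 3` numeric matrix for one frame; `ligandResidues`: a
#'   data.frame (`chainId`, `resSeq`, `insert`, `resName`) with one row per
#'   hetero (ligand) residue.
#' @name PdbStructure-accessors
NULL

#' Accessors for CDMModel objects
#'
#' @param object a [CDMModel-class] object.
#' @return numeric scalars for `scoreLowest`, `scoreHighest` and
#'   `scoreRange` (= highest - lowest); character vectors for `trainingIds`
#'   and `receptorIds`.
#' @name CDMModel-accessors
NULL

setMethod("structureId", "PdbStructure", function(x) x@id)
setMethod("nFrames", "PdbStructure", function(x) dim(x@coords)[3])
setMethod("nAtoms", "PdbStructure", function(x) nrow(x@atoms))
setMethod("atomData", "PdbStructure", function(x) x@atoms)
setMethod("frameCoords", "PdbStructure", function(x, frame = 1L) {
  frame <- as.integer(frame)
  if (frame < 1L || frame > dim(x@coords)[3])
    stop("frame index ", frame, " out of range 1..", dim(x@coords)[3])
  m <- x@coords[, , frame, drop = FALSE]
  dim(m) <- dim(x@coords)[1:2]
  m
})
setMethod("ligandResidues", "PdbStructure", function(x) {
  a <- x@atoms[x@atoms$het, , drop = FALSE]
  unique(a[, c("chainId", "resSeq", "insert", "resName")])
})

setMethod("scoreLowest", "CDMModel", function(object) object@scoreLowest)
setMethod("scoreHighest", "CDMModel", function(object) object@scoreHighest)
setMethod("scoreRange", "CDMModel",
          function(object) object@scoreHighest - object@scoreLowest)
setMethod("trainingIds", "CDMModel", function(object) object@trainingIds)
setMethod("receptorIds", "CDMModel", function(object) object@receptorIds)
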