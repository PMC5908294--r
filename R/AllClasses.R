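#' @import methods
NULL

#' Multi-frame molecular structure
#'
#' Container for one PDB-derived structure: a fixed atom topology shared by
#' all frames plus an `nAtoms x 3 x nFrames` coordinate array (Angstrom).
#' Frames correspond to MODEL records of a multi-MODEL PDB file (a single
#' frame when no MODEL records are present), so a trajectory saved as a
#' multi-MODEL PDB is represented directly.
#'
#' The `atoms` slot is a data.frame with one row per atom and columns
#' `serial`, `name`, `element`, `altLoc`, `resName`, `chainId`, `resSeq`,
#' `insert` and `het` (logical; `TRUE` for hetero/ligand atoms). Residues are
#' identified by the `(chainId, resSeq, insert)` triple, kept verbatim from
#' the input file (author numbering, no renumbering).
#'
#' @slot id character scalar, structure identifier (e.g. a PDB ID).
#' @slot atoms data.frame of per-atom annotation (see Details).
#' @slot coords numeric array, `nAtoms x 3 x nFrames`, finite, in Angstrom.
#'
#' @seealso [readPdb()], [writePdb()], [frameCoords()], [ligandResidues()]
#' @export
setClass("PdbStructure",
  representation(id = "character", atoms = "data.frame", coords = "array"))

.atomCols <- c("serial", "name", "element", "altLoc", "resName",
               "chainId", "resSeq", "insert", "het")

setValidity("PdbStructure", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id))
    msg <- c(msg, "'id' must be a single non-NA string")
  missing <- setdiff(.atomCols, names(object@atoms))
  if (length(missing))
    msg <- c(msg, paste0("atoms is missing column(s): ",
                         paste(missing, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
  else {
    if (d[1] != nrow(object@atoms))
      msg <- c(msg, "coords first dimension must equal nrow(atoms)")
    if (d[3] < 1L)
      msg <- c(msg, "at least one frame is required")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
  }
  if (!length(missing) && nrow(object@atoms)) {
    key <- paste(object@atoms$chainId, object@atoms$resSeq,
                 object@atoms$insert, sep = "|")
    runs <- rle(key)$values
    if (anyDuplicated(runs))
      msg <- c(msg, "residue keys (chainId, resSeq, insert) must be contiguous and unique")
  }
  if (length(msg)) msg else TRUE
})

#' Binding-pocket conformation
#'
#' An ordered coordinate set for the pocket residues of one complex, with
#' correspondence labels so conformations from different structures can be
#' superposed atom-by-atom. All conformations entering a pairwise RMSD
#' computation must share identical `labels` and `atomMode`.
#'
#' @slot structureId character scalar.
#' @slot labels character vector of correspondence keys, one per row of
#'   `coords` (typically `"chain|resSeq|atomName"`).
#' @slot coords numeric `N x 3` matrix, N >= 3, Angstrom.
#' @slot atomMode one of `"CA_only"`, `"backbone"`, `"heavy"`.
#'
#' @seealso [pocketConformation()], [pairwiseRmsd()]
#' @export
setClass("PocketConformation",
  representation(structureId = "character", labels = "character",
                 coords = "matrix", atomMode = "character"))

setValidity("PocketConformation", function(object) {
  msg <- character()
  if (length(object@structureId) != 1L)
    msg <- c(msg, "'structureId' must be a single string")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be a numeric N x 3 matrix")
  else {
    if (nrow(object@coords) < 3L)
      msg <- c(msg, "a pocket needs at least 3 atoms")
    if (nrow(object@coords) != length(object@labels))
      msg <- c(msg, "length(labels) must equal nrow(coords)")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
  }
  if (!object@atomMode %in% c("CA_only", "backbone", "heavy"))
    msg <- c(msg, "atomMode must be one of 'CA_only', 'backbone', 'heavy'")
  if (length(msg)) msg else TRUE
})

#' Fitted competitive docking model
#'
#' Stores the min-max normalization constants of the competitive docking
#' model: the lowest (most favorable) and highest winning docking scores
#' observed on the training set. The CDM value of a compound with winning
#' score \eqn{s} is \eqn{1 - (s - s_{lowest}) / (s_{highest} - s_{lowest})};
#' compounds with CDM value >= 0 are called binders.
#'
#' @slot scoreLowest numeric scalar, minimum training winning score.
#' @slot scoreHighest numeric scalar, maximum training winning score.
#' @slot trainingIds character vector of training ligand ids.
#' @slot receptorIds character vector of receptor-conformation ids seen in
#'   training.
#'
#' @seealso [fitCDM()], [predict,CDMModel-method], [writeCDMModel()]
#' @export
setClass("CDMModel",
  representation(scoreLowest = "numeric", scoreHighest = "numeric",
                 trainingIds = "character", receptorIds = "character"))

setValidity("CDMModel", function(object) {
  msg <- character()
  if (length(object@scoreLowest) != 1L || !is.finite(object@scoreLowest))
    msg <- c(msg, "'scoreLowest' must be a finite scalar")
  if (length(object@scoreHighest) != 1L || !is.finite(object@scoreHighest))
    msg <- c(msg, "'scoreHighest' must be a finite scalar")
  if (!length(msg) && object@scoreHighest <= object@scoreLowest)
    msg <- c(msg, "degenerate score range: scoreHighest must exceed scoreLowest")
  if (length(msg)) msg else TRUE
})

#' Compact display of CompDock objects
#'
#' @param object a [PdbStructure-class], [PocketConformation-class] or
#'   [CDMModel-class] object.
#' @return called for its side effect; returns `NULL` invisibly.
#' @name show-methods
#' @aliases show,PdbStructure-method show,PocketConformation-method
#'   show,CDMModel-method
#' @export
setMethod("show", "PdbStructure", function(object) {
  nres <- length(rle(paste(object@atoms$chainId, object@atoms$resSeq,
                           object@atoms$insert, sep = "|"))$values)
  lig <- unique(object@atoms$resName[object@atoms$het])
  cat("PdbStructure '", object@id, "': ",
      nrow(object@atoms), " atoms, ", nres, " residues, ",
      dim(object@coords)[3], " frame(s)\n", sep = "")
  if (length(lig))
    cat("  hetero ligand(s): ", paste(lig, collapse = ", "), "\n", sep = "")
})

setMethod("show", "PocketConformation", function(object) {
  cat("PocketConformation '", object@structureId, "': ",
      nrow(object@coords), " atoms (", object@atomMode, ")\n", sep = "")
})

setMethod("show", "CDMModel", function(object) {
  rng <- object@scoreHighest - object@scoreLowest
  cat("CDMModel fitted on", length(object@trainingIds), "winning scores\n")
  cat(sprintf("  CDM = 1 - (score - (%.3f)) / %.3f\n", object@scoreLowest, rng))
  cat(sprintf("  score range: [%.3f, %.3f]\n",
              object@scoreLowest, object@scoreHighest))
  if (length(object@receptorIds))
    cat("  receptor conformations:",
        paste(object@receptorIds, collapse = ", "), "\n")
})
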