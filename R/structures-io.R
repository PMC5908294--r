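.waterNames <- c("HOH", "WAT", "DOD")

# normalize a selection argument into a data.frame(chainId, resSeq, insert)
.asSelection <- function(selection) {
  if (is.data.frame(selection)) {
    sel <- selection
    if (!is.null(sel$chain_id) && is.null(sel$chainId)) sel$chainId <- sel$chain_id
    if (!is.null(sel$res_seq) && is.null(sel$resSeq)) sel$resSeq <- sel$res_seq
    if (is.null(sel$chainId) || is.null(sel$resSeq))
      stop("selection data.frame needs columns chainId/chain_id and resSeq/res_seq")
    if (is.null(sel$insert)) sel$insert <- ""
    sel <- sel[, c("chainId", "resSeq", "insert")]
  } else if (is.list(selection)) {
    if (!length(selection))
      return(data.frame(chainId = character(), resSeq = integer(),
                        insert = character()))
    sel <- do.call(rbind, lapply(selection, function(s)
      data.frame(chainId = as.character(s[[1]]),
                 resSeq = as.integer(s[[2]]),
                 insert = if (length(s) >= 3) as.character(s[[3]]) else "")))
  } else stop("selection must be a data.frame or a list of (chain, resSeq) pairs")
  sel$chainId <- as.character(sel$chainId)
  sel$resSeq <- as.integer(sel$resSeq)
  sel$insert <- as.character(sel$insert)
  sel
}

.resKey <- function(chain, resSeq, insert) paste(chain, resSeq, insert, sep = "|")

# parse one MODEL block with bio3d and return a clean atom table + xyz
.parseBlock <- function(lines, lineNumbers) {
  isCoord <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(isCoord)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed coordinate record at line ", lineNumbers[i],
           ": line too short", call. = FALSE)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("malformed coordinate field at line ", lineNumbers[i],
             " (columns ", fld[1], "-", fld[2], ")", call. = FALSE)
    }
  }
  if (!any(isCoord)) stop("no ATOM/HETATM records found", call. = FALSE)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(lines, "END"), tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  blank <- function(v) ifelse(is.na(v) | v == " ", "", as.character(v))
  at <- data.frame(
    serial = as.integer(a$eleno),
    name = as.character(a$elety),
    element = blank(a$elesy),
    altLoc = blank(a$alt),
    resName = as.character(a$resid),
    chainId = blank(a$chain),
    resSeq = as.integer(a$resno),
    insert = blank(a$insert),
    het = a$type == "HETATM",
    occ = ifelse(is.na(a$o), 1, as.numeric(a$o)),
    stringsAsFactors = FALSE)
  at$x <- a$x; at$y <- a$y; at$z <- a$z
  at
}

# alternate-location resolution: keep highest occupancy, ties prefer 'A'
.resolveAltLoc <- function(at) {
  key <- paste(at$chainId, at$resSeq, at$insert, at$name, sep = "|")
  if (!anyDuplicated(key)) return(at)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- at[idx, ]
    best <- idx[sub$occ == max(sub$occ)]
    if (length(best) > 1L) {
      alt <- at$altLoc[best]
      best <- if ("A" %in% alt) best[alt == "A"][1] else best[order(alt)][1]
    }
    best[1]
  }), use.names = FALSE)
  at[sort(keep), ]
}

#' Read a PDB-format structure
#'
#' Reads single- or multi-MODEL PDB text into a [PdbStructure-class]. Each
#' MODEL becomes one frame; without MODEL records the file yields a single
#' frame. Waters (HOH/WAT/DOD) are always dropped. Alternate locations are
#' resolved by highest occupancy (ties prefer altLoc 'A'). HETATM residues
#' are flagged as hetero ligands unless `ligandNames` overrides the record
#' type, in which case exactly the residues with those 3-letter codes are
#' treated as ligands. Elements missing from columns 77-78 are inferred from
#' the atom name. Residue numbering is kept verbatim (author numbering,
#' insertion codes preserved).
#'
#' @param file path to a PDB file.
#' @param ligandNames optional character vector of ligand residue codes.
#' @param id structure id; defaults to the file name without extension.
#' @return a [PdbStructure-class] object.
#' @examples
#' pdb <- writePdb(generatePeptideChain(3, phi = -57, psi = -47),
#'                 tempfile(fileext = ".pdb"))
#' readPdb(pdb)
#' @export
readPdb <- function(file, ligandNames = NULL, id = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts)) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts) || any(ends < starts))
      stop("unbalanced MODEL/ENDMDL records in ", file)
    blocks <- lapply(seq_along(starts), function(i)
      seq(starts[i] + 1L, ends[i] - 1L))
  } else blocks <- list(seq_along(lines))

  frames <- lapply(blocks, function(idx)
    .resolveAltLoc(.parseBlock(lines[idx], idx)))
  frames <- lapply(frames, function(at)
    at[!(at$resName %in% .waterNames), , drop = FALSE])

  topo <- lapply(frames, function(at)
    paste(at$chainId, at$resSeq, at$insert, at$resName, at$name, sep = "|"))
  for (i in seq_along(topo)[-1])
    if (!identical(topo[[i]], topo[[1]]))
      stop("inconsistent topology across MODEL blocks: MODEL ", i,
           " differs from MODEL 1")

  at <- frames[[1]]
  blankEl <- at$element == ""
  if (any(blankEl))
    at$element[blankEl] <-
      suppressWarnings(bio3d::atom2ele(at$name[blankEl]))
  if (any(is.na(at$element) | at$element == ""))
    stop("could not infer element for atom(s): ",
         paste(unique(at$name[is.na(at$element) | at$element == ""]),
               collapse = ", "))
  if (!is.null(ligandNames)) at$het <- at$resName %in% ligandNames

  coords <- array(NA_real_, dim = c(nrow(at), 3L, length(frames)))
  for (f in seq_along(frames))
    coords[, , f] <- as.matrix(frames[[f]][, c("x", "y", "z")])
  atoms <- at[, .atomCols]
  rownames(atoms) <- NULL
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(file))
  new("PdbStructure", id = id, atoms = atoms, coords = coords)
}

#' Write a structure as PDB
#'
#' Writes all frames of a [PdbStructure-class] to a PDB file (fixed-width
#' records, MODEL/ENDMDL blocks when more than one frame). Coordinates keep
#' the PDB's 3-decimal precision, so write/read round-trips agree to 1e-3 A.
#'
#' @param x a [PdbStructure-class].
#' @param file output path.
#' @return the path written, invisibly.
#' @export
writePdb <- function(x, file) {
  stopifnot(is(x, "PdbStructure"))
  a <- x@atoms
  nf <- nFrames(x)
  xyz <- matrix(NA_real_, nf, 3L * nrow(a))
  for (f in seq_len(nf)) xyz[f, ] <- as.vector(t(frameCoords(x, f)))
  if (nf == 1L) xyz <- xyz[1, ]
  blankNA <- function(v) ifelse(v == "", NA, v)
  suppressWarnings(bio3d::write.pdb(
    file = file, xyz = xyz,
    type = ifelse(a$het, "HETATM", "ATOM"),
    eleno = a$serial, elety = a$name, resid = a$resName,
    chain = blankNA(a$chainId), resno = a$resSeq,
    insert = blankNA(a$insert),
    o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element))
  if (nf > 1L && any(a$het)) {
    # bio3d's multi-model writer emits ATOM for every record; restore the
    # HETATM cards so ligand flags survive a round-trip
    lines <- readLines(file, warn = FALSE)
    hetSerial <- a$serial[a$het]
    isAtom <- grepl("^ATOM  ", lines)
    serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
    fix <- isAtom & !is.na(serial) & serial %in% hetSerial
    lines[fix] <- sub("^ATOM  ", "HETATM", lines[fix])
    writeLines(lines, file)
  }
  invisible(file)
}

#' Select residues from a frame
#'
#' Returns the atoms of the requested residues, in selection order, with the
#' coordinates of one frame attached. All selection keys must exist.
#'
#' @param x a [PdbStructure-class].
#' @param selection data.frame with columns `chainId`/`chain_id` and
#'   `resSeq`/`res_seq` (optional `insert`), or a list of
#'   `c(chain, resSeq)` pairs.
#' @param frame frame index (default 1).
#' @return data.frame of atoms (annotation plus `x`, `y`, `z`) with a
#'   `selIndex` column giving each atom's position in the selection.
#' @export
selectResidues <- function(x, selection, frame = 1L) {
  stopifnot(is(x, "PdbStructure"))
  sel <- .asSelection(selection)
  a <- x@atoms
  xyz <- frameCoords(x, frame)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  if (!nrow(sel)) return(cbind(a[0, ], selIndex = integer()))
  akey <- .resKey(a$chainId, a$resSeq, a$insert)
  skey <- .resKey(sel$chainId, sel$resSeq, sel$insert)
  missing <- setdiff(skey, akey)
  if (length(missing))
    stop("residue(s) not found in structure '", x@id, "': ",
         paste(gsub("\\|", ":", missing), collapse = ", "))
  out <- do.call(rbind, lapply(seq_along(skey), function(i) {
    sub <- a[akey == skey[i], , drop = FALSE]
    sub$selIndex <- i
    sub
  }))
  rownames(out) <- NULL
  out
}

#' Backbone phi/psi dihedrals of a chain
#'
#' Computes per-residue backbone dihedral angles from N, CA and C atoms.
#' `phi` is undefined (NA) for the first residue and `psi` for the last;
#' residues missing a required backbone atom get NA for the affected angles
#' rather than raising an error. Angles are in degrees in (-180, 180].
#'
#' @param x a [PdbStructure-class].
#' @param chainId chain identifier.
#' @param frame frame index (default 1).
#' @return data.frame with columns `chainId`, `resSeq`, `insert`, `resName`,
#'   `phi`, `psi`.
#' @export
backboneDihedrals <- function(x, chainId, frame = 1L) {
  stopifnot(is(x, "PdbStructure"))
  a <- x@atoms
  xyz <- frameCoords(x, frame)
  inChain <- !a$het & a$chainId == chainId
  if (!any(inChain)) stop("no polymer atoms found in chain '", chainId, "'")
  key <- .resKey(a$chainId, a$resSeq, a$insert)[inChain]
  resKeys <- rle(key)$values
  idx <- which(inChain)
  getAtom <- function(k, name) {
    i <- idx[key == k & a$name[idx] == name]
    if (length(i)) xyz[i[1], ] else NULL
  }
  tors <- function(p1, p2, p3, p4) {
    if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4))
      return(NA_real_)
    ang <- suppressWarnings(
      bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4))[1]
    # map -180 to +180 so results live in (-180, 180]
    if (!is.na(ang) && ang <= -180) ang <- ang + 360
    ang
  }
  nres <- length(resKeys)
  phi <- psi <- rep(NA_real_, nres)
  N <- lapply(resKeys, getAtom, "N")
  CA <- lapply(resKeys, getAtom, "CA")
  C <- lapply(resKeys, getAtom, "C")
  for (i in seq_len(nres)) {
    if (i > 1L) phi[i] <- tors(C[[i - 1L]], N[[i]], CA[[i]], C[[i]])
    if (i < nres) psi[i] <- tors(N[[i]], CA[[i]], C[[i]], N[[i + 1L]])
  }
  first <- match(resKeys, key)
  data.frame(chainId = chainId,
             resSeq = a$resSeq[idx][first],
             insert = a$insert[idx][first],
             resName = a$resName[idx][first],
             phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

# internal constructor used by generators
.newStructure <- function(id, atoms, coordsList) {
  coords <- array(NA_real_, dim = c(nrow(atoms), 3L, length(coordsList)))
  for (f in seq_along(coordsList)) coords[, , f] <- coordsList[[f]]
  rownames(atoms) <- NULL
  new("PdbStructure", id = id, atoms = atoms[, .atomCols], coords = coords)
}
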