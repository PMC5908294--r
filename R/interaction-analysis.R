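#' Geometric interaction criteria
#'
#' Bundle of distance/angle cutoffs and chemical templates used by the
#' interaction detectors. The defaults follow the conventions of common
#' simulation-interaction-diagram tools: hydrogen bond donor-acceptor
#' distance <= 3.5 A with a D-H...A angle >= 120 degrees when explicit
#' hydrogens are present (distance-only otherwise), apolar carbon-carbon
#' contact <= 4.0 A, aromatic ring centroid-centroid distance <= 5.5 A for
#' pi-pi, and cation-to-ring-centroid distance <= 6.0 A for pi-cation.
#'
#' Aromatic rings of PHE, TYR, TRP (both rings) and HIS are built in. Ligand
#' rings are taken from `ringTemplates[[ligand resName]]` (a list of
#' atom-name vectors) when supplied, otherwise perceived automatically as
#' minimal cycles of the distance-inferred bond graph that are planar to
#' within 0.15 A. Cation sites default to the arginine guanidinium carbon
#' (CZ) and lysine ammonium nitrogen (NZ); ligand cations come from
#' `cationDefinitions[[ligand resName]]`, with a fallback that flags
#' nitrogens bonded to four neighbours (quaternary ammonium).
#'
#' @param hbondDaMax H-bond donor-acceptor distance cutoff (A).
#' @param hbondDhaMinDeg minimum D-H...A angle (degrees).
#' @param hydrophobicCcMax apolar C-C contact cutoff (A).
#' @param pipiCentroidMax ring centroid distance cutoff (A).
#' @param picationMax cation to ring centroid cutoff (A).
#' @param ringTemplates named list: residue/ligand name -> list of aromatic
#'   ring atom-name vectors (merged over the built-in protein rings).
#' @param cationDefinitions named list: residue/ligand name -> atom names
#'   carrying a formal positive charge (merged over ARG/LYS defaults).
#' @return a list of class `InteractionCriteria`.
#' @export
interactionCriteria <- function(hbondDaMax = 3.5, hbondDhaMinDeg = 120,
                                hydrophobicCcMax = 4.0, pipiCentroidMax = 5.5,
                                picationMax = 6.0,
                                ringTemplates = list(),
                                cationDefinitions = list()) {
  stopifnot(hbondDaMax > 0, hydrophobicCcMax > 0, pipiCentroidMax > 0,
            picationMax > 0, hbondDhaMinDeg > 0, hbondDhaMinDeg < 180)
  proteinRings <- list(
    PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
    TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
    TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
               c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
    HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")))
  cations <- list(ARG = "CZ", LYS = "NZ")
  rings <- utils::modifyList(proteinRings, ringTemplates)
  cats <- utils::modifyList(cations, cationDefinitions)
  structure(list(hbondDaMax = hbondDaMax, hbondDhaMinDeg = hbondDhaMinDeg,
                 hydrophobicCcMax = hydrophobicCcMax,
                 pipiCentroidMax = pipiCentroidMax, picationMax = picationMax,
                 ringTemplates = rings, cationDefinitions = cats),
            class = "InteractionCriteria")
}

.covalentRadii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39)

# bonded atom pairs inferred from covalent radii (+0.45 A tolerance)
.inferBonds <- function(xyz, elements) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(), 0, 2))
  r <- .covalentRadii[toupper(elements)]
  r[is.na(r)] <- 0.77
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") + 0.45
  hit <- which(d <= cut & d > 0.4 & upper.tri(d), arr.ind = TRUE)
  unname(hit)
}

.neighbors <- function(bonds, i)
  c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])

.angleDeg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# atoms of one frame, split into protein and the named ligand residue
.frameComplex <- function(x, ligandName, frame) {
  a <- x@atoms
  xyz <- frameCoords(x, frame)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  lig <- a[a$het & a$resName == ligandName, , drop = FALSE]
  if (!nrow(lig))
    stop("ligand '", ligandName, "' not found among hetero residues of '",
         x@id, "'")
  # one ligand copy: first (chain, resSeq, insert) instance
  key <- .resKey(lig$chainId, lig$resSeq, lig$insert)
  lig <- lig[key == key[1], , drop = FALSE]
  list(protein = a[!a$het, , drop = FALSE], ligand = lig)
}

.xyzOf <- function(at) as.matrix(at[, c("x", "y", "z")])

.emptyEvents <- function() {
  data.frame(frame = integer(), chainId = character(), resSeq = integer(),
             resName = character(), type = character(),
             proteinAtom = character(), ligandAtom = character(),
             detail = character(), distance = numeric(),
             stringsAsFactors = FALSE)
}

.event <- function(frame, at, type, proteinAtom, ligandAtom, detail, distance) {
  data.frame(frame = frame, chainId = at$chainId, resSeq = at$resSeq,
             resName = at$resName, type = type, proteinAtom = proteinAtom,
             ligandAtom = ligandAtom, detail = detail, distance = distance,
             stringsAsFactors = FALSE)
}

.hydrophobicResidues <- c("ALA", "VAL", "LEU", "ILE", "PRO", "MET",
                          "PHE", "TRP", "TYR", "CYS")

# carbons with no bonded N/O
.apolarCarbonIdx <- function(at, bonds) {
  idx <- which(toupper(at$element) == "C")
  keep <- vapply(idx, function(i) {
    nb <- .neighbors(bonds, i)
    !any(toupper(at$element[nb]) %in% c("N", "O"))
  }, logical(1))
  idx[keep]
}

#' Detect hydrophobic contacts in one frame
#'
#' Flags a residue when any apolar carbon (a carbon not bonded to N or O,
#' bonds inferred from covalent radii) of a hydrophobic-capable residue
#' (ALA, VAL, LEU, ILE, PRO, MET, PHE, TRP, TYR, CYS) lies within
#' `hydrophobicCcMax` of an apolar ligand carbon. Events are deduplicated to
#' one per residue per frame, keeping the closest pair.
#'
#' @param x a [PdbStructure-class] containing the complex.
#' @param ligandName 3-letter code of the hetero ligand residue.
#' @param criteria an [interactionCriteria()] list.
#' @param frame frame index.
#' @return data.frame of events (`frame`, `chainId`, `resSeq`, `resName`,
#'   `type`, `proteinAtom`, `ligandAtom`, `detail`, `distance`).
#' @export
detectHydrophobic <- function(x, ligandName, criteria = interactionCriteria(),
                              frame = 1L) {
  fc <- .frameComplex(x, ligandName, frame)
  prot <- fc$protein[fc$protein$resName %in% .hydrophobicResidues, ,
                     drop = FALSE]
  if (!nrow(prot)) return(.emptyEvents())
  pBonds <- .inferBonds(.xyzOf(fc$protein), fc$protein$element)
  pApolar <- .apolarCarbonIdx(fc$protein, pBonds)
  pApolar <- pApolar[fc$protein$resName[pApolar] %in% .hydrophobicResidues]
  lBonds <- .inferBonds(.xyzOf(fc$ligand), fc$ligand$element)
  lApolar <- .apolarCarbonIdx(fc$ligand, lBonds)
  if (!length(pApolar) || !length(lApolar)) return(.emptyEvents())
  out <- .emptyEvents()
  lxyz <- .xyzOf(fc$ligand)[lApolar, , drop = FALSE]
  for (i in pApolar) {
    p <- as.numeric(fc$protein[i, c("x", "y", "z")])
    d <- sqrt(.dist2(p, lxyz))
    j <- which.min(d)
    if (d[j] <= criteria$hydrophobicCcMax)
      out <- rbind(out, .event(frame, fc$protein[i, ], "hydrophobic",
                               fc$protein$name[i],
                               fc$ligand$name[lApolar[j]], "", d[j]))
  }
  if (!nrow(out)) return(out)
  # one event per residue: keep the closest contact
  key <- .resKey(out$chainId, out$resSeq, "")
  out <- out[order(out$distance), ]
  out <- out[!duplicated(.resKey(out$chainId, out$resSeq, "")), ]
  rownames(out) <- NULL
  out
}

#' Detect hydrogen bonds in one frame
#'
#' Donor/acceptor typing uses nitrogen and oxygen heavy atoms. When explicit
#' hydrogens are present the geometric criterion is donor-acceptor distance
#' <= `hbondDaMax` (inclusive) and D-H...A angle >= `hbondDhaMinDeg`;
#' without hydrogens a distance-only criterion is used and the result
#' carries attribute `distance_only = TRUE`. Both directions (protein donor
#' and ligand donor) are scanned; backbone and side-chain atoms are both
#' eligible.
#'
#' @inheritParams detectHydrophobic
#' @return event data.frame as in [detectHydrophobic()]; `detail` records
#'   the donor side ("protein_donor"/"ligand_donor"/"distance_only").
#' @export
detectHBonds <- function(x, ligandName, criteria = interactionCriteria(),
                         frame = 1L) {
  fc <- .frameComplex(x, ligandName, frame)
  prot <- fc$protein; lig <- fc$ligand
  pNO <- which(toupper(prot$element) %in% c("N", "O"))
  lNO <- which(toupper(lig$element) %in% c("N", "O"))
  out <- .emptyEvents()
  if (!length(pNO) || !length(lNO)) return(out)
  hasH <- any(toupper(prot$element) == "H") || any(toupper(lig$element) == "H")
  if (!hasH) {
    lxyz <- .xyzOf(lig)[lNO, , drop = FALSE]
    for (i in pNO) {
      p <- as.numeric(prot[i, c("x", "y", "z")])
      d <- sqrt(.dist2(p, lxyz))
      for (j in which(d <= criteria$hbondDaMax))
        out <- rbind(out, .event(frame, prot[i, ], "hbond", prot$name[i],
                                 lig$name[lNO[j]], "distance_only", d[j]))
    }
    attr(out, "distance_only") <- TRUE
    return(out)
  }
  pBonds <- .inferBonds(.xyzOf(prot), prot$element)
  lBonds <- .inferBonds(.xyzOf(lig), lig$element)
  scan <- function(dAt, dBonds, aAt, aIdx, donorSide) {
    res <- .emptyEvents()
    dNO <- which(toupper(dAt$element) %in% c("N", "O"))
    for (i in dNO) {
      hs <- .neighbors(dBonds, i)
      hs <- hs[toupper(dAt$element[hs]) == "H"]
      if (!length(hs)) next
      D <- as.numeric(dAt[i, c("x", "y", "z")])
      for (j in aIdx) {
        A <- as.numeric(aAt[j, c("x", "y", "z")])
        dda <- sqrt(sum((D - A)^2))
        if (dda > criteria$hbondDaMax) next
        angles <- vapply(hs, function(h)
          .angleDeg(D, as.numeric(dAt[h, c("x", "y", "z")]), A), numeric(1))
        if (max(angles) >= criteria$hbondDhaMinDeg) {
          protRow <- if (donorSide == "protein_donor") dAt[i, ] else aAt[j, ]
          pa <- if (donorSide == "protein_donor") dAt$name[i] else aAt$name[j]
          la <- if (donorSide == "protein_donor") aAt$name[j] else dAt$name[i]
          res <- rbind(res, .event(frame, protRow, "hbond", pa, la,
                                   donorSide, dda))
        }
      }
    }
    res
  }
  out <- rbind(scan(prot, pBonds, lig, lNO, "protein_donor"),
               scan(lig, lBonds, prot, pNO, "ligand_donor"))
  rownames(out) <- NULL
  out
}

# ring atom index sets for a residue, from templates; <3 resolved -> skip
.templateRings <- function(at, templates) {
  tpl <- templates[[at$resName[1]]]
  if (is.null(tpl)) return(list())
  rings <- list()
  for (ringNames in tpl) {
    idx <- match(ringNames, at$name)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 3L) {
      warning("ring of ", at$resName[1], " ", at$resSeq[1],
              " has fewer than 3 resolved atoms; skipped")
      next
    }
    rings[[length(rings) + 1L]] <- idx
  }
  rings
}

# minimal-cycle ring perception on the bond graph; keeps 5/6-cycles planar
# to within maxDev (max out-of-plane deviation, A)
.perceiveRings <- function(xyz, elements, maxDev = 0.15) {
  bonds <- .inferBonds(xyz, elements)
  if (nrow(bonds) < 3L) return(list())
  g <- igraph::graph_from_edgelist(apply(bonds, 2, as.character),
                                   directed = FALSE)
  rings <- list()
  seen <- character()
  for (e in seq_len(nrow(bonds))) {
    u <- as.character(bonds[e, 1]); v <- as.character(bonds[e, 2])
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, u, v)$vpath[[1]])
    if (!length(sp)) next
    cyc <- as.integer(igraph::V(g)$name[as.integer(sp)])
    if (length(cyc) < 5L || length(cyc) > 6L) next
    key <- paste(sort(cyc), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    ring <- xyz[cyc, , drop = FALSE]
    centered <- sweep(ring, 2, colMeans(ring))
    normal <- svd(centered)$v[, 3]
    if (max(abs(centered %*% normal)) <= maxDev)
      rings[[length(rings) + 1L]] <- cyc
  }
  rings
}

.ringGeom <- function(xyz) {
  ctr <- colMeans(xyz)
  normal <- svd(sweep(xyz, 2, ctr))$v[, 3]
  list(centroid = ctr, normal = normal / sqrt(sum(normal^2)))
}

# rings of all aromatic protein residues: list of (residueRow, geom)
.proteinRingList <- function(prot, templates) {
  key <- .resKey(prot$chainId, prot$resSeq, prot$insert)
  out <- list()
  for (k in unique(key[prot$resName %in% names(templates)])) {
    at <- prot[key == k, , drop = FALSE]
    for (idx in .templateRings(at, templates)) {
      out[[length(out) + 1L]] <-
        list(res = at[1, ], geom = .ringGeom(.xyzOf(at)[idx, , drop = FALSE]),
             atoms = at$name[idx])
    }
  }
  out
}

# ligand rings as index lists (template preferred, else perception)
.ligandRings <- function(lig, templates) {
  tpl <- templates[[lig$resName[1]]]
  if (!is.null(tpl)) {
    idxs <- lapply(tpl, function(names) {
      idx <- match(names, lig$name)
      idx[!is.na(idx)]
    })
    idxs <- Filter(function(i) length(i) >= 3L, idxs)
    if (length(idxs)) return(idxs)
  }
  .perceiveRings(.xyzOf(lig), lig$element)
}

#' Detect pi-pi stacking in one frame
#'
#' An event is recorded when the centroid of an aromatic protein ring (PHE,
#' TYR, both TRP rings, HIS, or user templates) lies within
#' `pipiCentroidMax` of a ligand ring centroid. Ring planes are fitted by
#' SVD; `detail` annotates the geometry as `face_to_face` (inter-normal
#' angle <= 30 deg), `edge_to_face` (>= 60 deg) or `intermediate`.
#'
#' @inheritParams detectHydrophobic
#' @return event data.frame as in [detectHydrophobic()].
#' @export
detectPiPi <- function(x, ligandName, criteria = interactionCriteria(),
                       frame = 1L) {
  fc <- .frameComplex(x, ligandName, frame)
  pRings <- .proteinRingList(fc$protein, criteria$ringTemplates)
  lIdx <- .ligandRings(fc$ligand, criteria$ringTemplates)
  out <- .emptyEvents()
  if (!length(pRings) || !length(lIdx)) return(out)
  lGeoms <- lapply(lIdx, function(i)
    .ringGeom(.xyzOf(fc$ligand)[i, , drop = FALSE]))
  for (pr in pRings) for (li in seq_along(lGeoms)) {
    lg <- lGeoms[[li]]
    d <- sqrt(sum((pr$geom$centroid - lg$centroid)^2))
    if (d > criteria$pipiCentroidMax) next
    ang <- acos(pmin(1, abs(sum(pr$geom$normal * lg$normal)))) * 180 / pi
    detail <- if (ang <= 30) "face_to_face"
              else if (ang >= 60) "edge_to_face" else "intermediate"
    out <- rbind(out, .event(frame, pr$res, "pi_pi", pr$atoms[1],
                             paste0("ring", li), detail, d))
  }
  rownames(out) <- NULL
  out
}

# ligand cation sites: template atom names, else quaternary nitrogens
.ligandCations <- function(lig, cationDefinitions) {
  tpl <- cationDefinitions[[lig$resName[1]]]
  if (!is.null(tpl)) {
    idx <- match(tpl, lig$name)
    return(idx[!is.na(idx)])
  }
  bonds <- .inferBonds(.xyzOf(lig), lig$element)
  nIdx <- which(toupper(lig$element) == "N")
  nIdx[vapply(nIdx, function(i) length(.neighbors(bonds, i)) >= 4L, logical(1))]
}

#' Detect pi-cation interactions in one frame
#'
#' Scans both directions: a ligand cation site (quaternary/charged nitrogen
#' from the `cationDefinitions` template, or a nitrogen with four bonded
#' neighbours) near an aromatic protein ring, and a protein cation site
#' (ARG CZ, LYS NZ by default) near a ligand ring. An event is recorded when
#' the cation lies within `picationMax` of the ring centroid; `detail`
#' records the direction (`protein_ring` or `ligand_ring`).
#'
#' @inheritParams detectHydrophobic
#' @return event data.frame as in [detectHydrophobic()].
#' @export
detectPiCation <- function(x, ligandName, criteria = interactionCriteria(),
                           frame = 1L) {
  fc <- .frameComplex(x, ligandName, frame)
  out <- .emptyEvents()
  # direction 1: protein ring + ligand cation
  pRings <- .proteinRingList(fc$protein, criteria$ringTemplates)
  lCat <- .ligandCations(fc$ligand, criteria$cationDefinitions)
  for (pr in pRings) for (i in lCat) {
    d <- sqrt(sum((pr$geom$centroid -
                     as.numeric(fc$ligand[i, c("x", "y", "z")]))^2))
    if (d <= criteria$picationMax)
      out <- rbind(out, .event(frame, pr$res, "pi_cation", pr$atoms[1],
                               fc$ligand$name[i], "protein_ring", d))
  }
  # direction 2: ligand ring + protein cation
  lIdx <- .ligandRings(fc$ligand, criteria$ringTemplates)
  catDef <- criteria$cationDefinitions
  catRows <- which(fc$protein$resName %in% names(catDef))
  if (length(catRows))
    catRows <- catRows[vapply(catRows, function(i)
      fc$protein$name[i] %in% catDef[[fc$protein$resName[i]]], logical(1))]
  if (length(lIdx) && length(catRows)) {
    lGeoms <- lapply(lIdx, function(i)
      .ringGeom(.xyzOf(fc$ligand)[i, , drop = FALSE]))
    for (i in catRows) for (li in seq_along(lGeoms)) {
      d <- sqrt(sum((lGeoms[[li]]$centroid -
                       as.numeric(fc$protein[i, c("x", "y", "z")]))^2))
      if (d <= criteria$picationMax)
        out <- rbind(out, .event(frame, fc$protein[i, ], "pi_cation",
                                 fc$protein$name[i], paste0("ring", li),
                                 "ligand_ring", d))
    }
  }
  rownames(out) <- NULL
  out
}

#' Interaction fractions over a frame window
#'
#' Runs all four detectors on each frame of the analysis window and reports,
#' per (residue, interaction type), the fraction of window frames in which
#' the interaction is present. The default window is the last 10% of frames
#' (at least one) -- the "last nanosecond" convention for trajectory
#' analysis -- overridable with `lastN`.
#'
#' @inheritParams detectHydrophobic
#' @param lastN number of trailing frames to analyze; `NULL` for the last
#'   10% (ceiling, minimum 1).
#' @return data.frame (`chainId`, `resSeq`, `resName`, `type`, `fraction`,
#'   `n_frames`), sorted by fraction descending.
#' @export
interactionFractions <- function(x, ligandName,
                                 criteria = interactionCriteria(),
                                 lastN = NULL) {
  stopifnot(is(x, "PdbStructure"))
  nf <- nFrames(x)
  if (is.null(lastN)) lastN <- max(1L, ceiling(0.1 * nf))
  lastN <- as.integer(lastN)
  if (lastN < 1L || lastN > nf)
    stop("lastN must be between 1 and the number of frames (", nf, ")")
  window <- seq(nf - lastN + 1L, nf)
  perFrame <- lapply(window, function(f) {
    ev <- rbind(detectHydrophobic(x, ligandName, criteria, f),
                detectHBonds(x, ligandName, criteria, f),
                detectPiPi(x, ligandName, criteria, f),
                detectPiCation(x, ligandName, criteria, f))
    unique(ev[, c("chainId", "resSeq", "resName", "type")])
  })
  all <- do.call(rbind, perFrame)
  if (!nrow(all))
    return(data.frame(chainId = character(), resSeq = integer(),
                      resName = character(), type = character(),
                      fraction = numeric(), n_frames = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(all$chainId, all$resSeq, all$resName, all$type, sep = "|")
  counts <- table(key)
  first <- all[!duplicated(key), ]
  first <- first[match(names(counts), key[!duplicated(key)]), ]
  out <- data.frame(first,
                    fraction = as.numeric(counts) / length(window),
                    n_frames = length(window),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$chainId, out$resSeq, out$type), ]
  rownames(out) <- NULL
  out
}

# per-frame coordinates of the selected atoms, superposed to a reference
.superposedSelection <- function(x, selection, reference = c("mean", "first")) {
  reference <- match.arg(reference)
  a <- x@atoms
  idx <- which(!a$het & a$name %in% selection)
  if (length(idx) < 3L)
    stop("selection matches fewer than 3 atoms; cannot superpose")
  nf <- nFrames(x)
  frames <- lapply(seq_len(nf), function(f) frameCoords(x, f)[idx, , drop = FALSE])
  fitTo <- function(tgt) lapply(frames, function(m) {
    fit <- kabschSuperpose(m, tgt)
    applyTransform(m, fit$rotation, fit$translation)
  })
  fitted <- fitTo(frames[[1L]])
  if (reference == "mean") {
    avg <- Reduce(`+`, fitted) / nf
    fitted <- fitTo(avg)
  }
  list(idx = idx, fitted = fitted, atoms = a[idx, , drop = FALSE])
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom around its mean
#' position, after superposing every frame onto the reference (the mean
#' structure by default, obtained by fitting to frame 1, averaging and
#' re-fitting; or frame 1 with `reference = "first"`). Atom RMSFs are
#' averaged per residue.
#'
#' @param x a [PdbStructure-class] with >= 2 frames.
#' @param selection atom-name set used for both superposition and the
#'   profile (default `"CA"`).
#' @param reference `"mean"` (default) or `"first"`.
#' @return data.frame (`chainId`, `resSeq`, `resName`, `rmsf`) in Angstrom.
#' @export
rmsf <- function(x, selection = "CA", reference = c("mean", "first")) {
  stopifnot(is(x, "PdbStructure"))
  if (nFrames(x) < 2L) stop("RMSF needs at least 2 frames")
  sup <- .superposedSelection(x, selection, reference)
  nf <- length(sup$fitted)
  avg <- Reduce(`+`, sup$fitted) / nf
  dev2 <- Reduce(`+`, lapply(sup$fitted, function(m) rowSums((m - avg)^2))) / nf
  atomRmsf <- sqrt(dev2)
  at <- sup$atoms
  key <- .resKey(at$chainId, at$resSeq, at$insert)
  agg <- tapply(atomRmsf, key, mean)
  first <- at[!duplicated(key), , drop = FALSE]
  data.frame(chainId = first$chainId, resSeq = first$resSeq,
             resName = first$resName,
             rmsf = as.numeric(agg[.resKey(first$chainId, first$resSeq,
                                           first$insert)]),
             stringsAsFactors = FALSE)
}

#' Per-frame RMSD time series
#'
#' RMSD of each frame to a reference frame, computed on an atom-name
#' selection after optimal superposition of that selection.
#'
#' @param x a [PdbStructure-class].
#' @param selection atom-name set (default `"CA"`).
#' @param referenceFrame reference frame index (default 1).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsdTimeseries <- function(x, selection = "CA", referenceFrame = 1L) {
  stopifnot(is(x, "PdbStructure"))
  nf <- nFrames(x)
  referenceFrame <- as.integer(referenceFrame)
  if (referenceFrame < 1L || referenceFrame > nf)
    stop("reference frame index ", referenceFrame, " out of range 1..", nf)
  a <- x@atoms
  idx <- which(!a$het & a$name %in% selection)
  if (length(idx) < 3L)
    stop("selection matches fewer than 3 atoms; cannot superpose")
  ref <- frameCoords(x, referenceFrame)[idx, , drop = FALSE]
  vapply(seq_len(nf), function(f)
    .fitRmsd(frameCoords(x, f)[idx, , drop = FALSE], ref), numeric(1))
}
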