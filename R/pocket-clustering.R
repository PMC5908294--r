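#' Extract a binding-pocket conformation
#'
#' Pulls the pocket residues out of a structure and returns their
#' coordinates with correspondence labels, ready for pairwise superposition.
#' With `atomMode = "CA_only"` (default) only the alpha carbons enter the
#' comparison, which stays well defined across homologous structures whose
#' pocket side chains differ; `"backbone"` uses N/CA/C/O and `"heavy"` all
#' non-hydrogen atoms (appropriate only when the residues are identical).
#'
#' @param x a [PdbStructure-class].
#' @param selection pocket residue selection (see [selectResidues()]).
#' @param atomMode `"CA_only"`, `"backbone"` or `"heavy"`.
#' @param frame frame index.
#' @return a [PocketConformation-class].
#' @export
pocketConformation <- function(x, selection,
                               atomMode = c("CA_only", "backbone", "heavy"),
                               frame = 1L) {
  atomMode <- match.arg(atomMode)
  at <- selectResidues(x, selection, frame)
  keep <- switch(atomMode,
    CA_only = at$name == "CA",
    backbone = at$name %in% c("N", "CA", "C", "O"),
    heavy = toupper(at$element) != "H")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) < 3L)
    stop("pocket of '", x@id, "' has fewer than 3 atoms in mode ", atomMode)
  new("PocketConformation",
      structureId = x@id,
      labels = paste(at$chainId, at$resSeq, at$insert, at$name, sep = "|"),
      coords = as.matrix(at[, c("x", "y", "z")]),
      atomMode = atomMode)
}

#' Pairwise pocket RMSD matrix
#'
#' Computes the symmetric matrix of minimal RMSDs between all pairs of
#' pocket conformations. Every pair is superposed independently with
#' [kabschSuperpose()] before the RMSD is taken (no common reference frame).
#' All conformations must share identical correspondence labels and atom
#' mode.
#'
#' @param pockets list of [PocketConformation-class] objects (>= 2).
#' @return symmetric numeric matrix (Angstrom) with structure ids as
#'   dimnames and a zero diagonal.
#' @export
pairwiseRmsd <- function(pockets) {
  if (length(pockets) < 2L) stop("need at least two pocket conformations")
  ok <- vapply(pockets, function(p) is(p, "PocketConformation"), logical(1))
  if (!all(ok)) stop("all elements must be PocketConformation objects")
  ids <- vapply(pockets, function(p) p@structureId, character(1))
  ref <- pockets[[1]]
  for (p in pockets[-1]) {
    if (!identical(p@labels, ref@labels) || !identical(p@atomMode, ref@atomMode))
      stop("pocket correspondence mismatch between '", ref@structureId,
           "' and '", p@structureId,
           "': labels and atomMode must be identical")
  }
  n <- length(pockets)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    r <- .fitRmsd(pockets[[j]]@coords, pockets[[i]]@coords)
    m[i, j] <- m[j, i] <- r
  }
  m
}

.checkRmsdMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("dissimilarity input must be a square matrix")
  if (any(!is.finite(m)) || any(m < 0))
    stop("dissimilarities must be finite and non-negative")
  if (max(abs(m - t(m))) > 1e-9)
    stop("dissimilarity matrix must be symmetric (tolerance 1e-9)")
  if (is.null(rownames(m)))
    dimnames(m) <- list(paste0("S", seq_len(nrow(m))),
                        paste0("S", seq_len(nrow(m))))
  m
}

#' Ward hierarchical clustering of pocket conformations
#'
#' Agglomerative clustering of an RMSD matrix with Ward's minimum-variance
#' criterion, cut at `k` clusters. The default `"ward.D2"` linkage applies
#' the Lance-Williams update on squared dissimilarities; `"ward.D"`
#' reproduces the legacy behaviour of early `hclust(method = "ward")`
#' releases, offered because published pocket-clustering work used that
#' interface. Ids are sorted lexicographically before clustering so merge
#' tie-breaks are deterministic.
#'
#' @param m symmetric dissimilarity matrix with id dimnames, e.g. from
#'   [pairwiseRmsd()].
#' @param k number of clusters, between 1 and `nrow(m)`.
#' @param linkage `"ward.D2"` (default) or `"ward.D"`.
#' @return list with `assignments` (named integer vector; cluster labels are
#'   renumbered in first-appearance order of the sorted ids), `tree` (the
#'   `hclust` object, merge heights non-decreasing), `k`, and `linkage`.
#' @seealso [clusterNewick()], [selectRepresentatives()]
#' @export
wardCluster <- function(m, k, linkage = c("ward.D2", "ward.D")) {
  linkage <- match.arg(linkage)
  m <- .checkRmsdMatrix(m)
  n <- nrow(m)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  ord <- order(rownames(m))
  m <- m[ord, ord]
  tree <- stats::hclust(stats::as.dist(m), method = linkage)
  assignments <- stats::cutree(tree, k = k)
  list(assignments = assignments, tree = tree, k = k, linkage = linkage)
}

#' Export a clustering dendrogram as Newick
#'
#' Converts the merge tree of a [wardCluster()] result to a Newick string
#' with branch lengths derived from the merge heights.
#'
#' @param clustering result of [wardCluster()].
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
clusterNewick <- function(clustering, file = NULL) {
  phy <- ape::as.phylo(clustering$tree)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Select one representative complex per cluster
#'
#' Applies the template-selection rule: within each cluster pick the member
#' with the highest target sequence identity; break ties by the best
#' (smallest) crystallographic resolution, then by lexicographic id.
#'
#' @param clustering result of [wardCluster()], or a named vector of cluster
#'   assignments.
#' @param metadata data.frame with columns `structure_id`,
#'   `sequence_identity_pct` and `resolution_A` covering every clustered id
#'   (extra rows are ignored; duplicated ids must agree).
#' @return list with `representatives` (cluster label -> structure id) and
#'   `criteria` (data.frame of the chosen rows).
#' @export
selectRepresentatives <- function(clustering, metadata) {
  assignments <- if (is.list(clustering)) clustering$assignments else clustering
  ids <- names(assignments)
  md <- unique(metadata[, c("structure_id", "sequence_identity_pct",
                            "resolution_A")])
  if (anyDuplicated(md$structure_id))
    stop("conflicting metadata rows for: ",
         paste(unique(md$structure_id[duplicated(md$structure_id)]),
               collapse = ", "))
  missing <- setdiff(ids, md$structure_id)
  if (length(missing))
    stop("metadata missing for structure(s): ", paste(missing, collapse = ", "))
  rows <- md[match(ids, md$structure_id), ]
  picks <- lapply(split(seq_along(ids), assignments), function(idx) {
    sub <- rows[idx, ]
    sub <- sub[order(-sub$sequence_identity_pct, sub$resolution_A,
                     sub$structure_id), ]
    sub[1, ]
  })
  chosen <- do.call(rbind, picks)
  chosen$cluster <- names(picks)
  rownames(chosen) <- NULL
  reps <- stats::setNames(chosen$structure_id, chosen$cluster)
  list(representatives = reps, criteria = chosen)
}

#' Read pocket definitions
#'
#' Reads per-structure pocket residue selections from JSON (a named list of
#' records with `chain_id` and `res_seq`) or TSV (columns `structure_id`,
#' `chain_id`, `res_seq`). Correspondence across structures is by row order,
#' so all pockets must list their residues in matched order.
#'
#' @param file path to a `.json` or `.tsv` pocket-definition file.
#' @return named list of data.frames with columns `chainId`, `resSeq`.
#' @export
readPocketDefinitions <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
    out <- lapply(raw, function(df)
      data.frame(chainId = as.character(df$chain_id),
                 resSeq = as.integer(df$res_seq)))
    return(out)
  }
  df <- utils::read.delim(file, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("structure_id", "chain_id", "res_seq")
  if (!all(need %in% names(df)))
    stop("pocket TSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$structure_id)[unique(df$structure_id)], function(s)
    data.frame(chainId = as.character(s$chain_id),
               resSeq = as.integer(s$res_seq)))
}
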