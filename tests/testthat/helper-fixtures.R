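# Hand-rolled PDB text fixtures (fixed-column records built with sprintf so
# the tests do not depend on the package's own writer).

pdbLine <- function(record, serial, name, resName, chain, resSeq, x, y, z,
                    occ = 1, b = 0, element = "", altLoc = " ",
                    insert = " ") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altLoc, resName, chain, resSeq, insert,
          x, y, z, occ, b, element)
}

# two alanine residues (N/CA/C each) plus an optional NCT hetero ligand
twoResidueLines <- function(withLigand = FALSE, shift = 0) {
  l <- c(
    pdbLine("ATOM", 1, "N", "ALA", "A", 1, 0 + shift, 0, 0, element = "N"),
    pdbLine("ATOM", 2, "CA", "ALA", "A", 1, 1.458 + shift, 0, 0, element = "C"),
    pdbLine("ATOM", 3, "C", "ALA", "A", 1, 2.009 + shift, 1.42, 0, element = "C"),
    pdbLine("ATOM", 4, "N", "ALA", "A", 2, 1.329 + shift, 2.5, 0, element = "N"),
    pdbLine("ATOM", 5, "CA", "ALA", "A", 2, 1.88 + shift, 3.92, 0, element = "C"),
    pdbLine("ATOM", 6, "C", "ALA", "A", 2, 3.405 + shift, 3.92, 0, element = "C"))
  if (withLigand)
    l <- c(l,
      pdbLine("HETATM", 7, "C1", "NCT", "B", 900, 8 + shift, 8, 8,
              element = "C"),
      pdbLine("HETATM", 8, "N1", "NCT", "B", 900, 9.2 + shift, 8, 8,
              element = "N"),
      pdbLine("HETATM", 9, "O", "HOH", "B", 901, 20, 20, 20, element = "O"))
  l
}

writePdbText <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# a structure with M static anchor atoms plus one atom alternating +/- d
# along x around its base position, over an even number of frames; the
# mobile atom sits at the anchor centroid so superposition couples to it
# only through the O(1/M) translation term
alternatingAtomStructure <- function(nAnchor = 200L, d = 1.0, nFrames = 10L) {
  t <- seq_len(nAnchor)
  anchors <- cbind(4 * cos(0.8 * t), 4 * sin(0.8 * t), 1.4 * t)
  base <- rbind(anchors, colMeans(anchors))
  atoms <- data.frame(name = "CA", element = "C", resName = "ALA",
                      chainId = "A", resSeq = seq_len(nAnchor + 1L),
                      het = FALSE)
  frames <- lapply(seq_len(nFrames), function(f) {
    m <- base
    m[nAnchor + 1L, 1] <- m[nAnchor + 1L, 1] + d * ifelse(f %% 2 == 0, 1, -1)
    m
  })
  pdbStructure(atoms, frames, id = "alternating")
}
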