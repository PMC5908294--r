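test_that("single- and multi-MODEL PDB text parse into frames with shared topology", {
  f1 <- writePdbText(twoResidueLines())
  s1 <- readPdb(f1)
  expect_s4_class(s1, "PdbStructure")
  expect_equal(nFrames(s1), 1L)
  expect_equal(nAtoms(s1), 6L)
  expect_equal(unique(atomData(s1)$resSeq), c(1L, 2L))

  body <- twoResidueLines()
  f2 <- writePdbText(c("MODEL        1", body, "ENDMDL",
                       "MODEL        2", twoResidueLines(shift = 0.5),
                       "ENDMDL"))
  s2 <- readPdb(f2)
  expect_equal(nFrames(s2), 2L)
  expect_identical(atomData(s2), atomData(s1))
  expect_equal(frameCoords(s2, 2)[, 1], frameCoords(s2, 1)[, 1] + 0.5)
})

test_that("HETATM residues become hetero ligands and waters are dropped", {
  f <- writePdbText(twoResidueLines(withLigand = TRUE))
  s <- readPdb(f)
  lig <- ligandResidues(s)
  expect_equal(lig$resName, "NCT")
  expect_false("HOH" %in% atomData(s)$resName)
  # explicit ligand list overrides the record type
  s2 <- readPdb(f, ligandNames = "ALA")
  expect_true(all(atomData(s2)$het[atomData(s2)$resName == "ALA"]))
  expect_false(any(atomData(s2)$het[atomData(s2)$resName == "NCT"]))
})

test_that("alternate locations keep the highest occupancy, ties prefer A", {
  lines <- c(
    pdbLine("ATOM", 1, "N", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdbLine("ATOM", 2, "CA", "ALA", "A", 1, 1.0, 0, 0, occ = 0.4,
            altLoc = "A", element = "C"),
    pdbLine("ATOM", 3, "CA", "ALA", "A", 1, 2.0, 0, 0, occ = 0.6,
            altLoc = "B", element = "C"),
    pdbLine("ATOM", 4, "C", "ALA", "A", 1, 2.5, 1.0, 0, occ = 0.5,
            altLoc = "A", element = "C"),
    pdbLine("ATOM", 5, "C", "ALA", "A", 1, 3.5, 1.0, 0, occ = 0.5,
            altLoc = "B", element = "C"))
  s <- readPdb(writePdbText(lines))
  a <- atomData(s)
  xyz <- frameCoords(s)
  expect_equal(nrow(a), 3L)
  expect_equal(xyz[a$name == "CA", 1], 2.0)   # occupancy 0.6 wins
  expect_equal(xyz[a$name == "C", 1], 2.5)    # tie -> altLoc A
})

test_that("parse and topology errors are reported with context", {
  bad <- twoResidueLines()
  substr(bad[3], 33, 38) <- "xx.yyy"
  expect_error(readPdb(writePdbText(bad)), "line 3")

  f <- writePdbText(c("MODEL        1", twoResidueLines(), "ENDMDL",
                      "MODEL        2", twoResidueLines()[-2], "ENDMDL"))
  expect_error(readPdb(f), "topology")
})

test_that("elements missing from columns 77-78 are inferred from atom names", {
  lines <- vapply(twoResidueLines(), function(l) substr(l, 1, 76),
                  character(1))
  s <- readPdb(writePdbText(lines))
  expect_equal(atomData(s)$element, c("N", "C", "C", "N", "C", "C"))
})

test_that("write/read round-trip preserves coordinates to PDB precision", {
  set.seed(42)
  ens <- generateInteractionComplex("pi_pi", nFrames = 3, framesWith = 1:2,
                                    seed = 11)
  f <- tempfile(fileext = ".pdb")
  writePdb(ens, f)
  back <- readPdb(f, ligandNames = "LIG")
  expect_equal(nFrames(back), 3L)
  expect_identical(atomData(back)$name, atomData(ens)$name)
  expect_lt(max(abs(back@coords - ens@coords)), 1e-3 + 1e-9)
})

test_that("selectResidues returns residues in selection order and flags missing keys", {
  f <- writePdbText(twoResidueLines(withLigand = TRUE))
  s <- readPdb(f)
  out <- selectResidues(s, list(c("A", 2), c("A", 1)))
  expect_equal(unique(out$resSeq[out$selIndex == 1]), 2L)
  expect_equal(unique(out$resSeq[out$selIndex == 2]), 1L)
  expect_equal(nrow(selectResidues(s, list())), 0L)
  expect_error(selectResidues(s, list(c("A", 86), c("A", 88))),
               "A:86.*A:88")
})

test_that("ideal chains reproduce their generating phi/psi torsions", {
  ext <- backboneDihedrals(generatePeptideChain(3, phi = 180, psi = 180), "A")
  expect_true(is.na(ext$phi[1]) && is.na(ext$psi[3]))
  expect_true(all(abs(abs(na.omit(c(ext$phi, ext$psi))) - 180) < 1e-6))

  helix <- backboneDihedrals(generatePeptideChain(6, phi = -57, psi = -47),
                             "A")
  expect_true(all(abs(na.omit(helix$phi) + 57) < 1))
  expect_true(all(abs(na.omit(helix$psi) + 47) < 1))
})

test_that("torsions match the direct atan2 oracle and are rigid-motion invariant", {
  ch <- generatePeptideChain(4, phi = -70, psi = 120)
  base <- backboneDihedrals(ch, "A")
  xyz <- frameCoords(ch)
  # oracle: phi of residue 2 = torsion(C1, N2, CA2, C2)
  phi2 <- torsionOracle(xyz[3, ], xyz[4, ], xyz[5, ], xyz[6, ])
  psi2 <- torsionOracle(xyz[4, ], xyz[5, ], xyz[6, ], xyz[7, ])
  expect_equal(base$phi[2], phi2, tolerance = 1e-6)
  expect_equal(base$psi[2], psi2, tolerance = 1e-6)

  set.seed(7)
  for (i in 1:5) {
    moved <- pdbStructure(atomData(ch),
                          xyz %*% randomRotation() +
                            matrix(runif(3, -30, 30), nrow(xyz), 3,
                                   byrow = TRUE))
    rot <- backboneDihedrals(moved, "A")
    expect_lt(max(abs(na.omit(rot$phi - base$phi))), 1e-6)
    expect_lt(max(abs(na.omit(rot$psi - base$psi))), 1e-6)
  }
})

test_that("residues with missing backbone atoms get undefined angles, not errors", {
  ch <- generatePeptideChain(3, phi = -57, psi = -47)
  a <- atomData(ch)
  keep <- !(a$resSeq == 2 & a$name == "CA")
  broken <- pdbStructure(a[keep, ], frameCoords(ch)[keep, ])
  d <- backboneDihedrals(broken, "A")
  expect_true(is.na(d$phi[2]) && is.na(d$psi[2]))
  expect_false(is.na(d$psi[1]) && is.na(d$phi[3]))
})
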