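test_that("hydrogen bonds obey distance and angle criteria, boundary inclusive", {
  s <- generateInteractionComplex("hbond", distance = 2.9, angle = 165)
  ev <- detectHBonds(s, "LIG")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$detail, "protein_donor")
  expect_equal(ev$distance, 2.9, tolerance = 1e-9)

  far <- generateInteractionComplex("hbond", distance = 4.5, angle = 165)
  expect_equal(nrow(detectHBonds(far, "LIG")), 0L)

  bentTooFar <- generateInteractionComplex("hbond", distance = 2.9,
                                           angle = 100)
  expect_equal(nrow(detectHBonds(bentTooFar, "LIG")), 0L)

  # exactly at the donor-acceptor cutoff: <= is inclusive (no rigid motion,
  # coordinates chosen so the distance is exactly representable)
  atoms <- data.frame(
    name = c("N", "H", "CA", "O1"), element = c("N", "H", "C", "O"),
    resName = c("GLY", "GLY", "GLY", "LIG"), chainId = c("A", "A", "A", "L"),
    resSeq = c(1L, 1L, 1L, 900L), het = c(FALSE, FALSE, FALSE, TRUE))
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(-0.7, 1.2, 0), c(3.5, 0, 0))
  bound <- pdbStructure(atoms, xyz)
  ev2 <- detectHBonds(bound, "LIG")
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$distance, 3.5)
})

test_that("without explicit hydrogens H-bond detection falls back to distance only", {
  atoms <- data.frame(
    name = c("N", "CA", "O1"), element = c("N", "C", "O"),
    resName = c("GLY", "GLY", "LIG"), chainId = c("A", "A", "L"),
    resSeq = c(1L, 1L, 900L), het = c(FALSE, FALSE, TRUE))
  xyz <- rbind(c(0, 0, 0), c(-0.7, 1.2, 0), c(3.0, 0, 0))
  s <- pdbStructure(atoms, xyz)
  ev <- detectHBonds(s, "LIG")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$detail, "distance_only")
  expect_true(isTRUE(attr(ev, "distance_only")))
})

test_that("hydrophobic contacts need apolar carbon pairs and dedup per residue", {
  s <- generateInteractionComplex("hydrophobic", distance = 3.8)
  ev <- detectHydrophobic(s, "LIG")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$resName, "LEU")
  expect_equal(ev$type, "hydrophobic")

  far <- generateInteractionComplex("hydrophobic", distance = 4.5)
  expect_equal(nrow(detectHydrophobic(far, "LIG")), 0L)

  # two LEU carbons in range -> still a single event for the residue
  close <- generateInteractionComplex("hydrophobic", distance = 2.5)
  expect_equal(nrow(detectHydrophobic(close, "LIG")), 1L)

  # a polar serine oxygen contact is not hydrophobic
  atoms <- data.frame(
    name = c("N", "CA", "C", "O", "CB", "OG", "C1"),
    element = c("N", "C", "C", "O", "C", "O", "C"),
    resName = c(rep("SER", 6), "LIG"),
    chainId = c(rep("A", 6), "L"),
    resSeq = c(rep(1L, 6), 900L),
    het = c(rep(FALSE, 6), TRUE))
  xyz <- rbind(c(-2.9, 1.2, 0), c(-2.0, 0.3, 0.5), c(-2.5, -1.1, 0.6),
               c(-3.6, -1.3, 1.0), c(-0.6, 0.4, -0.1), c(0.3, -0.6, 0.4),
               c(0.3, -0.6, 3.4))
  ser <- pdbStructure(atoms, xyz)
  expect_equal(nrow(detectHydrophobic(ser, "LIG")), 0L)
})

test_that("pi-pi stacking classifies face-to-face and edge-to-face geometries", {
  s <- generateInteractionComplex("pi_pi", distance = 3.8, angle = 0)
  ev <- detectPiPi(s, "LIG")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$resName, "TYR")
  expect_equal(ev$detail, "face_to_face")
  expect_equal(ev$distance, 3.8, tolerance = 1e-9)

  expect_equal(nrow(detectPiPi(
    generateInteractionComplex("pi_pi", distance = 7), "LIG")), 0L)

  tshape <- generateInteractionComplex("pi_pi", distance = 5.0, angle = 90)
  ev2 <- detectPiPi(tshape, "LIG")
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$detail, "edge_to_face")
})

test_that("pi-cation detection works in both directions", {
  s <- generateInteractionComplex("pi_cation", distance = 4.0)
  ev <- detectPiCation(s, "LIG")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$resName, "TYR")
  expect_equal(ev$detail, "protein_ring")
  expect_equal(ev$ligandAtom, "N1")

  expect_equal(nrow(detectPiCation(
    generateInteractionComplex("pi_cation", distance = 8), "LIG")), 0L)

  arg <- generateInteractionComplex("pi_cation", distance = 4.5,
                                    direction = "ligand_ring")
  ev2 <- detectPiCation(arg, "LIG")
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$resName, "ARG")
  expect_equal(ev2$proteinAtom, "CZ")
  expect_equal(ev2$detail, "ligand_ring")
})

test_that("detectors are invariant under the rigid motion applied per frame", {
  for (ty in c("hbond", "hydrophobic", "pi_pi", "pi_cation")) {
    s <- generateInteractionComplex(ty, nFrames = 4, framesWith = 1:4,
                                    seed = 23)
    det <- switch(ty, hbond = detectHBonds, hydrophobic = detectHydrophobic,
                  pi_pi = detectPiPi, pi_cation = detectPiCation)
    per <- lapply(1:4, function(f) {
      ev <- det(s, "LIG", frame = f)
      ev[, c("chainId", "resSeq", "resName", "type")]
    })
    for (f in 2:4) expect_identical(per[[f]], per[[1]])
    expect_equal(nrow(per[[1]]), 1L)
  }
})

test_that("enlarging distance cutoffs never removes events", {
  s <- generateInteractionComplex("pi_pi", distance = 5.2)
  small <- interactionCriteria()
  big <- interactionCriteria(hbondDaMax = 5, hydrophobicCcMax = 6,
                             pipiCentroidMax = 7, picationMax = 8)
  for (det in list(detectHBonds, detectHydrophobic, detectPiPi,
                   detectPiCation)) {
    evS <- det(s, "LIG", small)
    evB <- det(s, "LIG", big)
    keyS <- paste(evS$resSeq, evS$type, evS$proteinAtom, evS$ligandAtom)
    keyB <- paste(evB$resSeq, evB$type, evB$proteinAtom, evB$ligandAtom)
    expect_true(all(keyS %in% keyB))
  }
})

test_that("interaction fractions equal planted frame ratios", {
  s <- generateInteractionComplex("hbond", nFrames = 10, framesWith = 1:7,
                                  seed = 5)
  fr <- interactionFractions(s, "LIG", lastN = 10)
  hb <- fr[fr$type == "hbond", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$fraction, 0.7)
  expect_equal(hb$n_frames, 10L)

  pc <- generateInteractionComplex("pi_cation", nFrames = 10,
                                   framesWith = 1:5, seed = 6)
  frc <- interactionFractions(pc, "LIG", lastN = 10)
  expect_equal(frc$fraction[frc$type == "pi_cation"], 0.5)

  single <- generateInteractionComplex("hbond", nFrames = 1)
  fr1 <- interactionFractions(single, "LIG")
  expect_equal(fr1$fraction[fr1$type == "hbond"], 1.0)
  expect_equal(fr1$n_frames[1], 1L)

  # default window is the last 10% of frames
  lateOnly <- generateInteractionComplex("hbond", nFrames = 20,
                                         framesWith = 19:20, seed = 8)
  frLate <- interactionFractions(lateOnly, "LIG")
  expect_equal(frLate$n_frames[1], 2L)
  expect_equal(frLate$fraction[frLate$type == "hbond"], 1.0)

  expect_error(interactionFractions(single, "NOPE"), "NOPE")
})

test_that("RMSF is zero for static trajectories and matches the alternating-atom value", {
  base <- frameCoords(generatePeptideChain(10, -57, -47))
  atoms <- atomData(generatePeptideChain(10, -57, -47))
  static <- pdbStructure(atoms, list(base, base, base))
  prof <- rmsf(static, selection = c("N", "CA", "C"))
  expect_true(all(prof$rmsf < 1e-9))
  expect_error(rmsf(pdbStructure(atoms, base)), "at least 2")

  alt <- alternatingAtomStructure(nAnchor = 80, d = 1.0, nFrames = 10)
  prof2 <- rmsf(alt)
  moving <- prof2$rmsf[prof2$resSeq == 81]
  expect_equal(moving, 1.0, tolerance = 0.02)
  expect_lt(max(prof2$rmsf[prof2$resSeq != 81]), 0.05)
})

test_that("loop residues fluctuate more than the rigid core", {
  wob <- generateWobbleTrajectory(seed = 17)
  prof <- rmsf(wob$structure)
  loop <- prof$rmsf[prof$resSeq %in% wob$loopResidues]
  core <- prof$rmsf[!prof$resSeq %in% wob$loopResidues]
  expect_gt(min(loop), max(core))
})

test_that("RMSD time series is zero for rigid copies and scales as 1/sqrt(M)", {
  base <- frameCoords(generatePeptideChain(8, -57, -47))
  atoms <- atomData(generatePeptideChain(8, -57, -47))
  set.seed(12)
  moved <- base %*% randomRotation() +
    matrix(runif(3, -8, 8), nrow(base), 3, byrow = TRUE)
  s <- pdbStructure(atoms, list(base, moved))
  ts <- rmsdTimeseries(s, selection = c("N", "CA", "C"))
  expect_equal(ts[1], 0, tolerance = 1e-12)
  expect_lt(ts[2], 1e-9)

  M <- 200L
  t <- seq_len(M)
  anchor <- cbind(3 * cos(0.5 * t), 3 * sin(0.5 * t), 1.1 * t)
  displaced <- anchor
  displaced[M, ] <- displaced[M, ] + c(1, 0, 0)
  atoms2 <- data.frame(name = "CA", element = "C", resName = "ALA",
                       chainId = "A", resSeq = t, het = FALSE)
  s2 <- pdbStructure(atoms2, list(anchor, displaced))
  ts2 <- rmsdTimeseries(s2)
  expect_equal(ts2[2], 1 / sqrt(M), tolerance = 0.02)
  expect_error(rmsdTimeseries(s2, referenceFrame = 5), "out of range")
})
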