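# run expr with a private, fully specified RNG state (Mersenne-Twister /
# Inversion), restoring the caller's state afterwards, so every generator is
# seed-deterministic across platforms and sessions
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

.mkAtoms <- function(name, element, resName, chainId, resSeq, het = FALSE) {
  n <- length(name)
  data.frame(serial = seq_len(n), name = name, element = element,
             altLoc = "", resName = rep_len(resName, n),
             chainId = rep_len(chainId, n), resSeq = rep_len(resSeq, n),
             insert = "", het = rep_len(het, n), stringsAsFactors = FALSE)
}

#' Construct a PdbStructure from atom annotation and coordinates
#'
#' Low-level constructor, mainly for building test fixtures in code.
#'
#' @param atoms data.frame with columns `name`, `element`, `resName`,
#'   `chainId`, `resSeq`, `het` (optional `serial`, `altLoc`, `insert`).
#' @param coords `N x 3` matrix, or list of such matrices (one per frame).
#' @param id structure id.
#' @return a validated [PdbStructure-class].
#' @export
pdbStructure <- function(atoms, coords, id = "synthetic") {
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$altLoc)) atoms$altLoc <- ""
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$resSeq <- as.integer(atoms$resSeq)
  if (is.matrix(coords)) coords <- list(coords)
  .newStructure(id, atoms, coords)
}

#' Synthetic pocket ensemble with planted conformational groups
#'
#' Generates toy binding-pocket conformations (one C-alpha atom per pocket
#' residue, laid out along a helical arc) in `nGroups` conformational
#' groups. Groups differ by a radial pocket expansion of `betweenShiftA`
#' Angstrom per atom -- a shape change, mimicking closed versus open pocket
#' conformations, that survives rigid superposition. Each structure adds
#' isotropic Gaussian jitter (`withinNoiseA` per coordinate) and a random
#' rigid motion. Fully seed-deterministic.
#'
#' @param nPerGroup structures per group (default 3).
#' @param nGroups number of planted groups (default 2).
#' @param nResidues pocket residues (= C-alpha atoms) per structure.
#' @param withinNoiseA within-group Gaussian noise sd, Angstrom (default 0.2).
#' @param betweenShiftA between-group radial displacement, Angstrom
#'   (default 3).
#' @param seed integer RNG seed.
#' @return list with `structures` (named list of [PdbStructure-class]),
#'   `assignments` (named integer vector of true group labels), and
#'   `selection` (residue selection data.frame for [pocketConformation()]).
#' @examples
#' ens <- generatePocketEnsemble(seed = 7)
#' pk <- lapply(ens$structures, pocketConformation, selection = ens$selection)
#' range(pairwiseRmsd(pk))
#' @export
generatePocketEnsemble <- function(nPerGroup = 3L, nGroups = 2L,
                                   nResidues = 8L, withinNoiseA = 0.2,
                                   betweenShiftA = 3.0, seed = 1L) {
  stopifnot(nPerGroup >= 1, nGroups >= 1, nResidues >= 3,
            withinNoiseA >= 0, betweenShiftA >= 0)
  if (nGroups > 1 && betweenShiftA <= withinNoiseA)
    warning("between-group shift <= within-group noise: ",
            "planted groups may not be recoverable")
  .withSeed(seed, {
    t <- seq_len(nResidues)
    base <- cbind(6 * cos(0.6 * t), 6 * sin(0.6 * t), 1.2 * t)
    ctr <- colMeans(base)
    radial <- sweep(base, 2, ctr)
    radial <- radial / sqrt(rowSums(radial^2))
    atoms <- .mkAtoms(rep("CA", nResidues), rep("C", nResidues), "ALA", "A",
                      seq_len(nResidues))
    structures <- list()
    assignments <- integer()
    for (g in seq_len(nGroups)) {
      shape <- base + (g - 1L) * betweenShiftA * radial
      for (s in seq_len(nPerGroup)) {
        xyz <- shape + matrix(stats::rnorm(3 * nResidues, sd = withinNoiseA),
                              ncol = 3)
        xyz <- xyz %*% .randomRotation() +
          matrix(stats::runif(3, -20, 20), nResidues, 3, byrow = TRUE)
        id <- sprintf("G%dS%d", g, s)
        structures[[id]] <- pdbStructure(atoms, xyz, id = id)
        assignments[id] <- g
      }
    }
    list(structures = structures, assignments = assignments,
         selection = data.frame(chainId = "A", resSeq = seq_len(nResidues)))
  })
}

# internal NeRF: place atom at bond length r from c, bond angle theta
# (b-c-new, degrees) and torsion chi (a-b-c-new, degrees)
.nerf <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Ideal peptide backbone with prescribed phi/psi
#'
#' Builds an N/CA/C backbone chain from standard bond lengths and angles
#' (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A; trans peptide, omega = 180)
#' with every residue at the given phi/psi torsions. Useful as a dihedral
#' round-trip fixture: `phi = psi = 180` gives an extended chain,
#' `phi = -57, psi = -47` a canonical alpha helix.
#'
#' @param nRes number of residues (>= 2).
#' @param phi,psi backbone torsions in degrees.
#' @param id structure id.
#' @param chainId chain identifier.
#' @return a [PdbStructure-class] with one frame.
#' @export
generatePeptideChain <- function(nRes, phi = -57, psi = -47, id = "chain",
                                 chainId = "A") {
  stopifnot(nRes >= 2)
  ang <- function(a) a * pi / 180
  coords <- matrix(NA_real_, 3L * nRes, 3L)
  coords[1, ] <- c(0, 0, 0)                      # N1
  coords[2, ] <- c(1.458, 0, 0)                  # CA1
  coords[3, ] <- coords[2, ] +
    1.525 * c(cos(pi - ang(111.2)), sin(pi - ang(111.2)), 0)  # C1
  for (i in seq_len(nRes - 1L)) {
    o <- 3L * (i - 1L)
    Ni <- coords[o + 1, ]; CAi <- coords[o + 2, ]; Ci <- coords[o + 3, ]
    Nn <- .nerf(Ni, CAi, Ci, 1.329, 116.2, psi)
    CAn <- .nerf(CAi, Ci, Nn, 1.458, 121.7, 180)
    Cn <- .nerf(Ci, Nn, CAn, 1.525, 111.2, phi)
    coords[o + 4, ] <- Nn; coords[o + 5, ] <- CAn; coords[o + 6, ] <- Cn
  }
  atoms <- .mkAtoms(rep(c("N", "CA", "C"), nRes),
                    rep(c("N", "C", "C"), nRes), "ALA", chainId,
                    rep(seq_len(nRes), each = 3L))
  pdbStructure(atoms, coords, id = id)
}

# --- residue templates for planted-interaction complexes -------------------

.hexagon <- function(r = 1.39) {
  a <- seq(0, by = pi / 3, length.out = 6)
  cbind(r * cos(a), r * sin(a), 0)
}

# aromatic residue (TYR) with ring centered at origin in the xy-plane and
# the backbone stub pointing along -x
.tyrTemplate <- function(resSeq = 10L, chainId = "A") {
  ring <- .hexagon()
  # CG sits at ring[1]; CB extends outward from the ring in-plane
  cg <- ring[1, ]
  out <- cg / sqrt(sum(cg^2))
  cb <- cg + 1.51 * out
  ca <- cb + 1.53 * (out + c(0, 0, 0.4)) / sqrt(sum((out + c(0, 0, 0.4))^2))
  n <- ca + 1.46 * c(0, 1, 0)
  cc <- ca + 1.52 * c(0, -0.3, 0.95) / sqrt(sum(c(0, -0.3, 0.95)^2))
  xyz <- rbind(ring, cb, ca, n, cc)
  atoms <- .mkAtoms(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2",
                      "CB", "CA", "N", "C"),
                    c(rep("C", 7), "C", "N", "C"),
                    "TYR", chainId, resSeq)
  list(atoms = atoms, xyz = unname(xyz))
}

# leucine with the side chain pointing along +x; CD1 is the contact atom
.leuTemplate <- function(resSeq = 10L, chainId = "A") {
  xyz <- rbind(N = c(-2.9, 1.2, 0), CA = c(-2.0, 0.3, 0.5),
               C = c(-2.5, -1.1, 0.6), O = c(-3.6, -1.3, 1.0),
               CB = c(-0.6, 0.4, -0.1), CG = c(0.6, -0.2, 0.6),
               CD1 = c(1.9, 0.2, 0), CD2 = c(0.6, -1.7, 0.5))
  atoms <- .mkAtoms(c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
                    c("N", "C", "C", "O", "C", "C", "C", "C"),
                    "LEU", chainId, resSeq)
  list(atoms = atoms, xyz = unname(xyz))
}

# arginine fragment with the guanidinium CZ at the origin
.argTemplate <- function(resSeq = 10L, chainId = "A") {
  xyz <- rbind(CZ = c(0, 0, 0), NH1 = c(1.15, 0.65, 0),
               NH2 = c(-1.15, 0.65, 0), NE = c(0, -1.33, 0),
               CD = c(1.1, -2.2, 0.2), CG = c(0.8, -3.6, 0.6),
               CB = c(1.9, -4.6, 0.4), CA = c(1.6, -6.0, 0.9),
               N = c(0.4, -6.5, 0.3), C = c(2.8, -6.9, 0.7))
  atoms <- .mkAtoms(c("CZ", "NH1", "NH2", "NE", "CD", "CG", "CB", "CA",
                      "N", "C"),
                    c("C", "N", "N", "N", "C", "C", "C", "C", "N", "C"),
                    "ARG", chainId, resSeq)
  list(atoms = atoms, xyz = unname(xyz))
}

# glycine-like donor: backbone N with explicit amide hydrogen at the origin
.donorTemplate <- function(resSeq = 10L, chainId = "A") {
  xyz <- rbind(N = c(0, 0, 0), H = c(1.01, 0, 0),
               CA = c(-0.7, 1.25, 0), C = c(-2.2, 1.1, 0.2),
               O = c(-2.9, 2.1, 0.3))
  atoms <- .mkAtoms(c("N", "H", "CA", "C", "O"),
                    c("N", "H", "C", "C", "O"), "GLY", chainId, resSeq)
  list(atoms = atoms, xyz = unname(xyz))
}

#' Minimal complex with a planted protein-ligand interaction
#'
#' Builds a small protein fragment plus a hetero ligand placed so that the
#' requested interaction geometry holds exactly in the frames listed in
#' `framesWith`; in all other frames the ligand is moved a further 3
#' Angstrom along the separation axis, violating every default cutoff. A
#' random rigid motion (seed-deterministic) is applied to the whole complex
#' in every frame, so detector results also exercise rigid-motion
#' invariance.
#'
#' Planted geometries: `hbond` -- backbone N-H donor to a ligand oxygen at
#' donor-acceptor `distance` with D-H...A angle `angle` (default 165);
#' `hydrophobic` -- leucine CD1 to an apolar ligand carbon at `distance`;
#' `pi_pi` -- tyrosine ring to a ligand benzene at centroid `distance`, ring
#' planes at `angle` (0 = stacked face-to-face, 90 = T-shaped edge-to-face);
#' `pi_cation` -- either a ligand trimethylammonium nitrogen above the
#' tyrosine ring (`direction = "protein_ring"`) or the arginine CZ above a
#' ligand benzene (`direction = "ligand_ring"`), at `distance` from the ring
#' centroid.
#'
#' @param type interaction type to plant.
#' @param distance planted distance in Angstrom.
#' @param angle planted angle in degrees (hbond D-H...A, or pi-pi
#'   inter-plane angle).
#' @param nFrames number of frames.
#' @param framesWith frame indices (1-based) where the geometry holds.
#' @param direction for `pi_cation`: which side carries the ring.
#' @param ligandName 3-letter code of the generated ligand residue.
#' @param seed RNG seed for the per-frame rigid motions.
#' @return a [PdbStructure-class] with `nFrames` frames.
#' @export
generateInteractionComplex <- function(type = c("hbond", "hydrophobic",
                                                "pi_pi", "pi_cation"),
                                       distance = NULL, angle = NULL,
                                       nFrames = 1L,
                                       framesWith = seq_len(nFrames),
                                       direction = c("protein_ring",
                                                     "ligand_ring"),
                                       ligandName = "LIG", seed = 1L) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  stopifnot(all(framesWith >= 1), all(framesWith <= nFrames))
  if (is.null(distance))
    distance <- switch(type, hbond = 2.9, hydrophobic = 3.8,
                       pi_pi = 3.8, pi_cation = 4.0)
  if (is.null(angle)) angle <- switch(type, hbond = 165, pi_pi = 0, 0)

  if (type == "hbond") {
    prot <- .donorTemplate()
    th <- angle * pi / 180
    h <- 1.01   # donor-hydrogen bond length of the template
    s <- h * cos(th) + sqrt(max(h^2 * cos(th)^2 - h^2 + distance^2, 0))
    apos <- c(h, 0, 0) + s * c(-cos(th), sin(th), 0)
    ligAtoms <- .mkAtoms("O1", "O", ligandName, "L", 900L, het = TRUE)
    ligXyz <- matrix(apos, 1, 3)
    axis <- apos / sqrt(sum(apos^2))
  } else if (type == "hydrophobic") {
    prot <- .leuTemplate()
    cd1 <- c(1.9, 0.2, 0)
    axis <- c(1, 0, 0)
    ligAtoms <- .mkAtoms("C1", "C", ligandName, "L", 900L, het = TRUE)
    ligXyz <- matrix(cd1 + distance * axis, 1, 3)
  } else if (type == "pi_pi") {
    prot <- .tyrTemplate()
    axis <- c(0, 0, 1)
    ring <- .hexagon()
    th <- angle * pi / 180
    rot <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
    ligXyz <- sweep(ring %*% rot, 2, distance * axis, "+")
    ligAtoms <- .mkAtoms(paste0("C", 1:6), rep("C", 6), ligandName, "L",
                         900L, het = TRUE)
  } else { # pi_cation
    if (direction == "protein_ring") {
      prot <- .tyrTemplate()
      axis <- c(0, 0, 1)
      npos <- distance * axis
      # trimethylammonium: quaternary N so default perception flags it
      m <- 1.49
      arms <- rbind(c(m, 0, 0.5), c(-m / 2, m * 0.87, 0.5),
                    c(-m / 2, -m * 0.87, 0.5), c(0, 0, 1.49))
      arms <- sweep(arms * c(0.9, 0.9, 1), 2, npos, "+")
      # rescale arm bonds to ~1.49 A from N
      arms <- t(apply(arms, 1, function(p) {
        v <- p - npos; npos + 1.49 * v / sqrt(sum(v^2))
      }))
      ligXyz <- rbind(npos, arms)
      ligAtoms <- .mkAtoms(c("N1", paste0("C", 1:4)),
                           c("N", rep("C", 4)), ligandName, "L", 900L,
                           het = TRUE)
    } else {
      prot <- .argTemplate()
      axis <- c(0, 0, 1)
      ligXyz <- sweep(.hexagon(), 2, c(0, 0, -distance), "+")
      ligAtoms <- .mkAtoms(paste0("C", 1:6), rep("C", 6), ligandName, "L",
                           900L, het = TRUE)
      axis <- c(0, 0, -1)
    }
  }

  atoms <- rbind(prot$atoms, ligAtoms)
  atoms$serial <- seq_len(nrow(atoms))
  nProt <- nrow(prot$atoms)
  .withSeed(seed, {
    frames <- lapply(seq_len(nFrames), function(f) {
      lxyz <- if (f %in% framesWith) ligXyz
              else sweep(ligXyz, 2, 3 * axis, "+")
      xyz <- rbind(prot$xyz, lxyz)
      R <- .randomRotation()
      xyz %*% R + matrix(stats::runif(3, -10, 10), nrow(xyz), 3, byrow = TRUE)
    })
    pdbStructure(atoms, frames, id = paste0("planted_", type))
  })
}

#' Multi-frame trajectory with a wobbling loop
#'
#' C-alpha trace whose core residues stay (nearly) fixed while designated
#' loop residues fluctuate with a larger amplitude -- a minimal stand-in for
#' the loop-versus-secondary-structure RMSF contrast seen in receptor MD.
#'
#' @param nResidues chain length (default 30).
#' @param loopResidues indices of the mobile residues.
#' @param loopAmplitudeA per-coordinate sd of loop displacement (A).
#' @param coreAmplitudeA per-coordinate sd of core jitter (A).
#' @param nFrames number of frames.
#' @param seed RNG seed.
#' @return list with `structure` (a [PdbStructure-class]) and
#'   `loopResidues`.
#' @export
generateWobbleTrajectory <- function(nResidues = 30L, loopResidues = 11:15,
                                     loopAmplitudeA = 1.5,
                                     coreAmplitudeA = 0.05, nFrames = 20L,
                                     seed = 1L) {
  stopifnot(nFrames >= 2, all(loopResidues %in% seq_len(nResidues)))
  .withSeed(seed, {
    t <- seq_len(nResidues)
    base <- cbind(2.3 * cos(1.7 * t), 2.3 * sin(1.7 * t), 1.5 * t)
    sd <- rep(coreAmplitudeA, nResidues)
    sd[loopResidues] <- loopAmplitudeA
    frames <- lapply(seq_len(nFrames), function(f)
      base + matrix(stats::rnorm(3 * nResidues, sd = rep(sd, 3)), ncol = 3))
    atoms <- .mkAtoms(rep("CA", nResidues), rep("C", nResidues), "ALA", "A",
                      seq_len(nResidues))
    list(structure = pdbStructure(atoms, frames, id = "wobble"),
         loopResidues = loopResidues)
  })
}

.bundledFile <- function(name) {
  path <- system.file("extdata", name, package = "CompDock")
  if (path == "") stop("bundled file not found: ", name)
  path
}

#' Bundled docking-score tables and template metadata
#'
#' Returns the packaged transcriptions of the published study tables: the
#' training-set docking scores (17 ligands against the 3SQ6-based and
#' 2XYT-based receptor conformations, three of them with a failed 3SQ6
#' docking), the 12-compound test-set scores (two with a failed 3SQ6
#' docking), and the template metadata (per complex: sequence identity to
#' the human alpha7 nAChR-LBD and crystallographic resolution). The tables
#' ship as TSV files under `inst/extdata/` so they are user-inspectable;
#' this function parses them with [readScoreTable()].
#'
#' @return list with `train` and `test` (docking-record data.frames) and
#'   `metadata` (data.frame with `structure_id`, `ligand_id`,
#'   `sequence_identity_pct`, `resolution_A`, ...).
#' @examples
#' tabs <- bundledTables()
#' winningScores(tabs$train)
#' @export
bundledTables <- function() {
  train <- readScoreTable(.bundledFile("training_scores.tsv"))
  test <- readScoreTable(.bundledFile("test_scores.tsv"))
  metadata <- utils::read.delim(.bundledFile("template_metadata.tsv"),
                                comment.char = "#",
                                stringsAsFactors = FALSE)
  list(train = train, test = test, metadata = metadata)
}
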