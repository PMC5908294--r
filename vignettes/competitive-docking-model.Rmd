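---
title: "The competitive docking model: methods and design notes"
author: "CompDock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The competitive docking model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CompDock)
```

## The problem

No experimental structure of the human α7 nicotinic acetylcholine receptor
ligand binding domain (α7 nAChR-LBD) is available, yet screening compounds
for α7 binding is of direct toxicological and pharmacological interest.
The workflow this package implements works around that gap: candidate
template complexes (acetylcholine binding proteins and a chimeric
nAChR-LBD, each co-crystallized with an α7-active ligand) are compared by
the conformation of their ligand binding pockets; one representative
receptor conformation per pocket family is carried forward; each query
compound is docked against the whole ensemble of receptor conformations;
and a single normalized binding-potential score — the competitive docking
model (CDM) value — is derived from the most favorable docking score.

CompDock covers the computable stages of that scheme: pocket
conformational clustering, the CDM fit and prediction, and the geometric
analysis of receptor–ligand complexes. Homology modeling, molecular
dynamics and the docking runs themselves are upstream tools whose outputs
(PDB structures, score tables) this package consumes.

## Pocket conformational clustering

Each binding pocket is an ordered set of residues with an explicit
correspondence across structures, supplied as a pocket-definition file
(`readPocketDefinitions()`); the package deliberately does **not** align
sequences itself, because the candidate templates are homologs whose
author numbering differs — the user states the correspondence once, in
matched row order.

For every pair of pockets the minimal RMSD is computed after an optimal
rigid superposition of that pair (Kabsch least-squares via SVD,
`kabschSuperpose()`; reflections are excluded, so the rotation determinant
is always +1). Superposition is pairwise rather than to a common
reference: with only ~17 structures the cost is negligible and no
reference-choice bias enters the matrix. No outlier-rejection cycles are
applied — the RMSD is over all pocket atoms — because an
outlier-trimmed "align"-style RMSD changes with the rejection schedule and
is not reproducible from the matrix alone.

By default only the pocket Cα atoms enter the comparison
(`atomMode = "CA_only"`). Pocket side chains differ between non-identical
homologs, so an all-heavy-atom RMSD is only meaningful when the residues
are identical; `"backbone"` and `"heavy"` modes are available for that
case.

The RMSD matrix is clustered agglomeratively with Ward's minimum-variance
criterion (`wardCluster()`, backed by `stats::hclust`). The default
linkage is `ward.D2`, the Lance–Williams update on squared
dissimilarities, which is the textbook Ward criterion for a distance
matrix. The legacy `ward.D` variant (the behaviour of early `hclust`
releases under the name "ward") is offered as a flag because published
pocket-clustering work used that interface; on well-separated pocket
families both cuts agree, and the test suite pins both on planted
two-group ensembles. Structure ids are sorted lexicographically before
clustering so that merge tie-breaks do not depend on input order.

One representative complex per cluster is chosen by
`selectRepresentatives()`: highest sequence identity to the target first,
ties broken by best (smallest) crystallographic resolution, then by
lexicographic id. This is a deterministic codification of how templates
are picked in practice; when a study weighs additional considerations
(e.g. preferring the template whose bound ligand is large and rigid so
that the modeled pocket stays open), those judgments are outside a
reproducible rule, and the chosen rule may then differ from a published
pick within a tie set. The `criteria` element of the result records the
values behind each choice so such cases are visible.

## The competitive docking model

Docking results arrive as one record per (ligand, receptor conformation)
with a `docked`/`failed` status and an XP GScore-like score (more negative
= more favorable); the importer accepts "ND" and "failed to dock" markers.
The **winning score** of a ligand is resolved by the competitive rule
(`winningScore()`), with three scenarios:

1. the ligand docked to exactly one conformation — that score wins;
2. it docked to several — the minimum (most favorable) score wins;
3. it docked to none — no score, the ligand is a predicted non-binder.

Ties between conformations are broken by lexicographic receptor id (the
choice does not affect the score, only the reported receptor). The
ensemble may contain more than two conformations; the rule is min over
docked scores.

Fitting (`fitCDM()`) stores the lowest and highest winning score of the
training set. The CDM value of a winning score $s$ is

$$\mathrm{CDM}(s) = 1 - \frac{s - s_{\min}}{s_{\max} - s_{\min}},$$

a min–max normalization oriented so that more favorable scores give larger
values: the training minimum maps to 1, the training maximum to 0. A
compound is called a **binder** when its CDM value is ≥ 0 and a
non-binder otherwise. Fitted on the bundled 17-ligand training table this
gives $s_{\min} = -8.725$, $s_{\max} = -4.218$ and range $4.507$:

```{r}
tabs <- bundledTables()
model <- fitCDM(winningScores(tabs$train))
model
```

Three numerical choices are deliberate and documented here:

* **No clipping.** Test compounds scoring outside the training range map
  to values above 1 or below 0; only the sign matters for the call, and
  clipping would discard the ranking information.
* **Rounding.** Published tables print 3 decimals with half-up rounding;
  the `cdm` column reproduces that display convention, while `cdm_exact`
  keeps full precision and the binder threshold is applied to the
  unrounded value.
* **Degenerate fits fail loudly.** Fewer than two finite winning scores,
  or an all-equal training set, is an error, not a silent zero-range
  model.

Fitted models serialize to JSON (`writeCDMModel()`) with their
normalization constants and provenance (training ligand ids, receptor
ids), so a trained CDM instance is a storable artifact.

## Geometric interaction fingerprints

`interactionFractions()` reports, per residue and interaction type, the
fraction of analysis frames in which the interaction is geometrically
present in a (multi-MODEL) receptor–ligand PDB. Four types are detected,
with defaults following common simulation-interaction-diagram
conventions. The thresholds are not universal constants — different tools
use slightly different values — so all are configurable through
`interactionCriteria()` and the tests pin the defaults:

| type | criterion | default |
|---|---|---|
| hydrogen bond | donor–acceptor distance; D–H···A angle when H present | ≤ 3.5 Å; ≥ 120° |
| hydrophobic | apolar C – apolar C distance | ≤ 4.0 Å |
| π–π | ring centroid – centroid distance | ≤ 5.5 Å |
| π–cation | cation site – ring centroid distance | ≤ 6.0 Å |

Implementation notes:

* **Bond inference.** Bonds are inferred from covalent radii (+0.45 Å
  tolerance); an *apolar* carbon is one not bonded to N or O. Hydrophobic
  events are restricted to hydrophobic-capable residues (ALA, VAL, LEU,
  ILE, PRO, MET, PHE, TRP, TYR, CYS) and deduplicated to one event per
  residue per frame.
* **Hydrogens are optional.** With explicit hydrogens the H-bond
  criterion includes the D–H···A angle; without them a distance-only
  criterion is used and the result is flagged (`distance_only`
  attribute), since most deposited crystal structures lack hydrogens.
* **Rings.** Aromatic rings of PHE, TYR, TRP (both rings) and HIS are
  template-defined. Ligand rings come from a user template keyed by the
  ligand's 3-letter code when given; otherwise minimal cycles (5–6
  atoms) of the bond graph that are planar to within 0.15 Å maximum
  out-of-plane deviation are accepted as aromatic. Planarity is a
  geometric proxy for aromaticity — adequate for crystal poses and MD
  frames, but it will accept a flat saturated ring frozen in a planar
  conformation.
* **Cations.** Protein cation sites default to the arginine guanidinium
  carbon (CZ) and lysine ammonium nitrogen (NZ). Ligand cations are
  template-supplied, with a fallback that flags nitrogens with four
  bonded neighbours (quaternary ammonium). Both π–cation directions are
  scanned: ligand cation over a protein ring, and protein cation over a
  ligand ring.
* **Frame window.** The default analysis window is the last 10% of
  frames (at least one) — the "last nanosecond" convention for a
  trajectory whose frames are saved uniformly — overridable with
  `lastN`.

`rmsf()` superposes every frame onto a reference on a named atom
selection (default Cα) and reports the per-residue root-mean-square
fluctuation about the mean structure. The default reference is the mean
structure, obtained by fitting to frame 1, averaging and re-fitting once;
`reference = "first"` skips the averaging step. `rmsdTimeseries()` gives
the per-frame RMSD to a chosen reference frame after superposition on the
selection.

## Synthetic fixtures: what they emulate, what they do not

All test inputs are generated in code, deterministically (Mersenne–
Twister with a fixed, fully specified seed; generators restore the
caller's RNG state):

* `generatePocketEnsemble()` plants conformational groups that differ by
  a *radial pocket expansion* — a shape change that survives rigid
  superposition, mimicking the closed-versus-open pocket contrast that
  motivates using two receptor conformations. Defaults (3 structures per
  group, 0.2 Å within-group jitter, 3 Å between-group displacement)
  put the group separation 15× above the noise, comfortably inside the
  regime where two-group recovery must be exact.
* `generateInteractionComplex()` builds a minimal residue template plus a
  ligand positioned so one interaction geometry holds exactly in chosen
  frames and is violated by +3 Å elsewhere, with a random rigid motion
  per frame so detector invariance is exercised for free.
* `generateWobbleTrajectory()` contrasts a near-rigid core with
  high-amplitude loop residues for RMSF checks.
* `bundledTables()` returns the packaged TSV transcriptions of the
  published training scores, test scores and template metadata.

These fixtures are geometric caricatures, not physical structures: there
is no force field, no realistic side-chain packing, no solvent, and the
planted interactions are noise-free. Passing tests therefore demonstrate
that the *detectors and estimators implement their stated geometric
definitions* — they do not validate the biological realism of the default
cutoffs on real MD ensembles, which is inherited from the conventions the
defaults follow.

## What is, and is not, reproducible here

Reproduced exactly from bundled inputs: the CDM normalization constants,
the full training winning-score column, and all 12 test-compound CDM
values and binder calls (11 binders, 1 non-binder), each at the printed
3-decimal precision — see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.

Not reproducible at desk scale, by design: the published dendrogram of
the 17 real binding pockets (it requires the deposited crystal
structures; the package checks the two-group split on a synthetic
17-member ensemble instead, and an integration run on downloaded PDB
entries is possible but nothing depends on it), Ramachandran region
percentages of the homology models, the MD trajectories, and the
trajectory-derived key-residue lists (the trajectories are not
deposited). Test problem sizes are kept small on purpose — 6–20 point
superposition instances, 6-structure clustering oracles, 10–20 frame
trajectories — because the checked properties (oracle agreement,
invariances, planted-geometry recovery) are scale-free.

## Known limitations

* Pocket correspondence is the user's responsibility; mismatched pocket
  definitions produce a correspondence error, not a silent misalignment.
* Only PDB format is read; mmCIF is out of scope.
* The H-bond fallback without hydrogens cannot distinguish donors from
  acceptors, and counts N/O–N/O proximity.
* Aromaticity-by-planarity can misclassify rigid planar non-aromatic
  rings (see above).
* Interaction fractions treat each (residue, type) independently;
  water-mediated bridges and salt-bridge typing beyond the π–cation and
  H-bond categories are not implemented.
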