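---
title: "Quantifying beta-hairpin registries in disordered peptide ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying beta-hairpin registries in disordered peptide ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinreg)
```

## The scientific problem

Amyloid fibril formation is rate-limited by primary nucleation, and for the
tau aggregation motif the nucleation-competent species is thought to be a
small oligomer of monomeric beta-hairpins rather than a coalescence of
random coils.  For the 17-residue tau fragment 295--311 (sequence
`DNIKHVPGGGSVQIVYK`, carrying the PHF6 hexapeptide `VQIVYK` at 306--311),
a monomer hairpin folds the hexapeptide back onto the N-terminal arm.
Because cross-strand backbone hydrogen bonds alternate along a strand, two
distinct *registries* exist: "even" hairpins hydrogen-bond the
even-numbered hexapeptide residues (306V, 308I, 310Y) to the arm, while
"odd" hairpins bond 305S, 307Q and 309 instead.  Shifting the pairing by a
single residue flips every hexapeptide side chain from one face to the
other and inverts the exposed backbone donors/acceptors, which matters for
the intermolecular hydrogen bonding that builds the parallel cross-beta
fibril core.

This package quantifies, frame by frame over a conformational ensemble:

* the registry class of each frame (`classify_hairpin`),
* hexapeptide random-coil content, orthogonal to the hairpin calls
  (`frame_flags`, `summarize_ensemble`),
* the hexapeptide all-"E" beta content (`f_beta_hex`),
* the cross-beta hairpin amyloid trimer (xHAT) nucleation score
  $S_\mathrm{xHAT} = f_\mathrm{odd}\, f_\mathrm{even}^2$,

and relates these metrics to experimental Thioflavin-T (ThT) aggregation
kinetics across a mutant library.  The same machinery scales up to the
four-repeat tau fragment k18 (residues 244--372), where local hairpins form
around each PGGG turn motif (H1--H4) and the four aggregation-prone
hexapeptides pair with each other at long range.

## Hairpin criteria

A frame is called a hairpin when two criteria hold:

1. **Span.** The scored hexapeptide residues 306--310 (311K is excluded as
   highly mobile, as are both termini 295D/311K) must all lie within the
   hairpin span.  The span is delimited by the outermost hexapeptide
   residues that carry cross-arm hydrogen bonds, extended by one residue on
   each side (`span_slack = 1`).  The extension reflects antiparallel
   ladder geometry: hydrogen-bonded and non-bonded rungs alternate, so the
   sheet extends one residue past the outermost bonded rung.  Without the
   extension, an odd hairpin bonded at 305/307/309 would be rejected for
   "missing" 310 even though 310 still sits inside the sheet -- the slack
   makes the two registry classes symmetric under a one-residue shift.
   At least two cross-arm-bonded hexapeptide residues are required.
2. **Proper hydrogen bonds.** Cross-arm contacts are backbone amide-N to
   carbonyl-O pairs with a heavy-atom N--O distance of at most 3.5 A
   (inclusive), either donor orientation, with |i - j| >= 2.  No angular
   term is applied by default (an optional donor-H angle filter exists for
   sensitivity analysis); the heavy-atom criterion is deliberately
   tolerant because ensemble frames need not have ideal hydrogen
   positions.

The registry is **even** (**odd**) when the bonded hexapeptide residues
are a pure subset of {306, 308, 310} ({305, 307, 309}) with at least
`min_parity_bonds = 2` members.  Mixed parity yields `"none"` -- the
strictest rule consistent with a clean registry picture; `allow_mixed`
relaxes it to a majority vote for sensitivity analysis.  Partners must
decrease strictly with hexapeptide index (antiparallel geometry);
parallel-like orderings are rejected with an explicit reason.

**Orthogonality.** Hexapeptide coil content counts residues with
secondary-structure code "C", but only on frames not classified as
hairpins; hairpin frames contribute zero to the coil sum, so no fold is
counted in both categories.  The per-mutant coil probability is the
weighted coil count divided by 6 x (weighted frames).

## Geometry engines

* **Hydrogen bonds** (`detect_backbone_hbonds`) are a vectorised N-O
  distance scan; tests assert exact agreement with a brute-force
  all-pairs oracle and inclusivity at exactly 3.50 A.
* **Secondary structure** (`assign_secondary_structure`) is a
  Kabsch--Sander (DSSP-style) assigner over {H, G, I, E, B, T, C}: the
  electrostatic hydrogen-bond energy with the -0.5 kcal/mol threshold,
  n-turns, helices from consecutive turns, and parallel/antiparallel
  bridges and ladders.  Amide hydrogens are reconstructed at 1.0 A from N
  along the bisector-opposed direction of C(i-1)-N-CA when absent;
  prolines and the N-terminus do not donate.  No external DSSP/STRIDE
  binary is required; agreement with an independent reference
  implementation (mdtraj's DSSP) is asserted in the test suite on helix,
  hairpin and extended fixtures.  Borderline assignments can differ from
  STRIDE, which matters only for the coil metric; the all-coil and
  all-beta fixtures used in validation are unambiguous.
* **SASA** (`compute_sasa`, `atom_sasa`) is Shrake--Rupley with a
  deterministic golden-spiral point set (960 points/atom by default, no
  RNG, hence bit-reproducible) and fixed heavy-atom radii C 1.70, N 1.55,
  O 1.52, S 1.80 A, probe 1.4 A, hydrogens ignored.  Exactly coincident
  spheres are counted once (the quadrature boundary is otherwise
  ill-conditioned there).  Tests cover the analytic isolated-sphere value
  $4\pi (r + r_\mathrm{probe})^2$, the coincident-sphere limit, enclosed
  atoms, and monotone burial.
* **Superposition RMSD** (`kabsch_rmsd`) is the SVD-based Kabsch solution
  with reflection correction, cross-checked against bio3d's fitted RMSD
  and a brute-force rotation-grid search.

## Ensemble metrics and the xHAT score

`summarize_ensemble` aggregates per-frame calls with frame weights
(weights default to 1; replica-exchange temperature pooling is handled
upstream by concatenation, and the weight-aware summary makes alternative
poolings a no-code change).  Fractions are invariant under frame
duplication, weight rescaling and permutation.  The xHAT score
$S = f_\mathrm{odd} f_\mathrm{even}^2$ encodes the registry composition of
the transition-state trimer (two even hairpins, one registry-shifted
monomer); on the simplex $f_\mathrm{even} + f_\mathrm{odd} = 1$ it is
maximal at $(2/3, 1/3)$ with value $4/27$.  `rank_mutants` ranks
descending with average ranks on ties; total hairpin content for
correlation purposes is $f_\mathrm{even} + f_\mathrm{odd}$.

## Repeat-domain statistics

`make_repeat_spec` encodes the k18 conventions: hexapeptides 1--4 at
275--280 (PHF6*), 306--311 (PHF6), 337--342 (Module-B) and 369--374, each
preceded by a PGGG motif, with 5-residue N-terminal flanking sites.
Hexapeptide 4 extends two residues past the k18 terminus at 372; ranges
are clipped to the available sequence with a warning rather than erroring,
since the flanking convention, not the exact terminus, carries the
information.  Local hairpin probabilities H1--H4 reuse the peptide
classifier with a region map built per motif: the hexapeptide is the
C-terminal strand, the N-arm is the flank extended upstream to (but not
including) the previous hexapeptide, and parity sets are laid out relative
to the first hexapeptide residue.  Any registry counts as a local hairpin.
Inter-hexapeptide pairing calls an (i, j) event when at least
`min_bonds = 2` backbone hydrogen bonds join the two hexapeptides in a
frame; one bond is too noise-prone to call "beta-sheet formation", and the
threshold is exposed as configuration.  The `min_bonds = 1` matrix
dominates the `min_bonds = 2` matrix elementwise (tested).  Segment beta
totals add a local probability and caller-selected pairings
(`total_beta_for_segment`); totals above 1 warn because the underlying
events may overlap.  SASA differentials report per-residue ensemble-mean
differences with the convention positive = first ensemble more exposed.

## Kinetics

ThT plates are blank-subtracted (per-timepoint mean of the blank wells)
and fitted per replicate well with the 4-parameter logistic
$y(t) = b + (p - b) / (1 + e^{-k (t - T_{1/2})})$ by multistart
Levenberg--Marquardt; the reported $T_{1/2}$ is the median across
converged wells (a mean-curve fit is available behind a flag).  The
4-parameter logistic is the standard reading of a "sigmoidal fit" and
$T_{1/2}$ -- the inflection/half-amplitude time -- is well-defined
regardless of the precise form.  A well whose smoothed amplitude is below
five times the point-to-point noise floor is called "no aggregation"
(`converged = FALSE`); such mutants get aggregation speed 0
($1/T_{1/2}$ otherwise) and are excluded from correlations by default.
A fitted $T_{1/2}$ outside the observed window is flagged.  Correlations
are Spearman by default, with Pearson-on-ranks available because metric
rankings, not raw values, are the headline comparison; both are emitted by
the correlation result and the tests pin Spearman to the textbook
tie-corrected formula.

## The synthetic generators

The generators provide labelled ground truth for every stage and define
the package's validation conditions:

* `build_ideal_hairpin` constructs two antiparallel strands (CA spacing
  3.8 A, inter-strand N-O 2.90 A at bonded rungs, next-nearest
  non-designated N/O pairs > 3.9 A) joined by an equal-chord circular-arc
  turn whose bulge is tilted out of the strand plane so that junction
  carbonyls keep a wide margin from strand amides.  Cross-arm bonds land
  exactly on the requested parity set, pairing rung r with arm residue
  2 x turn_center - r.  Every build is validated closed-loop through the
  detector and classifier and errors when infeasible.
* `build_extended` uses ideal backbone internal coordinates (N-CA 1.458,
  CA-C 1.525, C-N 1.329 A) with beta-region dihedrals (-139, 135); the
  result is verified free of intra-chain hydrogen bonds.
* `build_coil` samples dihedrals from broad extended/polyproline and
  left-handed basins (excluding the alpha-helical core and the geometry
  that could complete a sheet), with 2.5 A clash rejection and a retry
  budget; draws are deterministic under the seed and guaranteed to
  classify as `"none"`.
* `build_k18_frame` lays the chain out as a straight strand and
  repositions segments to realise exactly the requested local-hairpin and
  pairing events; it is a geometric fixture and deliberately does not
  maintain chain continuity across repositioned segments.
* `simulate_tht_plate` draws quadruplicate 4PL wells plus blank wells on a
  30-minute grid over 144 h with i.i.d. Gaussian noise scaled to the curve
  amplitude (2% by default), emulating a plate-reader experiment.

Coordinate noise is i.i.d. Gaussian per coordinate -- the simplest
perturbation that exercises the distance cutoff.  Under sigma = 0.2 A the
classifier recovers the constructed registry on more than 99% of frames;
the residual losses are single rungs broken by noise, which the span
criterion correctly rejects.

**What passing these tests does and does not show.**  The generators are
geometric fixtures: ideal strands, a smooth turn, no side chains beyond
C-beta, no force-field energetics, and no physically realistic
conformational correlations.  Passing the closed-loop and recovery suites
shows the *analysis* is exact and robust on known ground truth; it does
not show that any particular simulated ensemble is thermodynamically
faithful, and real MD frames will populate the borderline geometries the
fixtures deliberately avoid.

## Numerical choices and problem sizes

Tolerance and size choices used by the validation suite, stated as the
package's own study conditions: composition recovery uses ensembles of
n = 2000 frames against a 3-binomial-sigma band; classifier robustness
uses sigma = 0.2 A noise with a >= 99% recovery requirement; half-time
recovery uses 100 seeded plates at 2% amplitude noise with a 5% median
error bound; smaller ensembles (tens of frames) are used where only
exactness, not sampling error, is at stake.  PDB coordinates round-trip
at the format's 0.001 A precision.  All randomness flows through
explicit seeds.

## Known limitations

* The secondary-structure assigner follows Kabsch--Sander; STRIDE (the
  common alternative) differs on borderline residues, which can shift coil
  counts slightly on real ensembles.
* The classifier reads hydrogen-bond topology only; an interpretation of
  the span criterion through per-residue "E" labels would require the SS
  string and is not the default.
* Side chains beyond C-beta are absent from synthetic frames, so absolute
  synthetic SASA values underestimate real per-residue exposure; SASA
  *differentials* between like-built ensembles remain meaningful.
* Non-aggregating mutants carry no finite half-time; they are excluded
  from correlations by default rather than imputed.
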