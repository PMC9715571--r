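---
title: "Integrative rigid-body assembly from chemical crosslinking restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative rigid-body assembly from chemical crosslinking restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Large multi-subunit complexes often resist complete experimental
determination: a rigid scaffold may be resolved to high resolution while a
flexibly tethered subunit averages out of the reconstruction. Chemical
crosslinking mass spectrometry (CXMS) fills the gap. A lysine-reactive
reagent such as BS3 covalently joins residue pairs that come within its
reach in solution; the digested and mass-identified peptide pairs become
distance restraints between specific residues. Given (i) coordinate models
of the individual subunits, (ii) an FDR-filtered table of crosslinked
residue pairs, and (iii) a mapping between full-length sequence numbering
and the deposited construct numbering, the placement of a mobile subunit
against a fixed scaffold can be posed as a rigid-body optimisation
problem.

`xlassemble` implements that workflow end to end: coordinate I/O, restraint
bookkeeping, restraint-guided rigid-body docking, candidate ranking, and
structural characterisation of the result (superposition RMSD, buried
interface areas, polar contacts, principal dimensions, helix bend angles).
A seeded synthetic-assembly generator makes every stage testable without
any external data.

## The restraint model

A BS3 crosslink between two lysines implies an upper bound on their
C$\alpha$–C$\alpha$ distance. We use the field-standard bound of

$$ d_{C\alpha-C\alpha} \le 30\ \text{Å}, $$

from the 11.4 Å spacer arm plus two lysine side chains and backbone
flexibility. A crosslink constrains only an upper bound — nothing rewards
shorter distances — so the pose score is a flat-bottom quadratic:

$$ S(\text{pose}) = \sum_{\ell} \max(0,\, d_\ell - c)^2 \cdot w_v
   \;+\; n_{\text{clash}} \cdot w_c $$

with cutoff $c = 30$ Å, violation weight $w_v = 1$ per Å$^2$, and a clash
term counting fixed–mobile C$\alpha$ pairs closer than 3 Å
($w_c = 10$ per pair). The satisfaction boundary is inclusive
($d \le c$ is satisfied), the distance is Euclidean (surface-path
distances are out of scope), and the FDR filter is likewise inclusive
($\mathrm{FDR} \le 0.05$ by default). When a homodimer makes a crosslink
end ambiguous between identical chains, the copy giving the shorter
distance is used — the standard permissive convention, since mass
spectrometry cannot distinguish identical sequences.

### Optimisation

`dock_rigid()` is a multi-start stochastic search over the six rigid
degrees of freedom. Each restart draws a uniform random rotation (random
unit quaternion) and places the mobile centroid uniformly in a sphere of
radius $1.5c$ around the centroid of the fixed body's linked anchors, then
refines by simulated annealing (geometric cooling, move scales shrinking
with the schedule) followed by greedy coordinate descent to local
convergence. Poses within 2 Å pairwise C$\alpha$ RMSD are merged (best
kept) and the survivors ranked by score, ties broken by restart seed.
Everything is reproducible from one integer seed. `rank_models()` applies
the same score to complete candidate assemblies in place and reports the
violated links per candidate, supporting "all crosslinks accounted for,
except ..." bookkeeping.

### What a flat-bottom score can and cannot localise

Because the restraints are pure upper bounds, every pose in which all
links are within the cutoff scores exactly zero. The diameter of this
zero-score set — not the optimiser — limits localisation precision. Each
link contributes a slack of $c - d_{\text{true}}$; a body held by links
with typical slacks of 5–15 Å can translate and reorient by comparable
amounts at zero score. Precision improves when links arrive from many
directions (a wrap-around, concave scaffold) and when their true
distances approach the bound; it degrades for thin, quasi-linear bodies,
where a near-mirror placement across the scaffold axis can satisfy every
restraint. This is a known property of XL-MS-based integrative models,
which localise flexible subunits to "close proximity" rather than to
atomic precision, and it is exactly what the package's recovery benchmark
measures. Users who need tighter placements must add information beyond
upper-bound crosslinks (density fitting, interface restraints), which is
outside this package's scope.

## Structural characterisation

* **Superposition** — `kabsch_superpose()` computes the least-squares
  proper rotation via SVD with determinant sign correction (reflections
  excluded); the RMSD is unweighted over the supplied pairing, with no
  trimming. `pair_common_ca()` builds the pairing from residues present
  in both chains of an explicit chain correspondence; for homodimers both
  chain assignments are evaluated and the lower-RMSD one kept.
* **Surface areas** — `sasa()` implements Shrake–Rupley with test points
  from a deterministic golden-spiral lattice (no RNG anywhere in the
  surface code, so values are bit-reproducible). Defaults: probe 1.4 Å,
  960 points per atom, vdW radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å and
  1.80 Å for anything else. Buried area between two groups is reported in
  both conventions — the PISA-style interface area
  $\Delta\mathrm{SASA}/2$ (primary) and the un-halved $\Delta$ — because
  published "buried area" figures do not always state which was used.
* **Polar contacts** — hydrogen bonds are heavy-atom N/O pairs within
  3.5 Å (no angle term and no hydrogen placement: maps at typical
  cryo-EM resolution carry no hydrogens, so the distance-only criterion
  is the reproducible floor), annotated side-chain vs main-chain from the
  atom name. Salt bridges pair Lys/Arg/His basic-group nitrogens with
  Asp/Glu carboxylate oxygens within 4.0 Å.
* **Shape** — `principal_dimensions()` reports extents along the
  principal axes of the C$\alpha$ covariance (computed on C$\alpha$ only:
  reproducible, and within the tolerance of "approximate overall
  dimensions" statements). `bend_angle()` measures the angle between
  best-fit axis directions of two residue windows flanking a named
  hinge; the hinge is an input, not auto-detected. Each window's axis is
  the principal axis of a one-turn (4-residue) moving average of the
  C$\alpha$ trace — without the smoothing, the ~100°/residue helical
  wobble tilts a literal line fit by ~2° even on an ideal helix.

## The synthetic benchmark

`generate_assembly()` builds C$\alpha$-trace chains from parametric
curves: an ideal $\alpha$-helix (rise 1.5 Å/residue, radius 2.3 Å,
100°/residue), a helix hairpin (two antiparallel arms), and an
$\alpha$-solenoid superhelix whose local helix axis follows a
superhelical path (radius 25 Å, pitch 30 Å — the scale of ARM-repeat
solenoids). Chains are placed without C$\alpha$ clashes (≥ 4 Å), with
seeded random tilts; every 7th residue is a lysine-like anchor
(crosslink geometry depends on anchor spacing, not sequence, so residue
identity is not modelled).

`simulate_crosslinks()` samples true links uniformly from anchor pairs
with ground-truth distance ≤ cutoff − margin (margin 2 Å) and decoys —
emulating FDR-level false identifications — from pairs beyond
cutoff + margin, in a binomial number averaging
$n_{\text{true}} \cdot r/(1-r)$ so decoys are a fraction $r$ of the set.
Links carry only the residue pair plus a synthetic FDR (true
$U[0, 0.01]$, decoy $U[0, 0.05]$). `perturb_pose()` scrambles the mobile
chain by a recorded random rigid motion, creating a docking problem with
known ground truth.

The default benchmark is a 120-residue solenoid scaffold with a
30-residue hairpin body docked at its channel — a compact core at the
cleft of a wrap-around scaffold, the geometry in which crosslinks to a
flexibly attached subunit are most informative, with link directions
spanning most azimuths. Benchmarks on this preset run in seconds
(50 restarts ≈ 3 s on one core); the test suite uses 20-replicate
recovery experiments at that size.

What the simulator does *not* emulate: side chains (anchors are
C$\alpha$ sites), realistic MS score distributions, under-crosslinked
surfaces, mono-links, or conformational flexibility within a body.
Passing recovery benchmarks therefore show that the search and scoring
machinery behaves correctly under the stated noise model — not that any
particular real assembly is determined to the same precision.

## Numerical choices and degenerate inputs

* All tie-breaks are deterministic: duplicate crosslinks keep
  first-occurrence order; equal docking scores rank by restart seed;
  alt-locs resolve to highest occupancy, ties first-seen.
* Coordinate descent terminates when a full sweep at step sizes below
  10$^{-3}$ Å / degrees yields no improvement (score changes below
  10$^{-6}$ are treated as converged).
* Coplanar inputs to `principal_dimensions()` are allowed (third extent
  ~0); superposition requires ≥ 3 non-collinear points and errors
  otherwise.
* Multi-model coordinate files reduce to the first model with a warning;
  hydrogens and waters are dropped everywhere.
* Unmapped crosslink ends (residues outside every mapped construct
  range) are a counted status, never a silent drop; the classification
  conserves `inter + intra + unmapped = total`. An `ambiguous` class is
  not emitted: with classification keyed on protein identity, a link is
  intra-subunit exactly when both ends name the same protein, which
  leaves nothing in between.

## Pipeline and reproducibility

`run_pipeline()` chains simulate (or load) → classify → dock →
characterise, writing TSV tables, ranked PDB poses and a run log. One
master seed fans out to per-stage seeds derived from the stage name, so
stages can be rerun independently yet bit-identically; rerunning a config
reproduces every output byte-for-byte. A thin command-line front end over
the same functions ships in `inst/scripts/xlassemble`.

```{r, eval = FALSE}
library(xlassemble)
res <- run_pipeline(demo_config(out_dir = "run1", seed = 42))
res$scoreboard
res$characterisation$recovery_rmsd
```

## Known limitations

* Restraints are upper bounds only: localisation precision is set by the
  link slack distribution (see above), so recovered poses should be read
  as a proximity statement, not an atomic placement.
* The mobile body is one rigid unit; internal flexibility and disordered
  regions are out of scope (links into unresolved regions are reported,
  not scored).
* The clash term is a C$\alpha$–C$\alpha$ count at 3 Å, permissive by
  design for speed; it does not prevent shallow interpenetration of
  C$\alpha$ traces the way an all-atom van der Waals term would.
* SASA on C$\alpha$-only synthetic models measures trace surfaces, which
  are smaller than all-atom surfaces; comparisons should stay within one
  representation.
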