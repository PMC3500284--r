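---
title: "Assembling protein topologies from idealized secondary structure elements"
author: "sseFold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling protein topologies from idealized secondary structure elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sseFold)
```

## The problem and the model

De novo structure prediction methods that fold a continuous chain sample
local contacts efficiently but struggle with the non-local contacts that
define large and complex topologies: every long-range contact couples
many backbone dihedrals.  sseFold takes the alternative route of
*assembling* a protein from its secondary structure elements (SSEs).
Helices and strands are treated as rigid, idealized bodies; flexible
loops are excluded from the search entirely and only rebuilt afterwards.
Because the chain is deliberately discontinued, two elements far apart in
sequence can be placed next to each other in a single move, which is
exactly what sampling a high-contact-order topology requires.

A model is therefore an ordered set of placed SSEs over one sequence
(class `ProteinModel`).  Each SSE carries idealized backbone coordinates
(N, CA, C, O and CB per residue, with a pseudo-CB at the HA2 position
for glycine) and a rigid body frame mapping its canonical template into
space.  Candidate SSEs come from an `SSEPool` built from three-state
secondary structure predictions; pools may contain overlapping entries
and several lengths for one region, and the search decides which
variants to use.

## Idealized geometry

The canonical templates are built from internal coordinates with
textbook values: bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329 A;
backbone angles 111.0/116.5/121.7 degrees; helix dihedrals
phi = -57, psi = -47; strand dihedrals phi = -135, psi = +135; omega
fixed at 180.  With this geometry a helix built forward from the
dihedrals has 3.6 residues per turn and a rise of about 1.55 A per
residue (the often-quoted nominal value is 1.50 A; the ~3% difference is
a property of the chosen textbook parameters, and the package asserts
the value its own construction actually produces).  A strand extends
about 3.45 A per residue.  The canonical frame places the CA centroid at
the origin and the element axis along +z (for helices the exact rotation
axis recovered from second differences of the CA trace, for strands the
dominant principal axis), with the N-terminus at negative z.  Rigid
placement then reduces to one rotation + translation per element, and an
element's axis is read directly off its body frame.

## The composite energy

Models are scored with a twelve-term composite energy (arbitrary energy
units).  The term inventory is: amino acid clash, amino acid pair
distance, amino acid solvation, SSE pair clash, SSE packing, strand
pairing, loop length, loop closure, radius of gyration, one secondary
structure agreement term per prediction method, and contact order.  The
functional forms are deliberately simple, documented stand-ins (the
inventory, not any specific histogram potential, is what the protocol
needs); every constant is exposed in the configuration:

* **aa_clash** - quadratic penalty (10 units/A^2) for CB pairs in
  different SSEs closer than 3 A; **sse_pair_clash** penalizes axis
  segment distances below 7.0 (helix-helix), 6.0 (helix-strand) and
  4.0 A (strand-strand).
* **sse_packing** - a negative well of width 2 A centered at the ideal
  packing distance (9.5 A helix-helix, 10.0 A helix-strand), scaled by
  `0.5 + 0.5 |cos(angle between axes)|` so aligned (parallel or
  antiparallel) packing is most favorable.  **strand_pairing** is a
  negative well on the mean nearest CA-CA distance between two strands,
  centered at 4.75 A with width 1 A.
* **loop_length** - for each sequence-adjacent SSE pair the chain-break
  distance per `sqrt(nLoop + 1)` above 2.5 A is penalized
  quadratically; **loop_closure** adds a flat 1000-unit penalty whenever
  the break exceeds `2.56 (nLoop + 1) + 2.0` A, the span of a fully
  extended loop, making unclosable arrangements effectively forbidden.
* **radius_of_gyration** - squared relative deviation of the CA radius
  of gyration from `2.2 N^0.38` A.
* **aa_pair_distance** - Kyte-Doolittle hydrophobicity-product
  attraction for CB pairs within 12 A at sequence separation >= 5;
  **aa_solvation** - a bounded neighbor-count potential,
  `-h tanh((nc - 13)/4)` with `nc` the number of CBs within 10 A:
  burying hydrophobics is rewarded and burying polars penalized, and
  the `tanh` saturation prevents unbounded rewards for over-collapse.
  The reference count of 13 was chosen once from the observed neighbor
  counts of buried versus exposed residues in designed bundles.
* **ss_agreement** - per prediction method, `-log p(assigned state)`
  summed over all residues; residues not represented in the model (the
  unfolded part) are scored as coil, and contribute a flat zero
  solvation reference, so adding an SSE competes fairly against leaving
  the region unmodeled.
* **contact_order** - squared deviation of the model's relative contact
  order (all contacts at separation >= 1, CB within 8 A, normalized by
  the full sequence length) from 0.3, in units of 0.15; a mild push
  toward non-local structure.

All weights default to 1.  The total is rigid-body invariant by
construction and equals the weighted sum of terms.

## Moves and the move set

The registry implements six categories - add, remove, swap, single-SSE,
SSE-pair and domain moves - with helix/strand/sheet specializations
(about 29 behaviors, covering every named move of the protocol:
`add_strand_next_to_sheet`, `sheet_pair_strands`, `add_sse_short_loop`,
`add_sse_next_to_sse`, `strand_translate_z_small`, resizing, splitting,
sheet shuffling/flipping/dividing, hinge rotations and more).  Large
amplitudes (translations up to 8 A, rotations up to 90 degrees) define
the assembly stage; small amplitudes (1.5 A / 15 degrees) the
refinement stage.  Resizing an SSE by one residue at a terminus is the
only move family used in both stages.  Sheets are detected by chaining
strands whose mean pairing distance is below 6 A and taking the
transitive closure.

Move-set weights are assigned per category (assembly: add 0.25, remove
0.05, swap 0.10, single-SSE 0.30, SSE-pair 0.15, domain 0.15;
refinement: single-SSE 0.50, SSE-pair 0.25, domain 0.15, resize 0.10),
split equally among a category's moves and renormalized.  Weights are
initialized from the pool content: strand/sheet moves get probability
zero for all-helix pools, helix-domain moves for all-strand pools.  An
inapplicable move drawn during the search counts as a *skipped* step
and consumes no energy evaluation.

## The Monte Carlo engine

Each model starts from a single randomly drawn pool SSE at the origin
and undergoes two minimizations.  The assembly stage stops after 5000
steps or 1000 consecutive steps without improvement; refinement after
2000 steps or 400 consecutive non-improving steps (accepted, rejected
and skipped steps all count as non-improving).  Every step draws a move,
scores the proposal and applies the Metropolis criterion **against the
energy of the best model observed so far**: downhill-from-best proposals
are `improved` (and replace the best model), uphill proposals are
`accepted` with probability `exp(-(E - E_best)/kT)` (the working model
moves on but the best is kept), and `rejected` steps reset the working
model to the best.  This best-anchored bookkeeping is unconventional but
is the engine's defining design; a flag restores the conventional
last-accepted comparison for experimentation.  A skipped step changes
nothing.

The temperature starts at 500 (k = 1, so temperatures are in energy
units) and adapts every 10th step: the cumulative acceptance ratio
(improved + accepted over non-skipped steps) is compared with a target
that falls linearly from 0.5 at the start to 0.2 at the end of the
stage, and the temperature is multiplied by 1.05 (ratio below target) or
0.95 (at or above target), clamped to [1e-3, 1e6].  Ties take the
cooling branch.  Because the comparison is cumulative, a stage that
opens hot relaxes toward the end target rather than tracking the
schedule pointwise; the controller test asserts exactly that behavior.

## Loop building

After assembly, loops are rebuilt in four stages.  (1) Every SSE is
trimmed by one residue per side (elements already at their minimum
length are spared) to make closure easier.  (2) Missing residues are
grown with (phi, psi) drawn from analytic Ramachandran tables - Gaussian
mixtures over the beta, alpha-R and alpha-L basins, with broader,
partially mirrored basins for glycine and a restricted phi for proline.
Interior loops are grown stepwise from the N-anchor: per residue a
handful of Ramachandran draws are tried and the draw that keeps the
downstream anchor within comfortable reach of the remaining residues is
kept; 20 such candidate loops are scored by clash plus closure bias and
the best is retained.  Terminal tails grow outward without a closure
target.  (3) Cyclic coordinate descent closes each interior loop: the
upstream psi, each loop residue's phi and psi, and the downstream
anchor's phi are visited in randomized order, each set to the
closed-form angle minimizing the RMSD of the mobile downstream anchor
triple (N, CA, C); the per-dihedral optimality makes the anchor RMSD
non-increasing within every sweep.  Sweeps stop at an anchor RMSD of
0.08 A or after 200 sweeps, with a short post-convergence polish so
closed loops re-enter the machinery safely inside the threshold.
(4) `forceClose` handles stubborn loops: first by continuing the
descent, then by re-growing with fresh dihedrals up to 5 rounds; a loop
that still cannot close is flagged with its final distance rather than
raising an error.

Pure CCD at the default 200-sweep budget closes about four of five
8-residue/12 A fixtures - coordinate descent has a long convergence
tail, which is also why the original algorithm relies on restarts - and
the force-close rounds take the pipeline to essentially complete
closure.  SSE atoms are never moved by any loop-building stage.

## Pools and their evaluation

`initialPool` assigns each residue its argmax state per prediction
method, demotes helix/strand calls below probability 0.5 to coil, turns
maximal runs into entries, drops helices shorter than 5 and strands
shorter than 3 residues, and unions the methods.  `refinePool` runs a
1000-step greedy Monte Carlo descent per method (single-residue state
flips and SSE divisions, improvements only) on the agreement score
`-log p(assigned state)` (probability floor 1e-4).  Pool quality
against a native assignment is measured by Q3 (a residue covered by
both helix and strand entries resolves to the state with higher
predicted probability, or helix when no prediction is supplied),
percent of native SSEs found (>= 1-residue same-type overlap; unmatched
native SSEs are excluded from the shift average), and the average
boundary shift `|dFirst| + |dLast|` of best-matching entries.

## The synthetic toy generator

`generateToyProtein` builds designed natives at desk scale.  The default
three-helix bundle uses three 14-residue helices on an equilateral
triangle of 10 A side with antiparallel neighbors and 4-residue loops
(about 50 residues) - the geometry of natural three-helix bundles.
Each element's spin about its own axis is chosen deterministically so
consecutive chain ends face each other (tight, closable loops), with a
small per-element offset that keeps same-direction helices from being
exact translates (exact translational symmetry would place many atom
pairs precisely on distance cutoffs).  Sequences are designed
amphipathically: positions whose CB points toward the bundle core draw
from hydrophobic types, exposed positions from polar types, loops from
coil-formers - the composition real bundles have, and the reason the
solvation and pair terms genuinely prefer the designed native.  The
generator emits the SSE-only native, a CCD-closed complete native,
perfect predictions (p = 0.95 on the true state for both method slots),
the native pool and a DSSP-style assignment, all deterministic per seed.

What the toy data do *not* emulate: real predictions are noisy and
systematically biased (the pool statistics of the benchmark tables show
Q3 around 70-80%), native elements deviate from ideal geometry (bent
helices, twisted sheets), and real sequences are not perfectly
amphipathic.  Passing the desk-scale experiments therefore demonstrates
that the protocol machinery works as specified, not that real proteins
of arbitrary topology will fold to these accuracies.

## Numerical choices and degenerate inputs

Probability floors (1e-4) keep agreement scores finite; prediction rows
off by up to 0.02 are renormalized, larger deviations are errors.
RMSD100 is undefined for 13 or fewer residues (its denominator turns
non-positive) and raises an error.  Zero-contact structures make the
contact order undefined (error in the metric; the energy term reads the
relative contact order of such a model as 0).  The temperature tie rule,
the strict inequalities of the native-like counts (RMSD100 < 8.0 A,
contact recovery > 20%), and the skipped-step exclusions from the
acceptance-ratio denominator are all fixed, documented tie-breaks.
Kabsch superposition forbids reflections (proper rotations only).

## Problem sizes

The shipped experiments use desk-scale sizes chosen as the package's
own defaults: the 50-residue toy bundle, 50 models per folding
repetition with 10 seeded repetitions in the test suite (3 in the
acceptance script), 100 seeded loop-closure fixtures in the tests (30
in the script), and 1e5 draws for Metropolis rate checks.  A folding
repetition of 50 models takes on the order of 1.5 minutes on one CPU.

## Known limitations

SSEs stay rigid: no backbone bending within elements, so strongly
curved sheets and bent helices cannot be reproduced exactly.  Side
chains beyond CB, membrane environments, model clustering and
atomic-detail refinement are out of scope.  The energy stand-ins share
the inventory but not the histogram shapes of knowledge-based
potentials derived from structure databanks, so absolute energies are
not comparable with other software; only within-run comparisons are
meaningful.
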