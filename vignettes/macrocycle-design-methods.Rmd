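---
title: "Designing membrane-permeable peptide macrocycles with cycpep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing membrane-permeable peptide macrocycles with cycpep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycpep)
```

## The problem

Head-to-tail cyclized peptides of 6-12 residues can cross lipid membranes
passively when every backbone amide NH is engaged in an intramolecular
hydrogen bond: exposed donors pay a large desolvation penalty in the
membrane.  `cycpep` implements, at desk scale, the computational pipeline
for designing such macrocycles: analytic closure of cyclic backbones,
hydrogen-bond-driven sequence design over a hydrophobic L/D alphabet with
backbone N-methylation, energy-landscape structure prediction, torsion-bin
clustering of designs under cyclic and mirror symmetry, genetic-algorithm
multistate design of conformation-switching ("chameleonic") macrocycles,
and apparent-permeability (PAMPA) computation from transwell concentration
measurements.

## Backbone model and kinematic closure

Backbones are built from internal coordinates (natural-extension reference
frames) with a single ideal-geometry table (`ideal_geometry()`).  The
peptide-bond constants - C-N 1.328685 Å, CA-C-N 116.199993°, C-N-CA
121.69997° - are used for *every* peptide bond, so the ring-closure bond is
indistinguishable from any other bond; the remaining bond lengths and
angles are standard amide values (Engh-Huber-like).  Since only the
closure-bond constants have a published provenance, the rest of the table
is a package choice, collected in one place and never mutated at runtime.

Ring closure is solved analytically by the tripeptide (triangle)
formulation: three pivot CA atoms split the ring into three rigid bodies;
the virtual CA-CA bonds form a rigid triangle and each body keeps one
rotation `tau` about its virtual-bond axis.  The N-CA-C angle constraint at
each pivot is linear in `(cos tau, sin tau)` of the two adjacent taus, so
the system reduces to one-dimensional root finding along a driver tau.  The
solver scans a 720-point grid from all three drivers and all four branch
combinations, refines sign changes by bisection (52 halvings), and treats
tangent roots and branch-domain edges by golden-section refinement of
|residual| followed by a local polish of the six pivot torsions against the
exact closure gap.  Any real solution (there are at most 16) is therefore
recovered; the erase-and-resolve self-consistency test in the suite
verifies recovery to better than 1e-3 degrees.  `solve_closure(thorough =
FALSE)` runs a single-driver sign-change-only scan, which is what the
backbone sampler uses - when thousands of random attempts are made, any one
solution per attempt is enough.

Conformations built from torsions carry auxiliary "image" atoms (the ideal
continuation of the first residue past the last) so that building and
measuring torsions is an exact inverse pair even while the ring is open.
Scoring, by contrast, always measures torsions from the actual cyclic
atoms, which makes every energy term exactly invariant under relabeling of
the starting residue.

## Torsional surrogate potentials and the sampling table

The package deliberately does not reimplement a molecular-mechanics force
field.  The surrogate score keeps the term names and roles of the original
pipeline (fa_rep, fa_atr, hbond_sr_bb, hbond_lr_bb, rama_prepro, p_aa_pp,
omega, chainbreak, aa_composition) with documented functional forms in
arbitrary score units:

* **rama_prepro** is a flat-bottom potential: zero inside rectangular
  favourable regions of the Ramachandran map (right-handed helical box phi
  in [-140, -40], psi in [-70, 30]; strand/polyproline box phi in
  [-180, -50], psi in [100, 180] plus the wrap below -170) and growing as
  0.002 deg^-2 times the squared angular distance outside them.  D-amino
  acid tables are exact mirrors; glycine and AIB take the pointwise minimum
  of both hands.  Residues preceding proline or an N-methylated position
  use a variant whose helical box excludes psi below -30, reflecting the
  steric pressure of the next residue's N-substituent.  The backbone
  sampler draws phi/psi uniformly from exactly these boxes (union of both
  hands), so the sampling distribution is the flat bottom of the scoring
  potential - the same potential biases sampling and scoring.
* **fa_rep / fa_atr** are the repulsive and attractive branches of a
  Lennard-Jones split (well depth 0.2, cutoff 6 Å) over backbone heavy
  atoms plus one CB-centred sphere per residue whose radius encodes
  side-chain bulk (ALA 1.8 Å up to PHE 2.4 Å; glycine has none).  Pairs
  within three covalent bonds are excluded.
* **hydrogen bonds** use a distance Gaussian centred at H···O 2.0 Å (width
  0.45 Å) times clipped cosines of the N-H···O deviation from linearity
  and of the H···O=C deviation from 125°, scaled to about -1 at ideal
  geometry so that the -0.25 reporting cutoff retains its published
  meaning.  Donor-acceptor pairs within cyclic separation 2 are never
  counted; a bond is short-range when the separation is at most 4.
* **omega** is harmonic to the nearest of 0/180; **chainbreak** sums
  harmonic deviations of *all* peptide bonds from ideal geometry (for
  chains built from torsions only the closure gap contributes), with a
  stiff spring (300 Å^-2) so minimisation cannot profitably open the ring.
* **aa_composition** implements penalty tables over the deviation of a
  residue-class count from an absolute target, constant below the
  tabulated range and quadratic above it.

Three weight sets are built in: `standard`, `closure_selection` (fa_rep
0.1, fa_atr 0.2, both hbond terms 2.0, rama_prepro 0.45, omega 0.4,
p_aa_pp 0.6 - used to pick among closure solutions) and
`hbond_upweighted` (both backbone hydrogen-bond weights at 5.0, i.e. a
five-fold upweighting, used in the first design round).

Every term is exactly invariant under mirroring and cyclic relabeling;
the test suite asserts this to 1e-9 on random conformations of every
length.

## Backbone sampling and acceptance

`sample_cyclic_backbones()` repeats: pick a random anchor; place three
pivots roughly equally spaced (offsets 1, n/2+1 and n-1 from the anchor,
the layout of the published 10-mer configuration); draw all non-pivot
phi/psi from the flat-bottom table; set omegas trans (with an optional cis
probability at proline/N-methyl positions only); solve the closure; filter
solutions by a pivot Ramachandran check (pseudo-energy at most 2), a
backbone bump check (no two backbone heavy atoms separated by more than two
bonds closer than 2.6 Å), and a minimum count of internal hydrogen bonds;
keep the lowest-energy survivor under `closure_selection` weights.  Both
published hydrogen-bond minimum policies are available and deliberately not
reconciled: the length schedule (1 for 6-7 residues, 2 for 8-9, 3 for 10
and up; the default) and a flat minimum of two.  Acceptance rates are
intentionally low - a few per cent at best, falling with both length and
the hydrogen-bond minimum - which mirrors the reference pipeline, where a
thousand closure attempts per accepted backbone are routine and overall
sampling runs into the millions of conformations.

With the same seed, `mirror = TRUE` negates the sampled torsion stream, so
running the sampler on the mirrored sequence yields the exact mirror
ensemble with identical energies.

## Sequence design and N-methylation

Positions with positive phi admit only D-amino acids, negative phi only
L-amino acids (phi exactly 0 counts as negative - a measure-zero,
deterministic tie-break); the alphabets are hydrophobic-only (A, V, L, F,
I, P and their D counterparts).  AIB is supported by the data model but
excluded from the default alphabet.  Design is simulated annealing over
per-position identities (geometric temperature schedule 3 to 0.05 over 250
steps per residue by default) against the same surrogate score evaluated
through a precomputed context, so each proposal costs only scalar
arithmetic; on small alphabets the annealer provably reaches the
exhaustive-search optimum (asserted in the suite).

After each design round, every backbone NH that donates no internal
hydrogen bond is *remedied*: if its phi/psi lies in the proline-compatible
bin (phi in [-100, -40] with psi in [-70, 10] or [110, 180], mirrored for
the D hand) it becomes proline of the matching hand, otherwise it becomes
the N-methylated variant of its identity.  The proline branch is tried
first: proline removes the donor without adding the synthetic burden of an
N-methyl group, and a position that later re-qualifies can still be
N-methylated in the next round, whereas the converse order would
methylate positions that proline could have fixed.  The full protocol runs
three rounds (`hbond_upweighted`, then `standard` twice) with remedies in
between and ends with torsion-space minimisation under the chainbreak
term - the stand-in for Cartesian relaxation, keeping closure enforced
without a Cartesian minimiser.  Records then carry pass/fail verdicts:
length-scheduled hydrogen-bond minimum, at most five N-methyls, zero
unsatisfied NH, no oversaturated acceptor (a carbonyl accepting more than
two bonds; the per-acceptor maximum is not published, two sp2 lone pairs
are assumed, and the value is configurable).  Most protocol runs fail
these filters, as they should.

## Landscapes, clustering and chameleonic design

`predict_landscape()` resamples closed backbones for a fixed sequence,
relaxes and scores each, and reports energy against backbone RMSD to the
design model, always including the local minimisation of the design itself
(labelled LE_0).  RMSD is a proper-rotation least-squares superposition
over N, CA, C, O and the N-methyl carbon CN where both structures carry
one; mirror comparisons reflect explicitly and then superpose properly,
and cyclic-permutation credit minimises over all relabelings.
`energy_based_cluster()` is greedy leader clustering: repeatedly take the
lowest-energy unassigned structure as a centre (1.0 Å default radius; the
published legends cluster the 250 or 500 lowest structures) and label
clusters LE_1, LE_2, ... by centre energy rank.  The funnel gap dE is the
energy of the best point farther than 2.0 Å from the design minus the best
point within it; the 2.0 Å split is a package choice since the reference
figures show dE graphically only.

Multistate design follows the published genetic algorithm exactly in its
scoring: threaded energies eA and eB on two fixed backbones, fitness
`(-5*|eA-eB|) - (eA-eB)`, which is bounded above by zero and maximal
exactly at eA = eB (writing D = eA-eB the fitness is -4D for D < 0 and
-6D for D > 0); variants must keep both energies below 10 score units and
the gap below 6.  "Best" therefore means maximal fitness, with ties broken
by lower eA+eB and then lexicographically, for determinism.  The ceilings
apply to total per-backbone energies (whether the published ceiling was
total or per-residue is not stated; total is used and configurable).
Reference-scale parameters (population 1000, survivors 500, 1000
generations) are available via `ga_params_reference()`; the constructor
defaults are desk-scale (60/30/50) because threading with relaxation at
reference scale is cluster-sized work.  Initial variants carry 1-3 random
point mutations each.  `switch_scan()` mutates every position to every
allowed identity (chirality and N-methylation preserved; proline excluded
both ways since it alters the donor pattern), relaxes, predicts a reduced
landscape and reports mutants with two or more states inside the
5-score-unit isoenergetic threshold, annotated by whether the states
differ in their cis/trans signature.

## Torsion-bin strings

Each residue maps to one of six bins: A (helical, phi <= 0), B (strand,
phi <= 0), X/Y (their exact mirrors) and O/Z for residues followed by a
cis peptide bond (|omega| < 90°; O for phi <= 0, Z for phi > 0).  The A/B
boundary is the half-open psi interval (-80, 50], chosen to contain the
canonical helical region and exclude the strand region; it and the cis
threshold are configurable because neither is published.  Cluster identity
is the lexicographic minimum over all rotations of the string and of its
mirror-mapped image.  Strings are *not* reversed: a physical mirror does
not change chain direction, and the published symmetry group is exactly
"circular permutation or mirror inversion".  The suite checks the
canonicalization against brute-force orbit enumeration for a thousand
random strings.

## PAMPA

`papp()` evaluates the published mass-balance and permeability formulas:
`Ce = (C_D V_D + C_A V_A) / (V_D + V_A)` and
`P_app = -ln(1 - C_A/Ce) / (A (1/V_D + 1/V_A) t)` in cm/s.  The one-line
source formula is ambiguous as typeset; the single-denominator grouping is
fixed by dimensional analysis (cm² · cm⁻³ · s in the denominator yields
cm/s).  Default well volumes are 300 and 250 µL (the published loading);
the filter area has no published value and is a required argument.  No
membrane-retention correction is applied (none is described).
Classification is inclusive upward at the published thresholds: 1e-7
(permeable), 1e-6 (significant), 1e-5 cm/s (high, the cell-assay bar).

```{r pampa-example}
m <- pampa_measurement(C_A = 1, C_D = 9, t = 16 * 3600, A = 0.3)
r <- papp(m)
c(C_e = r$C_e, P_app = r$P_app)
r$class
```

## What the synthetic fixtures do and do not show

All test inputs are generated in code: polyglycine rings closed by the
solver, motif-seeded fixture rings (`make_fixture_ring()`), and synthetic
hydrogen-bond geometries built atom-by-atom.  These exercise the geometry,
symmetry and bookkeeping contracts exactly, but they are not experimental
structures: passing tests demonstrate internal consistency of the pipeline
(closure to 1e-4 Å, mirror/permutation invariance to 1e-9, recovery of
erased torsions to 1e-3°), not agreement of the surrogate score with any
physical force field, and not membrane permeability of any particular
design.  Quantities tied to published constants (closure-bond geometry,
composition penalties, weight sets, fitness formula, PAMPA formulas and
thresholds) are reproduced exactly.

## Problem sizes used by the shipped tests

The suite runs at reduced, fixed sizes chosen for a single-CPU run: the
closure self-consistency check uses four to six recovered rings per length
(6-12) rather than hundreds; energy invariance uses twelve random
conformations per length; the design-protocol contract designs up to two
backbones per length sampled with the published closure-stage minimum of
one hydrogen bond and 250 attempts per length; landscape and switch-scan
tests use a handful of samples with shallow minimisation.  The GA oracle
runs the full 81-sequence exhaustive comparison.  Scaling these numbers up
only increases coverage of the same properties.

## Known limitations

* The surrogate score is not a calibrated force field; energies are
  comparable within this package only.
* Side chains are single CB-centred spheres: no rotamers, no aromatic
  geometry, no side-chain hydrogen bonding (the design alphabet is
  hydrophobic, which limits the damage).
* N-methyl groups are a single CN pseudo-atom; the freely rotating methyl
  hydrogens of the reference implementation are not modelled.
* Torsion-space minimisation with numerical gradients is shallow at desk
  scale; landscapes are coarse relative to the reference pipeline's
  10^5-10^6 relaxed samples.
* Backbone sampling acceptance falls steeply with the hydrogen-bond
  minimum; long macrocycles (10-12 residues) need attempt counts beyond
  what the shipped tests run.
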