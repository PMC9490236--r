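# cycpep

Desk-scale computational design of membrane-permeable peptide macrocycles
in R.

Head-to-tail cyclized peptides of 6–12 residues cross lipid membranes
passively when every backbone amide NH donates an intramolecular hydrogen
bond; exposed donors keep a macrocycle out of the membrane. `cycpep`
implements the full design loop around that principle for people who want
to study or extend it without a molecular-modelling cluster:

* **Kinematic closure** — analytic solution of the six pivot torsions that
  close an N-to-C cyclic backbone with exact peptide-bond geometry at the
  junction (C–N 1.328685 Å, flanking angles 121.69997° / 116.199993°),
  via the tripeptide triangle formulation.
* **Backbone sampling** — closure attempts with non-pivot φ/ψ drawn from a
  flat-bottom, mirror-symmetric Ramachandran table, filtered by a pivot
  Ramachandran check, a bump check, and a length-dependent minimum of
  internal backbone hydrogen bonds (1 for 6–7 residues, 2 for 8–9, 3 for
  ≥10).
* **Sequence design** — simulated annealing over a hydrophobic L/D
  alphabet (D identities at positive-φ positions only), with composition
  penalties, followed by conversion of unsatisfied NH donors to proline or
  their N-methylated variants, iterated over three rounds.
* **Structure prediction** — energy-vs-RMSD landscapes for a fixed
  sequence, symmetry-aware backbone RMSD (N, CA, C, O, CN), greedy
  energy-based clustering with `LE_X` labels, and detection of
  near-isoenergetic alternative states (< 5 score units) that differ by a
  cis/trans peptide-bond flip.
* **Torsion-bin strings** — per-residue classification into
  `A/B/X/Y/O/Z`, with cluster identity defined as the lexicographic
  minimum over all cyclic rotations and the mirror-mapped image
  (`canonical_form("XYABOX")` is `"AABXYZ"`).
* **Multistate (chameleonic) design** — a genetic algorithm over point
  mutations that drives a sequence toward two isoenergetic backbones,
  scored by the fitness `(−5·|eA−eB|) − (eA−eB)` under per-backbone (10)
  and gap (6) energy ceilings.
* **PAMPA permeability** — `Ce = (C_D·V_D + C_A·V_A)/(V_D+V_A)` and
  `P_app = −ln(1 − C_A/Ce) / (A·(1/V_D + 1/V_A)·t)` in cm/s, classified
  at the 1e-7 / 1e-6 / 1e-5 cm/s thresholds.

The scoring function is a documented surrogate with the term structure of
the original pipeline (fa_rep, fa_atr, hbond_sr_bb, hbond_lr_bb,
rama_prepro, p_aa_pp, omega, chainbreak, aa_composition) in arbitrary
score units — see the methods vignette
(`vignettes/macrocycle-design-methods.Rmd`) for every functional form and
constant.

## Worked example

Sample closed cyclo-(Gly)7 backbones, design one, and inspect it:

```r
library(cycpep)

seq <- macrocycle_sequence(rep("GLY", 7), rep("achiral", 7))
backbones <- sample_cyclic_backbones(seq, n_attempts = 300, rng_seed = 3)
length(backbones)
#> [1] 15

rec <- run_design_protocol(backbones[[4]], rng_seed = 100)
rec
#> design record: pi*a*f*Pf*a
#>   hbonds 1, N-methyls 4, unsatisfied NH {}
#>   filters: min_hbonds ok, max_n_methyl ok, no_unsat ok, oversat ok, all ok

binstring(rec$conformation)
#> [1] "XYYYBXY"
canonical_form(binstring(rec$conformation))
#> [1] "ABABBBY"
```

The printed record reads: sequence in one-letter code (lower case = D
residue, `*` = N-methylated), one internal backbone hydrogen bond
(meeting the minimum of 1 for a 7-mer), four N-methyls (≤ 5), and no
unsatisfied NH donors — the design passes every filter.  The torsion-bin
string `XYYYBXY` canonicalizes to `ABABBBY`, the cluster key under cyclic
rotation and mirror inversion.

Permeability from a PAMPA measurement (area in cm², time in seconds,
volumes default to the 300/250 µL loading):

```r
r <- papp(pampa_measurement(C_A = 1, C_D = 9, t = 16 * 3600, A = 0.3))
r$P_app
#> [1] 1.628286e-06
r$class
#> [1] "significant"
```

A thin command-line wrapper is installed as `exec/cycpep` with
subcommands `sample-backbones`, `design`, `predict`, `binstring`,
`cluster`, `ga`, `switch-scan`, `papp` and `rmsd`.

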