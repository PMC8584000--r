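---
title: "Designing drug-like molecules with a docking surrogate and CSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing drug-like molecules with a docking surrogate and CSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Structure-based de novo design wants molecules that (i) dock well
against a target receptor, (ii) look like oral drugs, and (iii) stay
close to a known active chemotype. Docking itself is far too slow to sit
inside a global optimizer that scores tens of thousands of candidates,
and for most targets there is too little assay data to train an
activity model. `dockgen` follows the now-standard answer: run a docking
campaign once, train a fast surrogate that maps a SMILES string to a
predicted docking energy, and let a combinatorial global optimizer work
against the surrogate.

The package implements the full loop with three interlocking pieces:
featurization, a docking-energy surrogate, and conformational space
annealing (CSA) over SMILES strings, plus a deterministic synthetic
test-bed (fragment generator + pseudo-docking oracle) so that every
experiment in the test suite reproduces bit-for-bit on any machine.

## Featurization

Every molecule is canonicalized with Open Babel (via ChemmineOB) and
encoded as a fixed 2232-long vector:

* positions 1–2048: a hashed **linear path fingerprint**. All simple
  paths of 1–7 bonds are enumerated on the molecular graph; each path's
  direction-canonical label string (element symbols, lowercase for
  aromatic atoms, with bond-order symbols) is hashed (FNV-1a) and sets
  two bits. This fingerprint also drives every Tanimoto similarity in
  the package (the objective's similarity term and the CSA bank
  cutoff). Path enumeration lives in C++ (`src/pathfp.cpp`).
* positions 2049–2215: **167 MACCS-key slots**. The MACCS set has 166
  defined keys, conventionally stored with a reserved slot 0 that is
  always zero; Open Babel's MACCS implementation supplies keys 1–166.
  The 167-slot convention is what makes the total 2048 + 167 + 17 = 2232.
* positions 2216–2232: **17 molecular descriptors**, in fixed order:
  H-bond donors and acceptors, rotatable bonds, ring count, radical
  centers, heteroatoms, heterocycles, Lipinski acceptors (N+O) and
  donors (H on N/O), aromatic carbocycles and heterocycles, amide
  bonds, aliphatic carbocycles and heterocycles, fraction of sp³
  carbons, Labute approximate surface area (Å²) and topological polar
  surface area (Å²).

Open Babel supplies molecular weight, logP (atom-contribution), TPSA
and donor/acceptor counts; graph-derived counts (rings, radicals,
heterocycle classes, sp³ fraction) are computed from the kekulized bond
table of Open Babel's MOL export together with the SMILES atom tokens.
Ring perception selects a smallest-rings set: the cyclic core is
isolated by leaf pruning, the shortest cycle through every core bond is
found by BFS, and rings are accepted smallest-first until the
cyclomatic count is reached (rings are classified up to size 12; larger
macrocycles still count toward the ring total). The Labute surface area
is computed from the published sphere-overlap approximation with Bondi
van der Waals radii and covalent-radius bond lengths; values are on the
usual Å² scale but are not numerically identical to other toolkits'
implementations — within this package it only needs to be
self-consistent.

Radical detection deserves a note: Open Babel's MOL export does not
carry radical flags, so radical electrons are inferred per bracket atom
as `effective_valence − bracket_H − bond_order_sum`. This reproduces
the expected counts on, e.g., `[CH3]` and `[CH2]CC`.

**QED.** Drug-likeness uses the weighted-geometric-mean desirability
construction over eight properties (MW, logP, acceptors, donors, PSA,
rotatable bonds, aromatic rings, structural alerts), with the published
asymmetric-double-sigmoid parameters and mean weights. The 116
structural-alert SMARTS are matched with Open Babel; the two
component-disconnected patterns in the published list (≥ 4 fluorines;
≥ 3 ester groups) are expressed as match-count rules with identical
meaning. Because logP, acceptor counts and SMARTS semantics follow Open
Babel rather than other toolkits, absolute QED values can differ a few
hundredths from other software; orderings of clearly drug-like vs
non-drug-like molecules are preserved (the suite checks this).

## The surrogate

The predictor is a multilayer perceptron `2232 → 1024 → 528 → 1` with
ELU activations, normalization of the input vector, dropout 0.3 after
each hidden activation, Adam (learning rate 0.001) on mean-squared
error, trained for a configurable number of epochs (200 by default;
the desk-scale experiments use 50). Batch size defaults to 256.

Two numerical choices matter and are deliberate:

* **Input normalization uses dataset statistics.** Normalizing each
  batch by its own statistics amplifies rare fingerprint bits by
  enormous, batch-dependent factors (a bit present once in a 256-row
  batch is scaled by ~16, and differently in every batch). We compute
  the mean and variance once over the training set, use them in both
  training and evaluation, and keep them in the checkpoint. Evaluation
  is therefore exactly deterministic.
* **Zero-variance features are masked, not amplified.** A fingerprint
  bit never seen in training carries no information; dividing by
  `sqrt(0 + eps)` would scale it by ~316 at prediction time and wreck
  generalization to new molecules. Features with zero training variance
  are mapped to 0. Before this masking, held-out correlation on the
  synthetic recovery task was ~0.37; with it, ~0.97 — the difference is
  entirely extrapolation noise from never-seen bits.
* A small decoupled weight decay (1e-4) on the dense weight matrices is
  on by default; it is cheap insurance against bit-memorization at
  desk-scale sample sizes and has no measurable effect on the recovery
  task's correlation.

The spec-level training protocol (Adam, lr 0.001, dropout 0.3, MSE,
fixed epoch count, 80/20 split) is otherwise unchanged. Checkpoints
(`save_surrogate()`) carry architecture, weights, normalization
statistics and a feature-layout stamp, so predictions reproduce across
sessions.

## The objective

For a molecule $m$ with predicted docking energy $D(m)$ (kcal/mol),
drug-likeness $Q(m) \in [0,1]$ and Tanimoto similarity $S(m; m_{ref})$
to a reference molecule:

$$R(m) = \omega_D \, [D(m) + P(m)] - \omega_Q\, Q(m) - \omega_S\, S(m; m_{ref})$$

and the optimizer **minimizes** $R$: good docking energies are negative
and $Q$ and $S$ enter negatively, so the best molecules have the lowest
objective values. (One passage of the source method's description
speaks of preferring "higher" objective values; the weight-sweep
behavior and the reported "lowest objective value" selections are only
consistent with minimization, which is what we implement.)

$P(m)$ is the Lipinski penalty: 1000 kcal/mol is added to the docking
term if MW > 500 Da **or** logP > 5, and a further 1000 if the molecule
carries radical centers. The OR reading is deliberate: the published
property profiles of generated molecules show *neither* violation ever
survives, which only the OR rule guarantees (an AND rule would let a
560 Da, logP 3 molecule through unpenalized). The radical penalty
magnitude is not stated anywhere; we reuse the same 1000 constant.
With $\omega_D = 0.03$ a penalty moves the objective by +30, two orders
of magnitude above the typical objective range (about −2 to 0), so
penalized molecules are effectively excluded while remaining scoreable.

Defaults: $\omega_D = 0.03$, $\omega_Q = \omega_S = 1$ (both terms are
already on a 0–1 scale). The reference molecule defaults to ML216, a
known inhibitor of the BLM/WRN RecQ helicases, taken from its public
chemical record; every function accepts any other reference SMILES, and
the test suite uses its own fixture reference throughout.

## The CSA optimizer

CSA keeps a **bank** of `n_bank` distinct molecules (default 500,
desk-scale runs use 30). Each iteration:

1. **Seed selection** — the `n_seed` (default 300; desk 10) best
   not-yet-used members become seeds and are flagged used; when fewer
   than `n_seed` unused members remain, all flags reset (standard CSA
   bookkeeping).
2. **Children** — per seed, 20 crossover children are generated
   (random bank partner per slot, random prefix/suffix role), then each
   of the three mutation kinds is applied to every crossover child:
   `20 × (1 + 3) = 80` targeted children per seed. Operators work
   directly on the SMILES string: crossover splices a prefix of one
   parent onto a suffix of the other, cutting only where branch
   parentheses are balanced and ring-closure digits are paired;
   mutations replace one atom symbol (aromatic symbols stay aromatic),
   remove one atom that carries no ring closure, or insert one atom
   inline or as a branch. Every candidate must parse (Open Babel);
   failures retry up to `max_operator_attempts` (50), then the slot is
   forfeited. Children are deduplicated by canonical SMILES.
3. **Bank update** — children are processed in list order. A child
   identical to a bank member is skipped. Otherwise its most similar
   bank member is located: if that similarity is **at or above** the
   cutoff, the child competes with that member (same niche); below the
   cutoff it competes with the current worst member (new niche). Either
   way the child enters only on *strict* objective improvement, so bank
   size and distinctness are invariants and the best objective is
   monotone non-increasing.
4. **Cutoff** — initialized to half the average pairwise bank
   similarity. The literal published rule keeps it there, which is the
   default (`cutoff_factor = 1`); a geometric annealing factor toward a
   floor is available but off, since only the avg/2 rule is stated.

Sequential child processing is a deliberate determinism choice (the
rule statement does not define simultaneity); the test suite pins the
exact semantics against an independent brute-force implementation on
200 randomized small instances. Everything downstream of one
`rng_seed` is bit-reproducible; per-iteration seeds are derived from it
so stages can be replayed.

## The synthetic test-bed

Real docking campaigns and compound databases are not reproducible
inside a test suite, so the package ships deterministic stand-ins:

* `generate_pool()` assembles molecules from ~46 fragments (aromatic
  carbo-/heterocycles, amide/urea/sulfonamide/ether/amine linkers,
  halogen and alkyl decorations), chaining 1–4 fragments through a
  single attachment point with automatic ring-digit renumbering. All
  outputs are valid, canonical, distinct; assembly sizes favor 2–3
  fragments so the pool sits in a lead-like MW range.
* `pseudo_docking_score()` is a deterministic energy oracle:
  heavier (saturating at 550 Da), more aromatic molecules with more
  H-bonding capability and logP near 2 score better, clipped to
  [−16.4, −0.4] kcal/mol — the energy range a docking campaign of this
  kind reports. Coefficients were chosen so a typical pool molecule
  scores −3 to −7 with ≥ 90% of molecules strictly inside the clip
  bounds. Optional Gaussian noise is available and off by default.

What passing tests do and do not show: the oracle is a smooth
five-property function, so surrogate recovery (held-out *r* ≥ 0.8 with
2000 molecules / 50 epochs) demonstrates the training machinery
learns a docking-energy-shaped signal from the 2232-vector — it says
nothing about how well a real Vina campaign can be predicted, which in
the source work required ~85k docked molecules (r = 0.94 there).
Likewise the weight-sweep and penalty properties are analogs of the
published figure-level behaviors at desk scale, not reproductions of
dataset-dependent statistics.

## Desk-scale study sizes

The acceptance script and suite use: pool 2000 / split 80:20 / 50
epochs for the surrogate; an oracle-scored efficacy run at bank 30 /
seeds 10 / 20 iterations; an oracle-scored weight sweep over
$\omega_D \in \{0.01, 0.03, 0.1\}$ at bank 30 / seeds 6 / 8
iterations (lighter but internally consistent, since only the
between-run ordering matters); a surrogate-scored validation run at
bank 100 / seeds 15 / 8 iterations, whose 100-molecule bank gives the
top-100 re-scoring statistic its full diversity; and a 250-molecule /
8-epoch /
6-iteration pipeline for the end-to-end determinism check. These sizes
were chosen as the smallest at which the behaviors of interest are
stable and visible.

## Known limitations

* Descriptor and QED values follow Open Babel's chemistry models
  (aromaticity, logP, acceptor definitions, SMARTS semantics); other
  toolkits will give slightly different numbers for the same molecule.
* The path fingerprint enumerates *linear* paths only (no branched
  subgraphs); it is not bit-compatible with any other fingerprint.
* String-level crossover and mutation can produce exotic but valid
  SMILES (including radical species, which the objective then
  penalizes); they explore locally around the bank chemotypes rather
  than sampling chemical space uniformly.
* Ring classification enumerates rings up to size 12; larger
  macrocycles count toward the total ring count but not the
  carbocycle/heterocycle splits.
* The docking adapter (`prepare_ligand()`, `dock_one()`) requires
  external binaries (`obabel`, `vina`) and is exercised in tests only
  through shipped synthetic logs and mocked engines.
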