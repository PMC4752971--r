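---
title: "Methods: chemogenomics profiling with chemoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemogenomics profiling with chemoprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chemoprofiler` is a desk-scale toolkit for navigating compound-target
bioactivity space: it standardizes heterogeneous bioactivity measurements,
organizes chemistry into scaffold trees, predicts targets by set-wise
similarity (SEA) and by per-target QSAR ensembles, annotates protein
neighborhoods, and assembles the resulting pharmacological heatmap. This
vignette documents the models, the tunable parameters, and the design
choices where the design was genuinely open.

## Bioactivity standardization

Bioactivity databases mix ten common measurement types. The package first
orients every value onto a common scale where **larger always means a
stronger interaction**:

| data types | stored unit | oriented value |
|---|---|---|
| IC50, EC50, Potency, AC50, Kd, Ki | nM | $-\log_{10}(\text{value in M})$ |
| pIC50, pKi, pEC50 | — | unchanged |
| LogKi ($\log_{10}$ molar) | — | negated |

Accepted concentration input units are M, mM, µM/uM and nM; anything else
is a rejected row with a reported count, never a guess. The orientation is
a single per-type transform table rather than post-hoc sign flips, so the
"large = strong" convention holds uniformly; the sign convention for
LogKi (negation onto the p-scale) is this package's choice, stated here
because conventions differ across databases.

Within each (target, data type) group the oriented values are z-scored
with the **sample (n−1) standard deviation**:
$z = (x - \bar{x}) / s$. Degenerate groups — a single measurement, or zero
spread — get $z = 0$ and a flag in the group statistics instead of being
excluded, so every stored interaction still renders on the heatmap. For
a two-measurement group this forces $z = \pm 1/\sqrt{2}$, a useful exact
test point. Duplicate measurements are kept as separate records; the
package deliberately does not aggregate replicates or merge z-scores
across data types into a consensus value.

## Fingerprints and similarity

Five binary fingerprint variants, all folded to 1024 bits by default:

* `path1024` — linear paths of 1–7 bonds (the Daylight convention for
  maximum path length), encoded as alternating element and bond-order
  codes, hashed direction-independently;
* `morgan_r2`, `morgan_r3` — circular environments of radius 2/3 grown
  from atom invariants (element, degree, hydrogen count, ring membership);
* `feat_morgan_r2`, `feat_morgan_r3` — the same growth over pharmacophoric
  features (donor, acceptor, halogen, ring membership) instead of element
  identity.

Hashing is a fixed polynomial hash modulo a prime below $2^{26}$, so all
arithmetic is exact in doubles and vectors are bit-reproducible across
platforms. The feature variants do not perceive aromaticity as a feature
(the graph carries kekulized/aromatic bond types but no aromatic atom
flag); donors and acceptors are approximated as N/O with and without
hydrogens. This is a deliberate simplification — the variants are meant to
span two fingerprint families for the QSAR ensemble, not to reproduce any
specific published implementation bit-for-bit.

Similarity is the Tanimoto coefficient $|a \wedge b| / |a \vee b|$,
defined as 0 for two empty vectors. Similarity search uses a **strict**
threshold (`> 0.85` by default, matching the usual "Tc > 0.85" reading);
`inclusive = TRUE` gives `>=`. Ties in the ranking are broken by compound
id so output order is total.

## Scaffold tree

Level 0 is the Murcko framework: iteratively prune terminal atoms, keep
rings and linkers, then restore atoms attached to the framework by double
or triple bonds. Each tree step removes exactly one peripheral ring.
Ring selection applies a condensed, totally ordered variant of the
classic prioritization rules:

1. prefer removing heterocycles of size 3, 5 or 6;
2. do not remove rings of 12 or more atoms while smaller rings exist;
3. minimize the number of acyclic linker bonds in the parent;
4. prefer removing rings of size 3, 5 or 6;
5. remove the ring with the fewest heteroatoms;
6. retain nitrogen over oxygen over sulfur;
7. remove smaller rings first;
8. final tie-break: lexicographically smallest parent canonical SMILES.

The published rule set also arbitrates bridged/spiro/nonlinear fusion
patterns and guards aromatic dissection; those rules are collapsed into
the final tie-break here because the package's graph representation does
not carry the ring-fusion taxonomy they require. The tie-break makes the
procedure a total order regardless, so a k-ring molecule always yields a
chain of exactly k scaffolds ending in a single ring, and forests are
invariant under input permutation.

Acyclic molecules are decomposed in a separate partition by iterative
terminal-atom pruning — halogens first, then S, O, N, then branch carbons,
ties broken by the canonical SMILES of the resulting fragment — until the
unbranched carbon backbone remains. The cited decomposition rules for
non-ring molecules are not restated in the literature we implement from,
so this deterministic variant is the package's own documented choice.

Scaffold identity is canonical-SMILES string equality with atom types
retained (no generic carbon-skeleton tier). Ring surgery preserves
aromaticity: molecules are carried with explicit aromatic bond types and
valence-complete hydrogen bookkeeping, so removing one ring of
naphthalene yields benzene, not cyclohexadiene.

## SEA target prediction

A query set is scored against each target's ligand set by the raw score
$\sum_{ij} T_{ij} \cdot [T_{ij} \ge t]$ over all cross pairs, with
inclusion threshold $t = 0.57$ by default (the classic optimum for
Daylight-style fingerprints; configurable). Random raw scores grow with
the set-size product $n_1 n_2$, so the background model fits
$\mathrm{mean}(raw)$ and $\mathrm{sd}(raw)$ **linearly against
$n_1 n_2$** from seeded random disjoint set pairs (default: sizes
{4, 8, 16}, 50 pairs per size combination). A fitted sd floor of $10^{-9}$
guards degenerate libraries. The standardized score
$z = (raw - \hat{\mu}(n_1 n_2)) / \hat{\sigma}(n_1 n_2)$ is converted to a
p-value with the tail of a zero-mean, unit-variance extreme-value
(Gumbel) distribution,
$$P(Z > z) = 1 - \exp\!\big(-e^{-(z\pi/\sqrt{6} + \gamma)}\big),$$
with $\gamma$ the Euler–Mascheroni constant — at $z = 0$ this is
$1 - e^{-e^{-\gamma}} \approx 0.4296$, a closed-form test point. The
E-value multiplies the p-value by the number of targets actually scored
in the call (self-contained tool semantics, not a fixed database size).
Only targets with **more than 10 ligands** are scored; smaller sets are
reported as skipped. Ligand sets are defined by any recorded activity —
no activity cutoff — since the profiling use case wants all evidence.

## QSAR ensembles

For each target with **more than 20 distinct measured compounds**, fifteen
classifiers are trained: 5 fingerprint variants × 3 activity cutoffs
(oriented values 4, 5, 6; i.e. 100 µM, 10 µM, 1 µM). A compound is active
at a cutoff iff its strongest oriented measurement on the target reaches
the cutoff. Training sets are balanced exactly: measured inactives are
topped up (or subsampled) with seeded random library compounds, and
compounds with any measurement on the target are never drawn as random
negatives (leakage guard).

Each model is a Bernoulli naive Bayes over fingerprint bits with Laplace
add-one smoothing — the standard choice for binary substructure features —
assessed by seeded stratified 5-fold cross-validation. The ensemble weight
is the cross-validated **MCC clipped at zero** (AUROC is computed and
stored alongside for reporting); a cutoff with no actives or no inactives
produces a zero-weight skipped spec. The ensemble prediction is the
weight-normalized convex combination $\sum_i w_i p_i / \sum_i w_i$ of the
per-model active-class posteriors, always in [0, 1], reported together
with the number of training molecules as reliability context. The choice
of MCC as the weighting currency is a judgment call the package states
explicitly: it is the balanced performance measure this kind of ensemble
reports, and clipping at zero removes anti-predictive models instead of
inverting them.

## Network enrichment

A protein's "complex" is its PPI neighborhood: the protein plus all
partners within a hop limit (default 1, configurable). The neighborhood is
tested against disease/pathway/GO term sets with the upper-tail
hypergeometric probability $P(X \ge k)$, and corrected per category with
Benjamini–Hochberg across **all tested terms** (including zero-overlap
terms; only terms with overlap ≥ 1 are reported). Bonferroni is available.
The universe defaults to all proteins in the network. BH per category is
the package's choice where the correction method was unspecified; it is
the standard for term enrichment.

## Heatmap assembly

Rows are compounds in scaffold-forest depth-first order (ring partition
first, siblings by canonical scaffold SMILES, a node's own compounds
before its children); columns are proteins in a depth-first walk of the
family tree (siblings lexicographic). The cell for a pair is the
**maximum z across data types** — strongest evidence shown; mean is
available. Gap filling writes only empty cells and tags their origin:
QSAR fills store the [0, 1] prediction raw and a display value rescaled to
the measured scale; SEA fills display the SEA z-score and store the
E-value. Measured cells are immutable under any sequence of fills. TSV
export is a dense grid plus an origin sidecar, with numbers printed via
`%.17g` so export → import → export is byte-idempotent; JSON export keeps
the sparse records (including the raw prediction column, which the TSV
grid does not carry). The color legend convention is blue = weak,
orange = strong.

## The synthetic-data generator

The generator emulates a small-molecule screening corpus with known
ground truth: a library enumerated from five single-ring scaffolds
decorated with prefix/suffix fragments; a planted sulfonamide
pharmacophore whose carriers are potent (oriented mean 7, i.e. 100 nM) on
designated active targets while all other pairs sit at oriented mean 4
(100 µM), with configurable Gaussian noise (default sd 0.5) and
missingness (default 30%); values back-converted to random data types and
units to exercise the full standardization path; and a PPI network with a
planted 8-protein clique covered exactly by one annotation term. All
generation is a pure function of the configuration including its seed.

Two fixture settings recur in the tests. Default conditions (means 7/4,
sd 0.5) exercise standardization, similarity, SEA and enrichment. The
QSAR separability runs use inactive mean 3 with sd 0.3: with inactives at
the default mean of 4, the cutoff-4 models would be trained on coin-flip
labels by construction (half the inactive draws cross the boundary), which
tests nothing about the learner. Pulling the inactive mean one log unit
below the lowest cutoff makes all three cutoffs yield clean labels, so
cross-validated performance measures the planted signal.

What the generator does **not** emulate: real chemical diversity (its
~1 300-compound grammar is intentionally narrow), tautomers and salts,
correlated assay noise, inter-database unit errors, or class imbalance
beyond the missingness model. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted signals,
not predictive performance on real corpora.

## Numerical choices and problem sizes

* Canonicalization and all structure identity go through OpenBabel
  canonical SMILES; molecules are carried valence-complete so ring surgery
  never produces radicals.
* Fingerprint hashing is exact integer arithmetic in doubles (prime
  modulus $< 2^{26}$); no platform-dependent hashing.
* SEA sd floor $10^{-9}$; similarity threshold strict by default;
  E-value factor = targets scored.
* Every stochastic step (set sampling, balancing, fold assignment,
  generator) takes an explicit integer seed and restores the caller's RNG
  state.
* The test suite runs on libraries of 80–1 000 compounds, 10–20 targets,
  SEA calibration on 1 000 fresh set pairs, and QSAR at 200 compounds
  across 3 seeds — sizes chosen so the planted signals are comfortably
  detectable while the whole suite stays fast on one CPU.

## Known limitations

* No tautomer/salt standardization beyond SMILES canonicalization.
* The condensed scaffold prioritization omits the bridged/spiro/aromatic
  arbitration rules; molecules where those rules would disagree with the
  tie-break may be assigned a different (still deterministic) parent.
* Formal charges are not carried onto fingerprint features.
* SEA's linear sd-vs-product fit is an approximation; it is validated only
  within the calibrated set-size range, and extrapolating far outside it
  will distort z-scores.
* QSAR posteriors are naive Bayes posteriors: well-ranked but typically
  overconfident; no extra calibration layer is applied.
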