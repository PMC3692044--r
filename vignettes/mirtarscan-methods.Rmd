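---
title: "Methods: seed scanning, interaction energetics and repression scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed scanning, interaction energetics and repression scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarscan)
```

`mirtarscan` predicts and ranks microRNA targets in 3′-UTRs. This
vignette documents the models behind each feature family, the parameters
that matter, the numerical choices, and what the synthetic-data tests do
and do not establish.

## Site model

A candidate target site is an exact Watson–Crick match to the miRNA seed.
With miRNA positions numbered 1-based from the 5′ end, the seed is
positions 2–7 (6 nt) or 2–8 (7 nt); the miRNA binds the UTR antiparallel,
so position 1 faces the 3′-most residue of the site. The four canonical
site types are: 6mer (match to seed 2–7), 7mer-A1 (6mer plus a literal A
opposite position 1 — an adenine anchor, not complementarity to position
1), 7mer-m8 (match through position 8) and 8mer (both). Each match is
reported once with its maximal class; site coordinates are 0-based,
half-open, and include the A of the A1 types. G:U wobble and mismatch
seeds are deliberately not matched: the scanner defines candidates, and
weaker bindings are penalized downstream by the energy features instead.
All site classes are reported by default and can be filtered downstream;
`N` never matches anything.

## Interaction energetics

All free energies are kcal/mol at 37 °C (RT = 0.6163 kcal/mol) on a
self-contained nearest-neighbor backend, so the package runs and tests
with no external folding engine. The backend is deliberately simplified
and is a model of its own, not an emulation of any particular engine:

* **Stack table** (`inst/extdata/nn_stacks.tsv`): the ten standard
  Watson–Crick stack free energies plus G:U wobble stacks, completed under
  the strand-symmetry identity E(p1,p2) = E(rev p2, rev p1). Users can
  supply their own table of the same layout.
* **Duplex energies.** `dg_duplex` is the minimum free energy over all
  intermolecular structures (stacked helices separated by internal
  loops/bulges, no intramolecular pairs), by dynamic programming with the
  stack table, a duplex initiation penalty (+4.09), a weak-end (A:U/G:U)
  terminal penalty (+0.45, applied at both helix ends) and an affine loop
  penalty (1.7 + 0.35 per unpaired nt, loops capped at 30 nt per side).
  `dg_binding` replaces the minimization by the inside (partition
  function) recursion, −RT ln Z, with the empty structure included at
  weight 1 — so it is 0 when nothing can pair and never exceeds
  `dg_duplex`. Both are capped at 0: a destabilizing duplex means no
  binding. Partition arithmetic runs in log space, so long inputs cannot
  overflow.
* **Seed energies.** `dg_seed_duplex` / `dg_seed_binding` are the same
  computations restricted to miRNA positions 1–8 versus the matched site
  region.
* **Accessibility.** `dg_open` = G(site forced unpaired) − G(free) over
  the window extending `flank` nt on each side of the site (default 70 nt,
  following the accessibility-feature lineage; exposed as a parameter).
  Single-strand ensembles use the same stack table plus a +1.0 kcal/mol
  per-pair penalty (an entropic proxy that disfavors isolated pairs) and a
  minimum hairpin loop of 3 nt. Because the constraint can only remove
  states, `dg_open` ≥ 0 for every input.
* **Totals.** `dg_total` = `dg_duplex` + `dg_open`, exactly. The duplex is
  computed over the site region extended 15 nt upstream (5′) so the miRNA
  3′ arm has a target to pair with; `upstream` is a parameter.

The windows and flanks are committed defaults, not claims about any other
implementation; both are exposed in `site_energies()`, `run_score()` and
the CLI.

## Over-representation under an order-1 Markov model

The composition of a UTR is summarized by an order-1 Markov chain fitted
from its dinucleotide counts (`N` positions are excised first; unobserved
source nucleotides get uniform rows). For an observed count *n* of seed
matches (span 2–8 by default, configurable to 2–7; overlapping
occurrences all count — "AAA" contains two "AA"), the package reports the
probability of at least *n* occurrences in a sequence of the UTR's
length:

* `pover_binomial`: P(X ≥ n) with X ~ Binomial(L − k + 1, p(motif)),
  where p(motif) is the chain's probability of emitting the motif.
* `pover_exact`: the exact tail probability from a product automaton —
  the KMP matching automaton of the motif (failure-function construction,
  so self-overlap is handled exactly) augmented with the previous
  nucleotide (the chain is order 1) and the occurrence count truncated at
  *n*, advanced L steps. The full count distribution is exposed as
  `occurrence_distribution()` and sums to 1 by construction of the
  propagation; the test suite verifies `pover_exact` against brute-force
  enumeration of all 4^L sequences weighted by the chain on randomized
  small instances (L ≤ 10, k ≤ 4, n ≤ 3), to 1e−12.

Self-overlapping motifs are where the binomial approximation is worst;
for non-self-overlapping 7-mers on 5 kb near-uniform UTRs the two agree
to within a few percent relative error.

## Conservation

Conservation features need a user-supplied newick tree (branch lengths in
substitutions/site) and an orthologous UTR alignment keyed by species;
alignment rows for species absent from the tree are dropped with a
warning.

* **BLS.** The site is mapped through the ungapped reference row to
  alignment columns (±2 columns of slop for alignment jitter); a species
  carries the site if its gap-stripped subsequence over those columns
  contains the seed match exactly. The branch length score is the summed
  branch lengths of the minimal spanning subtree connecting the carrying
  species (0 for fewer than two), optionally normalized by total tree
  length for cross-tree comparability.
* **phyloP-style test.** Column likelihoods come from Felsenstein
  pruning under JC69 (default; HKY85 available — JC69 was chosen as the
  default because closed-form transition probabilities make independent
  oracles possible). A site-specific branch-scale λ is optimized in
  [1e−4, 10] and compared with the neutral λ = 1 by likelihood ratio; the
  p-value is half the χ²₁ tail on the side of the estimate, and
  `phylop_score` = −log10 p, signed positive for conservation (λ̂ < 1)
  and negative for acceleration. This is the self-contained
  likelihood-ratio flavor of the phyloP idea, not the exact
  null-distribution variant; it is calibrated by simulation in the test
  suite (type-I error within ±0.015 of α = 0.05 over 2000 neutral sites
  on a fixed 8-species tree of total length 3.5 with 7-column sites —
  sizes chosen as a realistic seed-site configuration) and its power
  increases as the true λ decreases through 0.8, 0.4, 0.1.

## Context features

Three sequence-context determinants of site efficacy, with the weights
isolated in one constants block (`R/context_features.R`):

* **AU content**: over up to 30 nt on each side, the position at distance
  i from the site edge carries weight 1/(i+1); the value is the weighted
  fraction of A/U among available positions. The window is symmetric; the
  site-type-specific asymmetries of the original context-score lineage
  are deliberately collapsed.
* **UTR position**: distance from the site midpoint to the nearest UTR
  end, capped at 1500 nt (closer sites tend to be more repressive).
* **3′ pairing**: the best run of contiguous Watson–Crick pairs between
  miRNA positions 9–3′ end and the 15 nt of UTR immediately 5′ of the
  seed-paired region, over register offsets up to ±6; paired positions
  13–16 score 1.0, others 0.5, minus 0.5 per nt of offset, floored at 0
  (negative totals are not propagated).

## Scoring, aggregation and percentiles

Pair-level features are site sums for the energy, context and
conservation families, plus the site count; the over-representation
probabilities are pair-level quantities by nature (functions of the total
match count). Summation is a committed choice — the aggregation rule was
genuinely open. The repression model is ordinary least squares of log2
fold-change on the features (rank deficiency is a hard error naming the
collinear columns); prediction is the linear form, more negative =
stronger repression. No published coefficients are shipped:
`demo_model()` carries synthetic demonstration values so the pipeline
runs out of the box, clearly labeled as such, and `fit_linear_model()` /
`run_fit()` refit on real data. Pairs lacking optional features (e.g.
conservation without a tree) are scored by the reduced model on the
available columns and flagged (`reduced_model`).

Raw values convert to percentiles by oriented empirical rank within a
background sample: with the direction map (lower is stronger for all ΔG,
both P.over values, UTR position and the score itself; higher is stronger
for BLS, phyloP score, AU content, 3′ pairing and site count), the
repression-oriented average rank r among N background values maps to
100·(r−1)/(N−1), so 100 is the strongest repression and ties average.
The three-point example {−10, −5, −1} with a lower-is-stronger feature
sends −5 to exactly 50. BED export scales the percentile to the 0–1000
score field (0 when unset), a committed interpretation of the otherwise
unspecified BED score semantics.

## Synthetic data: what it shows and what it does not

The generators are pure functions of their arguments including the seed:

* `gen_utr` draws i.i.d. sequences from a base composition — no repeats,
  no motif clustering, no real UTR grammar.
* `plant_sites` writes exact match strings onto a background and then
  deterministically mutates the background until the scanner finds
  exactly the planted truth; the immediate context is forced so a planted
  class is not accidentally upgraded. This gives exact ground truth for
  recovery tests but cannot probe sensitivity to near-matches.
* `gen_alignment` evolves the reference sequence over the tree with
  per-window branch-scale multipliers (λ = 0 freezes a window; λ < 0 is
  an error), conditioned on the reference leaf carrying the input
  sequence — equivalent to root sampling under the reversible models used
  and guaranteeing that site coordinates transfer exactly. There are no
  indels, so alignment-jitter behavior is covered only by small manual
  fixtures; a real aligner's errors are out of scope.
* `gen_repression_dataset` draws features uniformly from documented
  ranges and adds Gaussian noise — features are independent by
  construction, unlike real feature sets, so it validates the fitting
  machinery, not biological effect sizes.

Consequently, passing tests establish algorithmic correctness
(coordinates, probabilities, energies, likelihoods, rank transforms) and
calibration under the stated models; they do not establish predictive
performance on real transcriptomics data, which requires external
training sets that are out of scope here.

## Numerical choices and degenerate inputs

Partition functions accumulate in log space (log-sum-exp). Empty
ensembles return 0 energy by the no-interaction convention. λ
optimization uses Brent search on [1e−4, 10] with tolerance 1e−6; if the
optimum does not beat the neutral likelihood, the fit is clamped to λ = 1
with p = 1 and score 0. Pruning likelihoods are rescaled per node to
avoid underflow. Markov fits on sequences shorter than 2 non-N residues
are errors; all-zero transition rows fall back to uniform. Sites flush
against a UTR end simply lose the unavailable upgrade (no m8 slot at the
5′ edge, no A1 slot at the 3′ edge), and flank windows clamp to the UTR.
Percentile ranks against a single-value background return 50.

## Problem sizes

The shipped tests run at desk scale by design: enumeration oracles at
L ≤ 10, energy invariants over 500 random fixtures with 60-nt UTRs and
14-nt folding flanks, 2000 neutral and 3×250 selected phyloP simulations
on an 8-species tree, OLS recovery at up to 5000 synthetic pairs, and
100 planted-site fixtures. `scripts/acceptance.R` recomputes the same
families of quantities from scratch with sizes of the same order.

## Known limitations

No pseudoknots, no temperature other than 37 °C, and no attempt to
reproduce any specific folding engine's numbers. Centered and
3′-compensatory-only sites, ORF/5′-UTR scanning, higher-order Markov
models, the conservation-probability (Pct) filter and genome-coordinate
liftover are out of scope. Conservation features require a user-supplied
tree and alignment; no species databases are bundled.
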