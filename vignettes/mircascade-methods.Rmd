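---
title: "mircascade: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mircascade: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircascade)
```

## The problem

MicroRNA precursors (pre-miRNAs) are ~50-150 nt RNAs that fold into a
stem-loop: a mostly double-stranded stem, interrupted by internal loops
and bulges, closed by a terminal loop. Completely ab initio prediction
asks: given nothing but genomic sequence, where are the subsequences
that fold into such hairpins *and* look like real precursors rather
than the enormous background of incidental stem-loops? The second half
is the hard part — hairpins are everywhere in genomic sequence, so the
operational bottleneck of ab initio predictors is selectivity
(precision), not sensitivity.

`mircascade` addresses this with a three-stage search-and-classify
cascade. Structure building is cheap and classifier gating is applied
as early as possible, so that expensive work is only spent on
candidates that still look plausible.

## The pairing matrix

Each sliding window `s[0..n-1]` (150 nt by default, moved 10 nt at a
time, with a final window anchored at the 3' end) is folded through a
triangular base-pairing matrix. Column `j` represents `s[j]`, row `i`
represents `s[n-1-i]`; a cell is 0 when the two bases cannot pair and
otherwise extends the run of its up-left neighbour by one:

```{r}
pm <- build_pairing_matrix(rna_seq("GGGGAAACCCC"))
diag(pm$run)[1:4]
```

Runs of positive cells on one diagonal are *exact stems* —
uninterrupted helices. Complementarity includes the G:U wobble next to
the Watson-Crick pairs: wobbles are common in real RNA helices and the
stage-1 feature "percentage of G:U pairing" would otherwise be
identically zero. Only the triangle where the two arms are separated by
at least the minimum terminal loop (3 nt, the steric floor for RNA
loops; the reference method leaves this implicit) is searched.

Coordinates are 0-based half-open everywhere inside the package;
1-based coordinates appear only in GFF3/BED output.

## Three-stage construction and gating

1. **Exact stems.** Every maximal diagonal run of length >= 4 bp is
   enumerated. A random-forest model scores each stem from 29 features
   (size, duplex deltaG, composition, homopolymer runs, %G:U pairs,
   the 16 dinucleotide percentages, and (G+A)-(C+U) and G-C
   composition differences). Stems with P(positive) below the stage-1
   threshold are dropped.
2. **Non-exact stems.** Each surviving stem is extended *along its own
   diagonal only*, absorbing neighbouring runs whenever the symmetric
   internal loop between them is strictly smaller than both flanking
   stems. A second model scores the result from the 35 stage-2
   features (the stage-1 block recomputed over the spanned region plus
   pairing percentage and loop statistics).
3. **Complete hairpins.** The seed stem is anchored and other diagonals
   are explored so bulges and asymmetric internal loops can occur. A
   third model scores the 80 stage-3 features; survivors inside the
   50-150 nt size window become predictions.

### The stage-3 search rule

The reference description says only that other diagonals are tried; the
concrete strategy is this package's own design. We use a deterministic
best-first extension: from the current innermost (and then outermost)
base pair, every gap combination `(g5, g3)` with `0 <= g5, g3 <=
max_shift` (default 10 nt) is evaluated, scoring a candidate helix of
`L` pairs as `L - loop_penalty * (g5 + g3)` with `loop_penalty = 0.3`
per unpaired nucleotide. The best positive-scoring continuation is
taken; ties prefer the smaller total loop, then the smaller side
difference `|g5 - g3|`, then the 5'-most option, which makes the search
fully deterministic. Extension stops when no continuation has positive
score; helices are truncated so the terminal loop never drops below
3 nt. On toy sequences this greedy rule provably reaches the
maximum-pairing structure obeying the same constraints (the test suite
checks it against exhaustive enumeration); on realistic windows it is a
heuristic, which is the usual trade in this family of methods.

## Features

Stage vectors are strict prefix extensions: 29, 35, 80 values, the
shared block recomputed over the larger structure at each stage. Points
the reference text leaves open, decided here:

* *Stage-1 composition region*: the two arms concatenated (stage 1);
  the full spanned region including enclosed loops for stages 2-3.
* *"Size" at stages 2-3*: total paired bases of the structure (at
  stage 1 it is the stem length; the natural generalization).
* *"Average size of palindromes"* (stage 2) is read as the mean exact
  stem (helix) length — a palindromic subsequence is exactly what a
  paired helix is in this matrix.
* *Triplets* follow the paired/unpaired-pattern-times-middle-nucleotide
  scheme; a closing bracket counts as paired, giving 8 patterns x 4
  nucleotides = 32 features. Dinucleotides contribute 16. (Our block
  arithmetic gives 29/35/80 per stage; the reference's "51 extra
  features" total is not forced.)
* *MFE indices*: adjusted MFE = 100 x MFE / length; MFE1 = adjusted MFE
  / %(G+C); MFE2 = adjusted MFE / number of stems (the microPred-style
  definitions; the reference names but does not define them).
* Ratio features with a zero denominator (e.g. MFE1 on a G/C-free
  candidate) are emitted as 0 with a warning so vectors stay finite.

### The energy backend

deltaG and MFE would normally come from an external thermodynamic
folder. To keep the toolkit dependency-free and testable offline, the
default backend is a stacking-count approximation: each stack of
adjacent pairs contributes -2 kcal/mol if a G:C pair is involved, -1
for A:U, -0.5 for two G:U wobbles, and `fold_mfe()` minimizes the
per-pair analogue over all nested structures by dynamic programming.
These are not calibrated free energies; they are monotone surrogates
that rank candidates sensibly. Only 4 of the 80 stage-3 features
(deltaG, adjusted MFE, MFE1, MFE2) depend on the backend, and any list
providing `duplex_energy()` and `fold_mfe()` can replace it — swapping
backends is tested to leave every other feature untouched.

## Learning: SMOTE + random forest

Real training sets are heavily imbalanced (few true precursors, many
other ncRNAs and pseudo-hairpins). Each stage model therefore
SMOTE-oversamples the minority class to parity — synthetic points
`x + u (x_nn - x)` interpolated toward one of the k = 5 nearest
minority neighbours (the canonical SMOTE default; the reference does
not state k) — and trains a 100-tree random forest. Neighbour search
runs on min-max-scaled features so large-magnitude features (energies)
do not dominate the distances; the scaling bounds are persisted with
the model. The forest itself is implemented in C++ inside the package
(bootstrap bagging, per-split random feature subsets of size
`floor(sqrt(p))`, Gini splits, trees grown to purity, probability =
forest-averaged leaf class proportion) with an internal RNG so a seed
reproduces the model bit-for-bit on any platform; none of the R
tree/forest packages this would normally lean on are available in the
supported environment.

Training sets are built by running every labelled sequence through the
structural search with no gating and keeping, per stage, the single
highest-scoring candidate (most paired bases, ties 5'-most). One
example per sequence per stage bounds the label noise from spurious
stems inside true precursors; the alternative (all candidates) is not
exposed. Stage thresholds default to (0.3, 0.3, 0.7), the combination
with the best reported geometric mean in the reference experiments;
gating is inclusive (`P >= threshold`).

Cross-validation (`cross_validate()`) is stratified, applies SMOTE
inside each training fold only — never to evaluation folds, which the
suite audits explicitly — and pools fold-wise confusion counts before
computing SN/SL/GM (pooling, rather than averaging fold-wise ratios, is
our choice; the reference does not say which it used).

## Scanning, merging, evaluation

Windows are scanned left to right; surviving hairpins are mapped to
source coordinates. Overlapping windows re-find the same hairpin, so
stage results are cached by absolute coordinates and predictions are
merged: the highest-probability prediction absorbs every prediction
overlapping it reciprocally by at least 50%, and the rule repeats
(greedy non-maximum suppression). This particular rule was chosen over
single-linkage grouping because it provably keeps the prediction count
non-increasing as the stage-3 threshold rises — single-linkage can
split a group into several when a middle member is thresholded away.

Evaluation follows the field's center-distance criterion: a prediction
is a true positive when its center lies within 10% of the known
hairpin's length from the known center (inclusive), each known hairpin
matched at most once, greedily by smallest distance. SN = 100 TP /
(TP+FN), SL = 100 TP / (TP+FP), GM = sqrt(SN x SL). Zero denominators
yield 0 with a warning. Reverse-strand scanning exists behind
`scan_reverse` but is off by default (reference experiments used the
forward strand only).

## Synthetic data: what it does and does not establish

The generator emits idealized hairpins — a random arm, a loop, the
reverse-complemented arm — degraded by G:U conversion, bulge insertion
and point mutations, with every random choice driven by one explicit
seed. Negatives mix dinucleotide-preserving shuffles of positives
(structured but not hairpin-forming, standing in for other ncRNAs)
with i.i.d. background at matched GC. Implanted genomes place hairpins
at least 50 nt apart in i.i.d. background and return exact truth
intervals. Default geometry for training corpora: stems 22-45 bp,
loops 4-12 nt, 0-2 small bulges, up to 15% G:U and 5% mutation —
within the realistic pre-miRNA envelope and long enough that the
50-150 nt size filter accepts the implants.

A green end-to-end test on this material establishes that the
machinery — matrix, search, features, rebalancing, forests, gating,
coordinates, merging, evaluation — is wired correctly and that the
cascade separates clear structure from clear non-structure. It does
*not* establish the published selectivity on real genomes: real
negatives (expressed ncRNAs, pseudo-hairpins) are far harder than
shuffles, real positives are messier than generated stems, and the
published numbers also depend on miRBase-scale training corpora and an
external thermodynamic engine. Those experiments require the original
genomic data and are out of scope here.

## Numerical and degenerate-input choices

* Strict inequality in the symmetric-loop absorption rule (`g <
  min(L1, L2)`), matching "less than".
* Runs are clipped at the triangle boundary before the minimum-length
  filter, so stems never imply a terminal loop under 3 nt.
* A non-exact stem whose hairpin search finds nothing extendable is
  itself the candidate, closed by its terminal loop.
* Homopolymer or otherwise stem-free training sequences are skipped
  with a warning; a training class that ends up empty is an error, not
  a silent degradation.
* All randomness flows through explicit integer seeds; derived seeds
  are kept inside the 32-bit range R requires.

## Known limitations

* The stage-3 search is greedy; it can miss the global
  maximum-pairing structure on adversarial windows (bounded by the
  `max_shift`/`loop_penalty` contract, and irrelevant to the toy-scale
  oracle tests, but real).
* The stacking-count energies are surrogates, not kcal/mol
  measurements; plug in a thermodynamic backend for serious use.
* Multibranch structures and pseudoknots are outside the model: every
  candidate is a single stem-loop.
* Scanning is single-threaded R; throughput is roughly tens of kb per
  minute with default gating, so chromosome-scale scans want coarser
  steps or an external driver.
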