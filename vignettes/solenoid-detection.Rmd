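---
title: "Detecting alpha-solenoid organellar trans-acting factors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alpha-solenoid organellar trans-acting factors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solenoidscan)
```

## The problem

Organellar trans-acting factors (OTAFs) such as OPR and PPR proteins are
nucleus-encoded RNA-binding proteins that control chloroplast and
mitochondrial gene expression. Structurally they are α-solenoids: tandem
arrays of degenerate ~35–38 aa repeats, each repeat folding into an
antiparallel α-helix pair, stacking into a superhelix whose concave face
binds mRNA. Because the repeats diverge rapidly, single-sequence homology
search misses many members; detection instead exploits the *repeat
architecture* itself. This package implements three complementary
detectors — an iterative profile search over motifs, a decision tree over
structural annotations, and a random forest over a physico-chemical
descriptor — together with family clustering and motif positional-bias
analysis, all exercisable on synthetic fixtures with known truth.

## Iterative profile-based search

`run_ipb()` alternates five steps until no new organelle-targeted
(*pto*) candidate protein appears, or an iteration cap (default 10) is
reached, in which case the state is reported with a flag rather than an
error.

**Adaptive threshold.** With `X` motifs in the current set, all-vs-all
comparison keeps hits with E-value below `t = 10^-n`, where
`10^(n-1) <= X <= 10^n`. At exact powers of ten both brackets hold; we
take the smaller `n` (the more permissive threshold). The threshold is
non-increasing in `X`: the bigger the motif set, the stricter the graph.

**Pairwise comparison.** The built-in aligner adapter is Smith–Waterman
(BLOSUM62, gap open 11 / extend 1) with a Karlin–Altschul E-value using
the standard gapped BLOSUM62 constants (λ = 0.267, K = 0.041) and the
motif-set residue count as search space. It emulates a BLASTP run;
parity with BLASTP E-values is explicitly not asserted, and a reader for
external BLAST tabular output is provided for parity runs.

**Markov clustering.** `markov_cluster()` is a canonical MCL: self-loops
at each node's maximum incident weight, column normalization, then
expansion (matrix squaring) and inflation (entrywise power and
renormalization) with pruning (default 1e-5) until the change is below
1e-6 or 200 iterations. Clusters are connected components of the limit
support, so nodes in different components can never co-cluster, and
isolated nodes are singletons. Inflations quoted as integers above 10
are read as tenths (50 means 5.0), covering both conventions in which
the parameter is reported.

**Inflation selection.** For each inflation from 1.1 in steps of 0.1
(the grid's upper end is unstated in the source method; we cap at 5.0,
beyond which MCL partitions essentially stop changing on motif graphs),
each cluster's members are aligned and the clustering maximizing the
number of clusters with gap load ≤ 18 (OPR) or 16 (PPR) wins, ties going
to the lower inflation. *Gap load* is the maximum number of gap
characters in any single aligned member — about half a motif — so each
member must resemble its cluster over at least half its length
(anti-"slippage"). The alternative reading (total gap columns) was
considered and rejected because the cap is phrased per motif.

**Profiles and search.** Profiles are per-column log-odds scores from
the cluster alignment (columns above 50 % gaps dropped, Dirichlet
pseudocount mass 1, background from the searched proteins). The built-in
multiple aligner is center-star progressive alignment, adequate for
short near-equal-length motifs; an external aligner can be substituted
upstream since profiles take any alignment. Window scores are converted
to E-values using the *exact* null distribution of the window score
under iid background residues, obtained by convolving the per-column
score distributions (0.02-nat bins) — no normal-tail approximation, so
decoy hits are calibrated and planted hits are found without tuning.
Overlapping windows of one profile are reduced to non-overlapping score
peaks, mimicking domain envelopes. The acceptance E-value for hits is
not stated by the source method; the default is 1e-3 and is recorded
with results.

**Length filter and overlap resolution.** New hits must be within −6/+2
of the canonical motif length (OPR 38 → 32..40; PPR 35 → 29..37). Pairs
of hits overlapping by more than 80 % of the shorter hit merge into
their intersection (the "minimum overlapping region"), keeping the
better E-value's profile attribution; pairs overlapping 20–80 % are both
eliminated; below 20 % both stay. The rule is applied until stable, so
no surviving pair overlaps by more than 80 %.

**Reporting.** Candidates are proteins carrying at least one motif; the
conventional "at least 2 motifs" cut is a *view* filter
(`tidy(res, min_motifs = 2)`), never a deletion, and motif and candidate
sets grow monotonically across iterations.

## Decision-tree filter

`dt_classify()` applies, in order and short-circuiting: (1) exclusion of
proteins with a transmembrane helix beyond the N-terminal part (residue
78; a helix fully inside it is tolerated as a mis-predicted targeting
peptide — a straddling helix triggers exclusion since its
membrane-spanning body lies beyond); (2) at least one sequence repeat of
at least 29 aa; (3) at least 4 linkers, every consecutive pair 32–400 aa
apart (inclusive bounds); (4) at least 65 % helix between the two
extreme linkers; (5) the targeting consensus. A *linker* is one
representative per maximal run of residues with linker score strictly
above 0.15, placed at the run's maximum (leftmost on ties): the
predictor emits per-residue scores while the method counts linkers as
units, so run-collapsing is our reading, and inter-linker distances are
measured between representatives. The source text also contains an
alternative repeat reading (two repeats of ≥ 26 aa); it is available as
`dt_params(preset = "results-text")`, with the stated method defaults
(one repeat of ≥ 29 aa) as the primary.

`dt_parameter_sweep()` evaluates threshold grids exhaustively on a
labeled set. "Maximizing precision and recall" needs a combiner; we use
F1 with ties toward precision, and report NA rates on zero denominators.

## Targeting consensus

A protein is *pto* when at least 2 of the 4 localization predictors vote
chloroplast *or* mitochondrion. Whether the two required votes must name
the same organelle is unstated; votes pool here, because the notion
being captured is "addressed to organelles" — requiring agreement would
drop proteins with one chloroplast and one mitochondrial vote, which are
exactly the dual-targeted cases the class is known to contain. Absent
tools count as voting "other" (conservative). The consensus is monotone:
an added organelle vote can never revoke *pto* status.

## The 61-variable descriptor

`build_descriptor()` concatenates, in frozen order (version `ss61-v1`,
recorded on trained models):

| block | components | notes |
|---|---|---|
| solenoid geometry | 4 | repeat residue proportion, median repeat length, linker count, median inter-linker distance |
| composition | 20 | amino-acid frequencies, alphabetical; `X` excluded from numerator and denominator |
| disorder | 1 | fraction of residues with disorder score strictly > 0.5 |
| ACC | 36 | `acc(j,k,lag) = 1/(n−lag) Σ z_j(aa_i) z_k(aa_{i+lag})`, scales j,k ∈ 1..3, lag ∈ 1..4, lexicographic |

The ACC terms are *uncentered* lagged products of the three Hellberg
Z-scales — the most common convention for Z-scale auto-cross terms; the
source method defers to its descriptor reference without a formula, so a
centered variant (per-scale sequence means subtracted) is available via
`centered = TRUE` and the choice travels with the model, because trained
models are convention-bound. Unknown residues (`X`) carry zero Z-scales:
they contribute zero products while still counting toward `n`. The
phrase "the probability for an amino acid to be a linker" in the source
is read as describing the linker predictor's per-residue input, not a
62nd feature — otherwise the printed total of 61 (4+20+1+36) cannot
hold.

## Random forest

No CART or random-forest package is available in the target environment,
so the classifier backend is implemented in the package: bootstrap
bagging of Gini-impurity CART trees with per-node uniform feature
subsampling (`mtry = floor(sqrt(p))`), 500 trees, depth ≤ 10, ≥ 5
samples per leaf, all other behavior at the common defaults. Importances
are mean decrease in impurity, per-tree normalized then averaged,
summing to 1. Determinism is per-seed: the same seed reproduces the same
forest. `split_validation()` holds out a stratified 10 % never used for
training or selection (426 + 286 examples yield a 71–72-strong
validation set); `train_rf(grid = ...)` runs a stratified 5-fold
cross-validated grid search (fold count unstated in the source; 5 is
ours). For detection, `ensemble_detect()` varies both the seed and the
training data (a fresh 90 % stratified subsample per run) across the
1000 runs — what varied in the original 1000 runs is unstated, and
re-subsampling makes the ≥ 90 % retention quorum a stability statement
rather than 1000 identical fits. Retention compares with `>=`
("at least 90 %"): 900/1000 is retained, 899 is not.

## Family analysis

Candidate families are Markov clusters of the graph whose edges demand
E-value < 1e-6 *and* ≥ 70 % coverage of both proteins; members then
classify as singleton, species-specific, phylum-specific or inter-phyla
— a partition, each family in exactly one class. Paralogs are
deduplicated by keeping the longest member per family (the source does
not specify its rule). Motif positional bias uses the ordinal rank of a
motif among its protein's motifs (not a normalized coordinate): a motif
cluster with at least 5 occurrences is biased when ≥ 80 % of them share
one rank.

## The synthetic world

The generators state a fixed world; their defaults are not tuned against
test outcomes.

* The consensus repeat (`SOLENOID_CONSENSUS`) is a fixed 38-aa
  amphipathic helix-pair sequence, versioned in code.
* A solenoid record is N-flank + n mutated consensus copies + C-flank;
  per-position substitution rate 0.15 by default (two copies then match
  at ~72–74 %, the degeneracy regime of real OPR repeats); annotation
  tracks follow the construction truth (linker score 0.9 at repeat
  junctions over 0.02 background, helix calls over the two helices of
  each repeat, disorder 0.7 on flanks, no TM helix), and targeting gives
  two organelle votes.
* The labeled benchmark (200 positives / 150 negatives) varies repeat
  count 2–8 and flanks, targets positives with probability 0.8 and
  negatives 0.2, and builds a third of the negatives as
  composition-preserving shuffles of positives so amino-acid frequencies
  alone cannot separate the classes. Repeat-count variation is what
  produces the decision tree's characteristic high-specificity /
  moderate-recall pattern on this world (positives with fewer than five
  repeats lack the four linkers the tree demands), while the forest,
  free to use the continuous geometry, separates the classes almost
  perfectly. A green benchmark test therefore establishes that the
  protocols are implemented coherently — not the field performance of
  the detectors on real proteomes, whose negatives are adversarial
  (β-solenoids, other repeat proteins) in ways this generator does not
  emulate.
* The staged-divergence fixture demonstrates iterative gain. It is built
  as two correlated subfamilies: protein A repeats noisy (5 %) copies of
  one consensus variant at divergence 0.5, protein B copies of a further
  drift of A's variant near total divergence 0.8. Stages shallower than
  roughly 0.65 defeat the fixture's purpose: with exact-null log-odds
  scoring the seed profiles already detect motifs down to ~35–40 %
  identity, so a "far" protein at 40–60 % divergence is found in the
  first iteration. At (0.5, 0.8), across seeds, A is found at iteration
  1 and B only after A's motifs have joined the profile set.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; slices of `[s, e]` have
  length `e − s + 1`.
* Strict inequalities where the source says "above"/"more than": linker
  score > 0.15, disorder > 0.5, gap-column fraction > 0.8 (a column with
  exactly 80 % gaps is kept).
* E-values of numerical zero cap edge weights at 200 (−log10 scale);
  `-log(E)` is base-10, the BLAST convention.
* MCL non-convergence returns the current clustering with a warning;
  empty proteomes, empty hit sets and repeat-free annotations flow
  through as empty results, while a missing per-residue track reached by
  the decision tree is an error naming the track (absence of repeat
  *rows* means "no repeats found", since the table dialect cannot
  distinguish an absent track from an empty one).
* Medians over an even count are the mean of the two middle values;
  empty repeat/linker tracks give zero-valued geometry descriptors.

## Known limitations

* The built-in profile search scans at the profile's column width only;
  hits of other lengths arise through alignment columns, not through
  per-window length variation. With near-equal-length motifs this is
  immaterial, and external profile-HMM tools can replace the adapter for
  gapped motif families.
* The Smith–Waterman E-value is an approximation pegged to gapped
  BLOSUM62 constants; it orders hits correctly but is not a BLASTP
  E-value.
* The forest backend implements the standard algorithm but is not a
  drop-in reimplementation of any particular library's estimator;
  hyperparameters shared with the stated protocol (trees, depth, leaf
  size) are honored, and remaining behavior follows common defaults.
* Linker-count monotonicity in the score cutoff holds on unimodal peak
  tracks (the shape linker predictors emit); on arbitrary jagged tracks
  raising the cutoff can split a run and increase the count.
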