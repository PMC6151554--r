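---
title: "Classifying critical residues from structure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying critical residues from structure: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critres)
```

`critres` classifies residues that are critical for protein function from
structure-derived descriptors.  This vignette is the package's account of
the underlying models, the tunable parameters, and the design decisions
taken where the methods left genuine freedom.

## Residue contact graphs

A chain read from a PDB file (`readChain()`) keeps only standard
amino-acid residues (common modified residues such as selenomethionine are
mapped to their parent; hydrogens, waters and ligands are dropped;
alternate locations resolve to the highest-occupancy conformer, ties to
the first in file order).  Residues are indexed 1..N internally while the
original PDB numbering is carried for reporting, so no output ever depends
on renumbering conventions.

`buildContactGraph()` joins residues whose minimal inter-residue atom
distance is at most `cutoff` (default 5 Å).  Tunables:

* `atomMode` — `"heavy"` (default), `"CA"` or `"CB"`.  Contact-map
  literature divides between all-heavy-atom and C-alpha definitions; the
  all-heavy-atom minimum is the most common reading and the choice is
  deliberately a flag, never hard-coded.  Glycine has no C-beta; `"CB"`
  mode falls back to C-alpha with a warning.
* `minSeqSep` — minimal sequence separation (default 1, i.e. sequence
  neighbours count as contacts; no exclusion is assumed).

Distances are computed exactly over all atom pairs; no grid approximation
is used at the problem sizes this package targets.

## Centrality descriptors

`centralityProfile()` computes 11 per-residue measures on the unweighted
contact graph, distances in edge hops: eccentricity (longest shortest
distance) and its inverse; degree; sphere degree (sum of neighbour
degrees, the "degree at a second level"); accumulated sphere degree (SNN =
degree + sphere degree, reading "the counts include the number of
neighbors" as adding the node's own contact count); mean distance;
closeness; clustering coefficient; its inverse; and two traversity
variants.

Numerical conventions, chosen to keep feature tables finite and defined:

* **Closeness vs mean distance.** The two textbook phrasings ("inverse of
  the sum of distances" vs "1/mean distance") disagree by the count
  factor.  We implement `closeness = 1/Σd` and `mean_distance = Σd/count`
  over the reachable residues, so the identity
  `closeness = 1/(mean_distance · count)` holds exactly and is asserted in
  the tests.
* **Disconnected graphs.** All distance measures are computed within the
  node's component; isolated nodes score 0 on every measure.
* **Inverted measures at 0** return 0, not infinity.
* **Clustering** uses `o/(n(n−1))` with `o` the number of *ordered*
  adjacent pairs among the `n` neighbours (twice the undirected edge
  count), 0 when `n ≤ 1`.

**Traversity** counts how often a residue lies strictly inside the one
shortest path selected for each residue pair.  Selecting a single path
needs a deterministic tie-break; we orient each pair from its lower index
and take the lexicographically smallest shortest path (variant A: always
step to the smallest-index admissible neighbour) or the lexicographically
largest (variant B).  These two rules are reproducible, symmetric in
spirit ("with" and "against" the sequence order), and have a clean
independent oracle — exhaustive enumeration of all shortest paths followed
by lexicographic selection — which the test suite runs on hundreds of
random graphs.  Note one consequence: on even cycles the tied paths are
split asymmetrically, so traversity is *not* constant on every
vertex-transitive graph, only on those (odd cycles, complete graphs) where
shortest paths are unique.

## Correlated-mutation index

For residue *j* with contacts *i = 1..m*, `CM_j = Σ S_i`, where `S_i` is
the substitution frequency of the contacting residue's alignment column:
the fraction of non-gap homologs (reference excluded) differing from the
reference residue.  This is the simplest frequency consistent with an
"observed normalized frequency of residue substitutions" per column;
column-pair covariation is deliberately out of scope since the index is
defined as a sum of single-column quantities.  Because each `S ∈ [0, 1]`,
`0 ≤ CM_j ≤ degree(j)`.

Structure-to-alignment mapping matches the chain sequence against the
ungapped reference row (chosen by identifier or best match); more than 5 %
mismatch aborts, because a silently wrong mapping would corrupt every CM
value.  Any FASTA or Stockholm alignment containing the chain sequence is
accepted.

## The criticality index

`buildSubstitutionRanking()` scores all 380 ordered substitutions between
distinct amino acids (the 20 identity pairs among the 400 ordered pairs
are not mutations) by the Euclidean distance between the residues'
five-factor physicochemical score vectors, and ranks them ascending so
rank 380 is the most dissimilar.  The factor table shipped in
`inst/extdata/` holds the published factor-analysis scores of Atchley et
al. (2005) — polarity, secondary-structure propensity, molecular volume,
codon diversity, electrostatic charge; any complete 20×5 replacement can
be supplied.  Distance ties break by `(from, to)` lexicographic order so
the ranks are a gap-free permutation.

For a position whose *m* reported substitutions all gave a mutant
(loss-of-function) phenotype,

$$CI = \frac{\sum_{i=1}^{m} R_i}{\sum_{i=381-m}^{380} i},$$

the observed rank sum normalized by the largest sum *m* ranks can attain.
The denominator is the top-*m* sum — *m* terms — so that `CI = 1` is
attainable exactly when the reported substitutions are the most dissimilar
ones possible; a variant with an `m+1`-term denominator (under which the
index cannot reach 1) is available behind `strict = TRUE` for
compatibility with the literal summation bounds sometimes quoted.  Ranks
are global over all 380 substitutions, not renormalized within the 19
substitutions of the wild-type residue.

Mixed evidence (both phenotypes at one position) enters with opposite
signs, `CI = ½[(1 − ΣRW/D_w) + ΣRM/D_m]`, with separate top-rank
denominators for the wild-type and mutant sets (the alternative — one
shared denominator — is ambiguous when the two sets differ in size).
Positions where *only* tolerated substitutions were reported are not
covered by either formula; we score them with the tolerance term alone,
`CI = 1 − ΣRW/D_w`, the natural limiting case.  Duplicate reports of the
same substitution collapse; duplicates with conflicting phenotypes are
kept as one wild-type and one mutant record, routing the position to the
mixed formula — a conservative reading of contradictory evidence.
Intermediate phenotypes are rejected at input validation: the index is
defined for a binary phenotype vocabulary only.

The binary label is critical iff `CI > 0.5`, with the boundary value 0.5
itself non-critical.

## Descriptor filters

`filterFeatures()` applies three filters in a fixed, logged order:

1. `removeUseless()` — constant columns.
2. `spearmanRedundancyFilter()` — walking columns in file order, drop any
   column whose |Spearman ρ| with an already-kept column reaches the
   threshold (default 0.95; the keep-first policy and the file order make
   the result deterministic).  Rank correlation removes monotone
   transforms of kept columns at any threshold ≤ 1.
3. `informationGainFilter()` — binary classes only: each descriptor is
   discretized by Fayyad–Irani recursive entropy splitting with the MDL
   stopping rule, and descriptors with zero information gain are dropped.
   Information gain on raw reals is undefined, which is why the
   discretization step is intrinsic; bin edges are recomputed per
   descriptor.

All filters are idempotent and row-order invariant, and each appends a
removal report to the table's `filterLog()`.  Missing values are an error
at ingestion: imputation is a modelling decision the user must take
explicitly.

## Genetic-algorithm wrapper

`gaSelect()` searches descriptor subsets (the space for *m* descriptors
has 2^m − 1 non-empty subsets, so exhaustive search is out of the
question).  Defaults, all overridable through `gaControl()`:

* population 50, initial sizes uniform on [1, ⌊m/10⌋];
* binary tournament with replacement (ties favour smaller subsets — a mild
  parsimony pressure that also makes selection deterministic given the
  draw);
* SSOCF crossover with probability 0.7: children keep all features common
  to both parents and split the rest so each child has exactly its
  parent's size;
* toggle mutation with probability 0.1: one uniformly drawn index is
  added or removed; removal that would empty a chromosome re-draws, since
  an empty subset has no fitness;
* elitism 1; stop at 100 generations or after 20 without improvement.
  Elitism detail and stopping are unstated in the wrapper literature this
  follows; something reproducible had to be fixed.

Fitness is the mean Matthews correlation coefficient of a class-weighted
linear SVM (`e1071`, linear kernel; per-class penalty weights counter the
class imbalance typical of mutagenesis data — presets
`classWeightPreset("set1")` = (9, 3) and `"set3"` = (5, 1.22) for the
critical / non-critical classes) over stratified 10-fold cross-validation.
A degenerate fold confusion scores 0, the standard convention.  The fold
assignment is drawn once per run and fitness values are cached per subset,
so fitness is a pure function of the subset and the whole run is
bit-reproducible for a given seed and table.

## Evaluation harnesses

`leaveOneOut()` pools all n held-out predictions into a single confusion
matrix (fold size 1 makes per-fold metrics degenerate).  Reports carry
per-class one-vs-rest TP rate, FP rate, precision, recall, the binary MCC,
and ROC area from the classifier's signed distance to the separating
boundary, computed by the rank statistic (ties counted half, so the area
is invariant under monotone score transforms).  Summary rows weight
per-class values by class support; for single-label binary classification
the weighted recall equals overall accuracy, an identity the tests assert.
`swappedTest()` trains on one table and evaluates on another, intersecting
descriptor panels with a warning.  `modelOverlap()` normalizes the shared
critical calls by each model's own critical-call count, which is what
makes the comparison asymmetric: a model whose critical set is contained
in another's is 100 % covered in one direction and less in the other.

## Synthetic generators

Every generator is a pure function of its seed and returns the ground
truth it planted, so downstream tests assert against recorded — not
re-derived — expectations:

* `makeStructure()` — deterministic C-alpha traces: a helix-like spiral
  (2.3 Å radius, 100° twist, 1.5 Å rise — the approximate alpha-helical
  geometry), a straight 3.8 Å-spaced line (whose 5 Å contact graph is a
  path, analytically), or a random coil walk.
* `makeMSA()` — homolog rows mutated per position with a fixed
  probability; realized per-column substitution fractions are returned.
* `makeMutagenesis()` — searches wild-types and small rank subsets for
  substitution sets whose index lands within 0.02 of a target, and emits
  the exact expected index.
* `makeFeatureTable()` — informative descriptors with a class-conditional
  mean shift (`effectSize`), class-independent noise, and optional
  monotone "twin" columns for the redundancy filter.  Class imbalance
  defaults to 20 % critical, the typical shape of curated mutagenesis
  datasets.

These fixtures emulate the *shape* of real data, not its physics:
coordinates are single-atom traces, alignment columns are independent, and
descriptor distributions are Gaussian.  Passing tests therefore
demonstrate the correctness of the algorithms and their contracts, not
classification performance on real proteins.

## Problem sizes used by the test suite

The descriptor-recovery experiment plants 5 informative among 100
descriptors at n = 300 instances, balanced classes, with a per-descriptor
shift of 1.5 standard deviations, run for three seeds.  The shift is
deliberately moderate: at large shifts any two or three informative
descriptors already saturate the cross-validated MCC and full-set recovery
becomes unidentifiable, while at 1.5 each additional planted descriptor
still raises fitness, so recovering (nearly) all of them is both
achievable and diagnostic.  Oracle-equivalence tests run on graphs of up
to 15 nodes, where exhaustive enumeration (all-pairs dynamic programming,
triangle counting, full shortest-path listing) is exact and fast.

## Known limitations

* Contact graphs are intra-chain; inter-chain contacts and multi-model
  ensembles are out of scope (only model 1 of multi-model files is read).
* The correlated-mutation index uses single-column frequencies, not
  pairwise covariation, and applies no phylogenetic correction.
* The criticality index requires binary phenotypes and at least one
  reported mutation per scored position; positions without data are
  excluded, never scored 0.
* The SVM is the packaged classifier; the harnesses accept a declared
  classifier contract, but no other backend ships with the package.
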