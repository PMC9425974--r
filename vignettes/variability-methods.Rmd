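---
title: "Estimating protein family variability from alignment column homogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein family variability from alignment column homogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcog)
```

## The problem

Evolutionary rate is one of the most informative characteristics of a gene
family, but estimating it properly requires phylogenetic reconstruction that
is expensive at pangenome scale. `varcog` implements a cheap, calibrated
proxy: sequence variability computed directly from multiple protein
alignments of clade-specific clusters of orthologous genes (csCOGs) —
families of orthologs (and recent in-paralogs) restricted to one clade of
closely related genomes, e.g. a prokaryotic genus or family with 30–60
sequenced members. Because all families in a clade share the same
evolutionary depth, their alignment-level conservation scores are
comparable after a single clade-wide normalization.

## Column homogeneity

For an alignment column with residues $a_i$ and sequence weights $w_i$
(equal, $w_i = 1/N$), every candidate amino acid $x$ receives the score

$$Q_x = \sum_i w_i\, S_{a_i,x},$$

where $S$ is a substitution score matrix (BLOSUM62 in half-bit units by
default). The residue $c = \arg\max_x Q_x$ is the effective consensus. The
consensus score is calibrated against the expectation for a random
assortment of residues,

$$Q_R = \sum_b f_b\, Q_b,$$

with $f_b$ the background amino-acid frequencies, giving the homogeneity

$$h = \max\!\left(\frac{Q_c - Q_R}{S_{c,c} - Q_R},\, 0\right) \in [0, 1].$$

An invariant column scores exactly 1; a column indistinguishable from a
random draw scores 0. Unlike column entropy, $h$ sees through conservative
substitutions because mismatches are weighted by the score matrix.

Practical choices the formula does not fix:

* **Gaps** — weights are renormalized over the non-gap rows of each
  column. Columns with fewer than two non-gap residues cannot express
  diversity and are masked: one residue is a *singular insertion* (present
  in a single sequence), zero is an all-gap column.
* **Ambiguous residues** (B, Z, X, U, O, J) are treated as gaps; score
  matrix files do not reliably define them.
* **Background frequencies** — any strictly positive table summing to 1 is
  accepted; the default is the Robinson–Robinson table commonly distributed
  with alignment toolkits. The table in use is recorded in the
  `ScoreModel` metadata. (Homogeneity of *invariant* columns is 1 for any
  valid background, which is why the fixed points below are exact.)
* **Consensus ties** are broken alphabetically. Ties are exact in rational
  arithmetic (integer scores, rational weights), so the implementation
  compares the floating-point scores with a 1e-9 guard to keep the
  tie-break deterministic across summation orders.

Families enter the analysis only if they have at least 8 non-identical
sequences (exact duplicates of the ungapped residue string removed) and at
least 60 informative (non-singular, non-all-gap) columns; smaller families
give unstable homogeneity estimates.

## Relative variability

Mean homogeneities are computed per family ($h_C$) and over the whole clade
($h_T$, pooled over all scored columns of all families so that family-level
and position-level normalization share the same constant; a mean-of-means
mode is available). A family's relative variability is

$$v_C = \frac{(1 - h_C)\, h_T}{(1 - h_T)\, h_C},$$

which is 1 exactly when $h_C = h_T$, 0 for an invariant family, and grows
without bound as $h_C \to 0$. Families with $v < 0.5$ are classified
*conserved*, $v > 2$ *variable*, the closed band between them
*intermediate* (the boundary values are intermediate: the outer classes
are open intervals). The same transform applies per column, giving
position-level classes whose relative frequencies (a point on a 2-simplex)
fingerprint families with unusual conservation architecture; columns with
$h = 0$ get a finite sentinel (default 1e6, flagged in the output) standing
in for arbitrarily high variability. Raw, unsmoothed $h$ is used for
classification; smoothing is reserved for the distribution geometry below.

`cladeMeanHomogeneity()` refuses degenerate inputs ($h_T \ge 1$ or
$\le 0$): the transform requires that some column beats chance and some
column is imperfect.

## Homogeneity-distribution geometry

To compare families by the *shape* of their conservation profiles rather
than the mean, each profile is smoothed along the sequence with a Gaussian
kernel, $h_i' = \sum_j h_j K_{ij} / \sum_j K_{ij}$ with
$K_{ij} = \exp(-((j - i)/b)^2)$ and bandwidth $b = 20$ positions. The
kernel is truncated at the profile ends and the normalization absorbs the
edge effect; masked columns are excluded from the sums but keep their
coordinates, so distances across masked stretches are respected. The
smoothed values are converted to a probability density on a fixed grid of
101 equidistant points on $[0, 1]$ by a Gaussian KDE with Silverman's
rule-of-thumb bandwidth and boundary reflection at 0 and 1 (homogeneity
cannot leave the unit interval), renormalized to unit mass; a family whose
smoothed values all coincide degenerates to a unit spike at the nearest
grid point. Pairs of families are compared by the discrete Hellinger
distance

$$d(P, Q) = \sqrt{1 - \sum_i \sqrt{p_i q_i}} \in [0, 1],$$

and the resulting distance matrix is embedded in the plane by classical
(Torgerson) multidimensional scaling — R's `cmdscale`, with negative
eigenvalues truncated and reported.

Numerical notes: the density estimator and its bandwidth rule are recorded
in the `HomogeneityDensity` metadata; unit-mass normalization is what
bounds the Hellinger distance in $[0,1]$.

## csCOG extraction from gene trees

Gene trees mix orthologs, paralogs, and xenologs. Within a tree whose
leaves come from $S$ distinct genomes, a clade with $P_C$ leaves from
$S_C$ genomes has paralogy ratio $P_C/S_C$, genome coverage $S_C/S$, and
the coverage-paralogy tradeoff index

$$\frac{S_C^2}{P_C\, S} = \text{coverage} \times \frac{1}{\text{paralogy}}.$$

The clade maximizing the index is carved out as a csCOG (unless it is the
root, in which case the remaining tree is the final csCOG) and the
procedure iterates on the pruned tree. Design choices:

* $S$ stays frozen at the original genome count across rounds, keeping
  coverage comparable between rounds (recomputation per round is available
  via `freezeS = FALSE`).
* Leaves are eligible clades (index $1/S$), so orphan sequences become
  singleton csCOGs instead of being absorbed into the residual group.
* Ties on the index are broken by larger $S_C$, then smaller $P_C$, then
  the lexicographically smallest member sequence id. The final tie-break
  matters: tied maxima are disjoint clades, and extracting one can raise an
  ancestor's index above the other, changing the rest of the partition —
  so the rule must be a function of the leaf set alone. Traversal-order
  tie-breaks (e.g. postorder position) are not: they change under sibling
  rotations of the very same tree.
* Unrooted input trees are midpoint-rooted (with unit branch lengths
  substituted when the file carries none).

## Gain/loss interpretation of presence posteriors

Ancestral presence/absence reconstruction tools emit, for each family, a
posterior probability of presence at every node of the species tree.
`varcog` interprets these: a parent-to-child difference $\ge 0.5$ is a
discrete gain, $\le -0.5$ a loss. The root receives a virtual edge from
absence, so a root posterior $\ge 0.5$ registers the family's origination
as one gain; totals are reported with and without this root term so either
convention is recoverable. Expected totals over the whole history are the
sums of positive and negative differences. A family is *ancestral* when
the root posterior is $\ge 0.5$ (boundary inclusive); otherwise the
deepest (closest to the root) gain edge decides *intermediate* (internal
edge) versus *terminal* (leaf edge) acquisition — the category names are
standard, the deepest-gain-edge rule is this package's operational
definition — and families with no gain at all are flagged unclassified.

## Microsatellite-like regions

In a random sequence over an alphabet of size $A$, a fixed $k$-mer occurs
at each of $t = L - k + 1$ start positions of an $L$-character stretch
independently with probability $p = A^{-k}$; the recurrence count is
binomial, and a recurrence is *non-random* when the upper tail
$P(X \ge n)$ falls below $10^{-6}$ locally (within a 1000-character
window). For hexamers this yields the threshold ladder 6/5/4/3 recurrences
within 1000/500/200/80 bp. The trial count $t = L - k + 1$ is the reading
that reproduces the ladder exactly, including the borderline 80-bp case
(tail $9.7 \times 10^{-7}$).

MSR coverage is built from *tandem* recurrences: occurrences of the same
motif at start-to-start intervals $I \le k$ (overlaps allowed) form
chains; a chain is significant when its count within its own span (capped
at the window) beats the threshold for that span; a significant chain
covers its footprint, per-$k$ regions closer than $k$ merge, and the
tracks for $k = 1..6$ unite into one disjoint annotation. Testing the
$I \le k$ chains directly — rather than arbitrary occurrence stretches —
keeps a strong repeat from dragging unrelated distant occurrences of the
same motif into coverage, and makes recall of planted arrays deterministic
rather than dependent on chance background occurrences; scattered
recurrences without $I \le k$ partners contribute no coverage under any
reading, so nothing observable is given up. Ambiguity characters (N
etc.) never occur inside motifs and break chains. A 7-nt homopolymer
alone is already flagged (two overlapping hexamer copies, $t = 2$, tail
$p^2 \approx 6 \times 10^{-8}$).

A consequence worth stating plainly: the $10^{-6}$ threshold is per test,
and the scan performs one test per recurrence chain over all motifs and
positions. Chance short perfect repeats — 6-bp homopolymers (significant
via $k=3$: tail $(1/64)^4 \approx 6\times 10^{-8}$), ~9-bp period-2 or
period-3 repeats — occur in i.i.d. sequence at a rate of roughly one per
kb and are flagged. They are real repeats of the kind the definition
targets; whether they are "false" positives depends on whether the null
model is the whole sequence or the local window. Aggregate false-positive
counts over many kilobases therefore far exceed the naive per-test bound,
which is worth remembering when interpreting genome-wide MSR fractions.

## Synthetic data: what it does and does not emulate

The generators provide ground-truthed inputs for every stage:

* `simulateFamilyAlignment()` — star-tree substitution: a consensus drawn
  from the background; each sequence substitutes each site independently
  with probability $\theta$ by a background draw. This induces controlled
  column homogeneity (the quantity under test) but no phylogenetic
  correlation structure, no indels, no rate variation across sites —
  passing recovery tests shows the homogeneity-variability pipeline ranks
  divergence correctly, not that it handles tree-structured data better
  than any other column score. The background table is shared with the
  default `ScoreModel` so the $Q_R$ calibration is coherent.
* `plantMsrSequence()` — i.i.d. uniform background with a planted tandem
  array and exact truth coordinates.
* `simulateLabeledGeneTree()` — random species topology with whole-tree
  duplications by default: each duplication doubles every genome, and the
  duplicate copies are the true ortholog groups. Whole-tree duplication is
  the default because only copies whose genome coverage rivals the root's
  are separable by a coverage-maximizing index; duplications of partial
  subtrees (available via `at = "internal"`) produce paralogy that the
  extraction is *not* meant to resolve, which is itself worth knowing.
* `simulatePresenceHistory()` — Markov gain/loss along the tree emitted as
  0/1 posteriors with the exact event list, making event inference testable
  for equality rather than approximation.

All generators are deterministic under their `seed` argument and leave the
caller's RNG stream untouched.

## Problem sizes and defaults

The shipped tests and the acceptance script run at desk scale: 20 families
per divergence level on a 12-level $\theta$ grid (0.05–0.6), alignments of
10 sequences by 100 columns, 50 random gene trees of up to 12 leaves, 100
simulated presence histories on an 8-leaf species tree, 200 random 1-kb
sequences for the false-positive census, and 1000 fuzz columns against the
brute-force homogeneity oracle. These sizes make every distributional
claim reproducible in well under a minute each while keeping Monte-Carlo
noise far from the asserted margins.

Key defaults (all overridable): BLOSUM62 half-bit matrix; Robinson–Robinson
background; filter minima 8 sequences / 60 columns; variability thresholds
0.5 and 2; smoothing bandwidth $b = 20$ positions; 101-point density grid;
MSR $\alpha = 10^{-6}$, window 1000, $k \le 6$; position-variability
sentinel 1e6.

## Known limitations

* Equal sequence weights only (plus user-supplied vectors); no tree-aware
  down-weighting of redundant sequences, so clades of near-duplicates pull
  $h$ upward.
* The star-tree generator cannot produce the correlated rate structure of
  real families; parameter-recovery results bound what the tests
  demonstrate about real alignments.
* csCOG extraction assumes the gene tree is correct; it has no concept of
  support values, and partial-coverage duplicates are not separable by
  design.
* The gain/loss module interprets posteriors; it does not infer them, and
  its intermediate/terminal split is one reading of categories whose
  operational definition is not standardized.
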