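---
title: "OTU clustering by MCC optimization: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OTU clustering by MCC optimization: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otufit)
library(tibble)
```

## The model

Amplicon analyses bin 16S rRNA gene sequences into operational taxonomic
units (OTUs), conventionally at a 3% pairwise distance threshold.  The
quality of a set of OTU assignments can be judged directly against that
definition: every unordered pair of sequences is either *similar* (recorded
distance at or below the threshold) or not, and either co-clustered or not.
Crossing the two gives a confusion matrix over pairs —

* true positive: similar and in the same OTU,
* false negative: similar but split across OTUs,
* false positive: dissimilar but in the same OTU,
* true negative: dissimilar and separated —

and the Matthews correlation coefficient (MCC)

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$

summarizes the four counts in one number in $[-1, 1]$.  `otufit` implements
the two optimizers built on this objective:

* **`opticlust()`** (de novo): every sequence starts as its own singleton
  OTU; each sweep visits all sequences in a freshly shuffled order and
  moves each one to whichever option — stay, join an OTU containing at
  least one of its similar sequences, or split off as a new singleton —
  maximizes the MCC.
* **`optifit()`** (reference-based): reference OTU assignments are frozen;
  queries start as singletons and are iteratively reassigned among the
  reference OTUs that contain at least one of their similar sequences,
  maximizing the MCC over *all* pairs of the combined universe
  (reference–reference pairs included; a query whose best option is its
  own singleton stays unassigned).  Closed mode then discards unassigned
  queries; open mode clusters them de novo and appends the result as new
  OTUs.

Both optimizers stop when a full sweep improves the MCC by no more than a
tolerance, or when the sweep cap is reached.

## Input model: the sparse similarity graph

The only input the optimizers consume is which pairs are within the
threshold — a sparse graph built by `sim_graph()` from pairwise distances
(sparse column files or PHYLIP-style matrices).  Two conventions matter
and are deliberately explicit:

* **Boundary**: a distance exactly equal to the threshold counts as
  *within* (`<=`).  This matches the cutoff semantics of the ecosystem the
  column format comes from, but is a dialect choice; files produced under
  a strict-`<` convention will differ at boundary distances.
* **Sparsity**: a pair absent from a column-format file is treated as
  above threshold.  Consequently the full sequence universe (FASTA or
  name list) is required with column input — sequences with no close
  neighbor never appear in the distance file at all, and dropping them
  silently would change every pair count.

Duplicate listings of a pair are accepted when they agree about the
threshold and rejected as ambiguous when they straddle it; self-pairs are
ignored with a warning.

## Numerical conventions

* Confusion counts are exact (integer-valued doubles; they reach
  $n^2/2$).  The MCC denominator is computed as a product of four square
  roots rather than the square root of a product, so marginal products
  cannot overflow double precision.
* **Zero marginals.** When any marginal sum is zero the MCC formula is
  0/0; `otufit` defines the value as 0 ("no better than random").  The
  convention is mostly felt on degenerate toy inputs, and two consequences
  deserve a flag.  First, on a *complete* graph (no dissimilar pairs at
  all) every partition has a zero marginal, so all candidate clusterings
  tie at 0 and the optimizer's result among them is arbitrary.  Second, on
  a two-sequence subgraph joined by one edge, "merged" (TP=1, rest 0) and
  "apart" (FN=1, rest 0) both score 0, so whether the open-mode de novo
  step merges such a pair is decided by the tie-breaking RNG.  Real
  datasets, which always contain dissimilar pairs, are unaffected.
* **Ties.** Candidate moves whose MCC lies within `1e-12` of the best are
  treated as tied and broken uniformly at random; "stay" is one of the
  tied options and never wins by default.  This tolerance is distinct from
  the *convergence* tolerance (below).
* Accepted moves are applied through exact local updates (`move_delta()`):
  leaving an OTU where the sequence has $k$ similar members and $m$
  dissimilar ones changes the counts by $(TP{-}k, FN{+}k, FP{-}m, TN{+}m)$,
  joining is the mirror image.  The incremental state is cross-checked
  against a full recount at the end of every run.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `threshold` | 0.03 | distance fraction | defines similar pairs; changes the graph itself |
| `tolerance` | 0.0001 | MCC | minimum sweep-over-sweep gain to keep iterating |
| `max_iterations` | 100 | sweeps | hard cap when the tolerance is never reached |
| `seed` | 1 | — | drives visit order and tie breaks; fixed seed ⇒ bit-identical output |
| `mode` | — | open/closed | fate of unassigned queries in `optifit()` |

Convergence is assessed on the MCC after each *full pass* over the movable
sequences; visit order is reshuffled every sweep.  Because "stay" is
always available, the MCC trace over accepted moves is non-decreasing (the
engine asserts this in-run, and every result object carries the trace).

Two reporting choices are worth knowing about.  In closed mode the
returned confusion matrix and MCC are computed over the *retained*
universe — references plus mapped queries — because discarded sequences no
longer have pair outcomes; open mode reports over the full combined
universe.  And `fraction_mapped` is the share of queries placed into
reference OTUs (1 by construction in open mode; a zero-query fit reports 1
with a `no_queries` flag).

## Splitting strategies

For split-dataset experiments (`split_simple()`, `split_abundance()`,
`split_similarity()`), the reference side has `round(fraction * n)`
members (rounding half away from zero) and weighted sampling is performed
as sequential draws without replacement with renormalization — base R's
`sample(prob = )` scheme, stated explicitly because different weighted
without-replacement schemes have different inclusion probabilities.
"Similarity to other sequences" is operationalized as similarity-graph
degree with +1 smoothing so that sequences with no close neighbor remain
selectable; summed similarities or distance ranks would be equally
plausible readings, and the choice is documented rather than claimed
canonical.  Note a worked consequence of the formula: in a 5-sequence star
graph the hub (degree 4) carries weight 5 of 13, not 5 of 9 — leaf degrees
count too.

## Synthetic data and what passing tests mean

`generate_planted_graph()` emulates the one property the optimizers
consume: a sparse graph whose edges concentrate within planted OTUs
(`p_within`, default 0.9) with sparse noise across them (`p_between`,
default 0.005).  The default shape — 30 OTUs with sizes drawn from 1–19,
about 300 sequences — includes the rare tail (singleton and doubleton
OTUs) that dominates real communities; without it, closed-reference
fitting degenerates, as every query can be mapped at every reference
fraction and the fraction-mapped curve saturates at 1.
`generate_sequence_family()` produces equal-length sequences whose
pairwise distance is the Hamming mismatch fraction — a fixture
simplification, not a reimplementation of an aligner's distance; there is
no alignment, length variation, chimera structure, or abundance skew.
Tests passing on these fixtures validate the optimization and accounting
machinery, not preprocessing of real amplicon reads.

The brute-force oracles are the independent ground truth for small
instances: `brute_force_best_partition()` enumerates all set partitions
(restricted growth strings, capped at 12 sequences),
`brute_force_best_fit()` enumerates every assignment of queries to
(reference OTUs ∪ own singleton) with references frozen — the same move
space as the fit phase.  The package's evaluation uses 400 random graphs
($n \le 7$) and 400 planted fit instances (≤6 reference OTUs, ≤4
queries), 10 seeds each; the split-fit comparisons run on the ~300-sequence
planted default with 20 seeds at a 50% split and 5 seeds per reference
fraction across 10–90%.

## Known limitations

* **Greedy traps.** The optimizer only ever moves one sequence at a time,
  monotonically.  Instances exist where the global optimum requires a
  *coordinated* move — e.g. two similar queries, each with one weak link
  into a reference OTU, that must join it together because each join alone
  lowers the MCC.  No visit order or tie-break escapes such a trap, so
  best-of-many-seeds stays below the exhaustive optimum; on small planted
  fit instances this affects roughly 3–5% of cases.  This is a property of
  the published greedy dynamics, not of this implementation.
* During the fit phase two unassigned queries never merge with each other;
  query–query OTUs can only arise in the open-mode de novo step.  The
  alternative reading (allowing query–query OTUs mid-fit) would change
  results on instances like the trap above — it is deliberately not
  implemented, and the restriction also defines the move space of the fit
  oracle.
* Dereplication (names/count files mapping duplicate reads onto unique
  sequences) is not modeled; every id is an independent sequence, and
  abundance enters only through the count table used by
  `split_abundance()`.
* The closed-mode evaluation universe (retained vs full) is a reporting
  choice, as noted above; comparisons against tools that score closed
  results over the full universe must account for it.
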