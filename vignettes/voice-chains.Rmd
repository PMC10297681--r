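---
title: "Voice chains: linking gene sets to voice-related pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voice chains: linking gene sets to voice-related pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicechain)
```

## The model

A biological pathway is treated purely as the set of gene symbols it
involves, $B = \{g\}$. Two pathways are *linked* when they share at least one
gene, $B_1 \cap B_2 \neq \emptyset$; a collection of pathways therefore forms
an overlap graph with pathways as nodes. A *pathway chain* is a non-repeating
sequence of pathways in which every adjacent pair is linked. A *voice chain*
is a pathway chain whose head node $B_V$ -- and the head node alone --
contains a designated voice-related gene (FOXP2 throughout this vignette),
and whose terminus $S$ is not a pathway but an arbitrary gene set with a
common characterization, here the set of genes deleted in a chromosomal
microdeletion region. The *level* $\alpha$ of a chain is the number of
pathway nodes, not counting the terminus, so a level-1 chain is a head
pathway directly containing a gene of $S$, and a level-2 chain passes through
one intermediate pathway that overlaps a head pathway.

The genes of $S$ through which level-$\alpha$ chains reach it form the
*chainlink set* $V^{\alpha}$. The search is deliberately capped at
$\alpha \le 2$: beyond two pathway hops the chained influences cannot be
disambiguated, and extending chains further would require reusing pathways.
`find_chainlinks()` computes both sets with an inverted gene-to-pathway
index, which is exactly a breadth-first expansion from the head pathways:
level 1 is $S$ intersected with the head pathways' genes; level 2 is $S$
intersected with the genes of pathways that overlap a head pathway. No chain
reuses a pathway, which at these depths holds by construction because the
intermediate of a level-2 chain is never a head pathway.

Two reporting conventions matter and both are implemented:

* **Exclusive vs inclusive levels.** By default a gene already reported at
  level 1 is not repeated at level 2 (the two counts of the syndrome table
  are printed as separate columns, which only makes sense if they are
  disjoint); `inclusive = TRUE` switches to pure set membership per level.
  The packaged fixtures carry printed counts, so no fixture-based result
  depends on this choice.
* **Connectivity.** The *chainlink connectivity* of a gene set is the number
  of ensemble pathways containing its genes. The default `"union"` mode
  counts pathways the genes *collectively* touch, including head pathways:
  a syndrome whose single chainlink gene connects only to the head pathway is
  printed as connectivity 1 in the source material, which a strict
  "additional pathways" reading would print as 0. `"sum"` mode and an
  `exclude_head` flag expose the other readings.

When several pathways contain the head gene, every operation takes the union
over all of them; the motivating ensemble happens to have exactly one
(the 63-gene Adenoid Cystic Carcinoma pathway, shipped as
`acc_pathway()`).

## Phenotype annotation and cohort statistics

Reported speech effects are free text. `parse_effects()` maps them onto a
closed taxonomy -- normal, apraxic, dysarthric, impaired, delayed, absent --
using the code tokens conventionally used in the syndrome table (`Del`,
`Imp`, `Norm`, `Abs`, `Apr`, `Dys`, `Idio`; case-insensitive and
word-bounded) plus their spelt-out clinical forms, and a tiny phrase map
("No significant ...", hearing-only findings) for rows that describe no
speech anomaly. Idiosyncratic speech folds into apraxic by default, since
apraxia typically subsumes it; a flag keeps it separate. Deliberately, there
is no NLP beyond this ruleset: the inputs are short, coded strings, and an
auditable rule table is both sufficient and reproducible.

`build_cohort()` applies the cohort rules: regions listed twice because the
literature splits them by symptoms (not by gene content) are merged, keeping
one copy of the chain counts and the union of categories; rows with no
usable speech information are dropped. Rows that carry conflicting counts
for the same region are refused as an ambiguous merge. On the packaged
76-row table this produces the 73-syndrome analysis cohort whose
co-occurrence structure `cooccurrence_stats()` summarizes.

`category_stats()` tabulates, per category, the number of syndromes and the
mean and median of the *level-2* chainlink counts and connectivities.
Level-2 values alone are used because that convention exactly reproduces the
fully determined absent-speech row of the published summary from the fixture
(verified by independent spreadsheet arithmetic before the implementation
was written). Membership is non-exclusive -- a syndrome reported as
"delayed or absent" contributes to both rows -- and a syndrome with a
normal reading among other effects still contributes to the normal row (the
published 6-member normal group is not uniquely recoverable from the printed
table, so the normal row's own statistics are treated as indicative only).
Categories are rank-ordered by ascending mean chainlink count with ties
broken by ascending mean connectivity.

One caveat this package surfaces honestly: on the packaged transcription the
impaired and delayed groups have mean chainlink counts within about one gene
of each other, and the computed order places delayed before impaired,
whereas the published ordering prints the opposite. The two categories are
described in the source material as comparable in severity, and the
published impaired mean cannot be reconstructed from any category assignment
the printed table supports, so the adjacent swap is an irreducible
transcription-level discrepancy rather than a property of the method. The
robust qualitative claims -- normal lowest, absent highest -- hold exactly.

## The dispersion model

Chainlink counts and connectivities across syndromes are over-dispersed
counts, modelled as Conway--Maxwell--Poisson:
$$P(n) = \frac{\lambda^n}{(n!)^\nu}\,\frac{1}{Z(\lambda,\nu)},\qquad
Z(\lambda,\nu) = \sum_{n\ge 0}\frac{\lambda^n}{(n!)^\nu},\qquad
\lambda,\nu>0.$$
$\nu = 1$ recovers Poisson, $\nu < 1$ over-dispersion, $\nu > 1$
under-dispersion.

**Numerics.** Connectivity values reach several thousand, far beyond naive
factorial range, so everything is computed in log space. The normalizer
series is summed past its largest term (near $n = \lambda^{1/\nu}$) and
truncated when the next term falls below $10^{-12}$ times the partial sum,
with a hard cap of $10^5$ terms; parameter corners whose largest term lies
beyond the cap (tiny $\nu$ with $\lambda \ge 1$) are refused by a guard that
names the offending region rather than silently truncating a divergent sum.
The fitted PMF sums to 1 within $10^{-9}$ over the truncated support, which
the test suite asserts for every parameter pair it fits.

**Fitting.** `fit_cmp()` maximizes the log-likelihood over
$(\log\lambda, \log\nu)$ from two deterministic starts -- a moment-matched
point ($\nu_0$ from the mean/variance ratio, $\lambda_0$ from the CMP mean
approximation $\lambda^{1/\nu} - (\nu-1)/2\nu$) and the Poisson point
$(\bar{x}, 1)$ -- keeping the better optimum, so the fit is a pure function
of the data. For strongly under-dispersed small samples the CMP likelihood
increases monotonically along a ridge toward $\nu \to \infty$ (the
distribution degenerates to a point mass); when the simplex search runs out
of iterations on such a ridge, a box-constrained quasi-Newton step with
$\nu \in [10^{-4}, 100]$ finishes the fit at a well-defined constrained
maximizer. With `fix_nu = 1` the fit collapses to the closed-form Poisson
MLE, a cross-check the tests exercise.

**Code distance.** For two integer sets $C_i, C_j$ with fitted models
$\hat P_i, \hat P_j$, the distance is the excess number of bits required to
encode each set under the other set's optimal code rather than its own:
$$D = \sum_{n\in C_i}\log_2\frac{\hat P_i(n)}{\hat P_j(n)}
    + \sum_{m\in C_j}\log_2\frac{\hat P_j(m)}{\hat P_i(m)}.$$
The formula is sometimes written with the two ratios inverted, which makes
the expected value negative; the prose definition ("excess bits") fixes the
orientation used here, which is non-negative in expectation and symmetric by
construction, and an `as_printed` flag restores the inverted sign convention.
Cross-coded probabilities of grossly mismatched sets can underflow; the
log-PMF is floored at $e^{-700}$ with a warning so distances stay finite.
Exact published distance-table values are *not* reproducible -- they depend
on estimator and truncation details that are not stated -- so the package
tests the structure instead: symmetry, a zero diagonal, agreement of
large-sample distances with the plug-in
$n_i\,\mathrm{KL}(P_i\|P_j) + n_j\,\mathrm{KL}(P_j\|P_i)$ computed from the
true PMFs, and, on the fixture, that the normal-speech row dominates every
column of both matrices (normal speech standing clearly apart).

## The chance model

Why are chains never missing? If $m$ of the $N$ genes in the symbol universe
lie on pathways linked to a head pathway, a uniformly drawn gene is level-2
material with probability $p = m/N$, and a region of $k$ independent genes
carries a level-2 chain with probability $1 - (1-p)^k$. With the motivating
census ($m = 11{,}746$, $N = 42{,}764$, so $p \approx 27.5\%$) even the
shortest region considered (9 genes) reaches about $94\%$, which is the
entire explanation for the observed ubiquity of level-2 chains.
`linked_gene_census()` recomputes $m$ from any ensemble; genes occurring
*only* in head pathways are excluded by default (they are level-1, not
level-2, material -- the printed census value cannot adjudicate this
convention, so a flag provides the alternative), and the universe size is an
explicit input because a pathway collection covers only a fraction of the
genome. `chain_fraction()` gives the per-region covered fraction whose mean,
under the randomness assumption, matches $p$; the test suite verifies this
and the binomial agreement of simulated region frequencies with the closed
form on synthetic ensembles.

## The synthetic generator

`generate_ensemble()` emulates a pathway collection with a planted head gene
and tunable overlap: each new pathway inherits, with probability equal to the
overlap density, one gene from each earlier pathway, then fills up with fresh
genes, so the density is approximately the pairwise linkage probability, with
density 0 giving pairwise-disjoint pathways and density 1 a complete overlap
graph. `plant_region()` builds terminal sets with exact numbers of true
level-1, true level-2 (exclusive convention) and inert background genes, and
returns the truth labels. `brute_force_chainlinks()` re-derives chainlink
sets by nested loops over pathway pairs, sharing no code or index with the
production search, and is the independent oracle in the equivalence sweeps.

What the generator does *not* emulate: the heavy-tailed size distribution of
real pathway collections, gene multifunctionality beyond pairwise sharing,
within-genome gene families, or any biological structure in which genes
co-occur. Passing the sweeps therefore demonstrates algorithmic correctness
of the search on arbitrary overlap topologies, not biological validity of
any particular chain.

Test problem sizes were chosen to keep the whole suite fast while leaving
the oracle space non-trivial: equivalence and recovery sweeps use 100 seeded
ensembles of 20 pathways over a 250-gene universe at density 0.4 (every
planting seed is feasible there), parameter recovery uses 20 seeds at
2,000 draws, and the plug-in KL comparison uses two 1,000-draw samples.

## Known limitations

* Linkage is binary; edges are not weighted by the number of shared genes,
  and no level-3+ chains are searched (by design, see above).
* Symbol handling is uppercase-plus-trim only; no alias resolution is
  attempted, so ensembles and terminal sets must use the same nomenclature.
* The severity taxonomy is a reporting convention, not a clinical grading;
  category statistics inherit whatever reporting bias the underlying
  literature has.
* CMP fits for tiny, nearly constant sets sit on the $\nu$ box bound and
  should be read as "effectively degenerate", not as precise dispersion
  estimates.
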