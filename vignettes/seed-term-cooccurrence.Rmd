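---
title: "Mining seed-term co-occurrence in clinical records: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining seed-term co-occurrence in clinical records: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termnet)
```

## The problem

Hospitals that introduce a structured intervention — here the motivating
case is an antimicrobial stewardship program (ASP) run by ward
pharmacists — often want to know whether the *content* of clinical
documentation changed, not just its volume. termnet operationalizes one
way of asking that question: select the records that mention an anchor
("seed") term such as *antimicrobial*, reduce each record to a set of
standardized content terms, measure term-to-term association with the
Dice coefficient, organize the terms into a seed-centered co-occurrence
network and into clusters, and compare how often each cluster of terms
appears in records before versus after the intervention.

The pipeline assumes two-period data (a `pre`/`post` label derived from
a calendar cutoff month), records short enough that *record-level*
presence/absence is the meaningful co-occurrence unit, and a seed term
that is present in every selected record by construction.

## Stages and the quantities they compute

**Tokenization contract.** Morphological analysis is external to the
method: any tokenizer that emits `surface`, `base_form` and a
part-of-speech pair from the closed tagset (`POS_MAJOR`) can be
registered. The package ships an `annotated` tokenizer that parses
pre-tagged streams (`crp/noun wa/particle rise/verb`), which is what the
test suite and the synthetic generator use; an adapter for a Japanese
morphological analyzer would register the same contract. Base forms are
counted by default (surfaces are a flag) — inflection should not split a
term's record set.

**Filtering and anonymization.** The default `pos_filter_rules()` keep
nouns, verbs, adjectives, adverbs, interjections and prenominal
adjectives; drop suffixes, numbers, pronouns, formal nouns and auxiliary
nouns within nouns, auxiliary adjectives within adjectives, and all
symbols, particles and auxiliary verbs. Tokens tagged as person,
organization or location proper nouns are removed (or redacted to a
placeholder) before any counting; both operations are idempotent and
commute, which the suite checks property-style.

**Standardization.** Three tables drive it: a compound lexicon (noun
sequences merged to one term, greedy longest match, left to right), a
synonym table keyed by controlled-vocabulary identifiers (terms sharing
a MeSH/SNOMED CT code collapse to one canonical form), and an exclusion
list (plus an unconditional drop of single alphabet characters).
Matching keys are width-folded and lowercased; emitted canonical forms
are not rewritten. Merging, mapping and dropping can only reduce the
number of distinct term types. The greedy merge is equivalent to
re-tokenizing with a user dictionary as long as lexicon entries do not
overlap; overlaps resolve to the longest match.

**Compound discovery.** Candidates are maximal runs of adjacent noun
tokens. For a candidate $W = N_1 \dots N_L$ with corpus frequency
$f(W)$,
$$ LR(W) = \Big(\prod_{i=1}^{L}(FL(N_i)+1)(FR(N_i)+1)\Big)^{1/2L},
   \qquad FLR(W) = f(W)\,LR(W), $$
where $FL$/$FR$ count noun-bigram occurrences with $N_i$ as right/left
element. This is the geometric-mean ("average rate") form of
Nakagawa-style term scoring with bigram-frequency neighbor counts; both
are exposed because term-extraction tools differ in which variant they
compute. The compound lexicon is the multi-token candidates in the top
5% of $FLR$ scores (`select_top_percentile()`): the threshold is the
`ceiling(0.05 n)`-th largest score over *all* candidates, ties included.
Restricting the quantile population to multi-token candidates is a flag;
the default uses all candidates because single nouns dominate the score
distribution that the percentile is meant to summarize.

**Dice network.** With record sets $A, B$ for two terms,
$\mathrm{Dice}(A,B) = 2|A\cap B|/(|A|+|B|)$. Because the seed is in all
$n$ records, its coefficient with a term of frequency $f$ reduces to
$2f/(n+f)$, so an edge threshold $\theta$ admits exactly the terms with
$f \ge \theta n/(2-\theta)$ ($\theta = 0.3$: $f \ge 239$ of 1,353). The
default $\theta = 0.3$ is deliberately conservative since Dice runs
higher than Jaccard. The network's node set is the *connected component
containing the seed* in the thresholded pairwise-Dice graph, which
includes terms tied to the seed only through intermediaries — that is
why a per-period network can hold more nodes than the seed's direct
co-occurrent list. The alternative (seed plus direct neighbors only)
is a documented configuration choice, not the default. Networks are
built per period; their node-set union feeds clustering.

**Communities and spanning tree.** Louvain modularity optimization on
the Dice weights (resolution 1) labels the communities; node visiting
order is randomized, so the partition is made reproducible by seeding
the generator (`random_seed`). The maximum-weight spanning tree
(Kruskal on descending Dice, ties broken lexicographically by endpoint
names so the tree is unique and stable) is exported for legible
depictions; it never feeds statistics.

**Clustering and cross-tabulation.** Terms in the union node set are
clustered by Ward's method applied directly to $1-\mathrm{Dice}$
through the Lance–Williams recurrence (`stats::hclust`, `ward.D2`),
without any embedding step — the same treatment a precomputed condensed
matrix receives in the usual scientific-Python implementation, verified
in the suite against a naive recurrence oracle. The pairwise Dice for
clustering is computed on the pooled two-period record set by default
(`dice_pool` offers per-period alternatives), since the dissimilarity
should describe the whole study window when the resulting clusters are
compared *across* periods. The cluster count is 10% of the clustered
terms with half-up rounding, floored at 2; `k_override` exists because
cluster counts in published analyses are routinely fixed after
dendrogram inspection and no rounding rule recovers, e.g., 7 from 84.
A record contains a cluster if it contains any member term; the
per-cluster 2×2 table (post-with, post-without, pre-with, pre-without)
yields the sample odds ratio $ad/(bc)$ — oriented post over pre — a 95%
interval, and a two-sided Fisher exact p-value (point-probability
rule, via `stats::fisher.test`, which the suite checks against
exhaustive hypergeometric enumeration). No multiplicity adjustment is
applied across clusters, matching common practice for this descriptive
design; the result table prints p-values below 0.01 as "< 0.01".

### Confidence-interval method

`odds_ratio()` defaults to the Wald interval
$\exp(\ln OR \pm 1.96\,SE)$, $SE = \sqrt{1/a+1/b+1/c+1/d}$, with the
Haldane–Anscombe +0.5 correction (flagged) when a cell is zero and an
explicit `NA` when a full diagonal is zero. It also offers
`ci_method = "exact"`, the conditional exact interval from the
noncentral hypergeometric likelihood. The two differ in the second
decimal place for several published 2×2 tables we reproduce in the
acceptance tests: the exact interval matches all seven printed
intervals of the motivating study, while Wald deviates by 0.01 on four
bounds. Wald remains the default because it pairs naturally with the
sample odds ratio and is the textbook companion of the $ad/(bc)$
estimate; reproductions of printed tables should state which method
they use.

### Sensitivity analysis

`run_sensitivity()` re-runs the identical pipeline after dropping all
records dated at or after a configurable month (default 2020-04, the
start of pandemic-era disruption in the motivating setting), comparing
pre against the early post window only. Totals-of-record denominators
are dropped for the truncated window because they are no longer known.

## The synthetic corpus generator

Protected health records cannot ship with a package, so
`generator_config()`/`generate_corpus()` emit two-period corpora with
known ground truth. Per record: the seed term always; each planted
cluster activates as Bernoulli($\pi_{\text{period}}$) with
$\mathrm{odds}(\pi_{\text{post}}) = OR_c \cdot
\mathrm{odds}(\pi_{\text{pre}})$; an active cluster always emits its
first member (the "head" — this makes record-level cluster incidence
coincide with activation when background noise is off, which is the
identifiability condition for odds-ratio recovery) and other members
with probability `q`; every member also fires as noise with probability
`epsilon`. Records are padded with negative-binomial filler nouns,
Poisson-injected particles and proper-noun identifiers, and optional
adjacent-noun compound runs, then rendered in the annotated dialect.
Months are uniform within each period's range — no temporal trend is
modeled.

Defaults mirror the documented conditions of the motivating corpus:
1,353 pre- and 5,155 post-period records, April 2014–March 2022 with
the cutover at April 2018, and `filler_mu = 50` chosen so total
analyzed terms per record land in the reported 55–65 band;
`q = 0.9` and `epsilon = 0.02` were fixed once as plausible
co-activation tightness and noise for topical clinical terms. What the
generator does **not** emulate: real lexical diversity (the filler
vocabulary is 40 types, so filler terms are far more common per type
than real general vocabulary), temporal drift within periods, author
effects and template phrasing, or realistic morphology. Passing
recovery tests on this generator therefore demonstrates correctness of
the *computations* under the planted model, not robustness to real
clinical language.

## Numerical conventions and degenerate inputs

* Report rounding is half-up at the conventional precisions (2 decimals
  for percentages and odds ratios, 1 for means/shares-of-record, 3 for
  Dice); internal computation is never rounded.
* Dice of two all-absent terms is defined as 0 with a warning; an
  isolated seed yields a single-node network with a warning rather than
  an error.
* Ward input must be symmetric with zero diagonal; duplicate columns
  merge first at height 0; merge heights are non-decreasing.
* `+1` smoothing puts an $LR$ floor of 1 under isolated nouns.
* A period with zero records makes `summarize_corpus()` warn and leave
  that row empty; `crosstab()` requires both periods.
* All stochastic steps (generator, Louvain) consume explicit integer
  seeds; identical config and seed reproduce byte-identical output.

## Validation scale

The suite validates the statistical machinery at sizes chosen to keep a
single-CPU run comfortable while leaving no tolerance doing the work of
correctness: exhaustive oracles run at 3–6 points/nodes (all merge
sequences, all spanning trees, all 4,140 partitions of 8 nodes; 1,000
random Fisher tables), and recovery experiments use 500 replicates at
the full two-period scale (1,353/5,155 records) for coverage, 100 for
bias, and 20 replicates of 1,000 + 1,000 records for community
recovery (median adjusted Rand index against the planted grouping).

## Known limitations

* Corpus-scale inventories (how many compounds, synonym sets, network
  nodes or communities a *real* corpus yields) depend on the corpus and
  cannot be asserted from synthetic data; the pipeline logs them and
  the suite checks internal consistency only.
* Cluster and community *naming* is a human step; the package emits
  member term lists.
* Layout and visual styling of networks are left to external viewers
  (the GraphML carries frequencies, communities and Dice weights).
* The Fisher test and odds ratio treat records as independent; repeated
  admissions or author habits violate this silently, as in any
  record-level cross-tabulation.
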