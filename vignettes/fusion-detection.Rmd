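---
title: "Detecting gene fusions from domain architecture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene fusions from domain architecture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionscan)
```

## The problem

A gene fusion, in the strict ("Rosetta stone") sense, is a single gene
whose product combines two proteins that exist as separate, independently
functional entities in other genomes. Fusions are conceptually different
from ordinary multi-domain proteins, whose domains never occur separately
with the same functional roles. The distinction matters because fusions
carry functional information — the two halves almost certainly work
together — while generic multi-domain architecture mostly does not.

Detecting fusions from domain alignments alone is easy to do badly. Around
forty percent of bacterial proteins are multi-domain, and three artifact
classes dominate naive predictions:

* **multifunctional single-domain proteins** annotated with two roles but
  structurally one domain;
* **sub-domain models**: domain models that describe a small piece of a
  protein and never a whole gene, so two of them on one gene say nothing
  about fusion;
* **promiscuous modules** — ABC transporter components, two-component
  regulator receivers and their partners — which recombine so freely that
  co-occurrence carries no specific functional signal.

`fusionscan` implements a filter cascade against exactly these classes,
together with the downstream statistics (role- and subsystem-level fusion
frequency, pathway adjacency of fused roles) that make the calls
interpretable, and a synthetic-cohort generator that plants all three
artifact classes so the whole chain is testable without any database
access.

## The detection model

All coordinates are 1-based inclusive; an alignment's length is always
`end - start + 1`. "Non-overlapping" means strictly disjoint residue
intervals; because published procedures rarely say whether a one-residue
overlap disqualifies a pair, the tolerance is configurable
(`overlap_tolerance`, default 0).

**Hit threshold.** An alignment counts as a hit when its E-value is
strictly below `e_value_max` (default 1e-5).

**Full-gene models.** A model is flagged *full-gene* when a single
alignment covers strictly more than `full_gene_coverage` (default 0.90) of
both the model length and the gene length. The strict inequality follows
the "greater than 90 %" reading of the rule; it also makes the flag
monotone — loosening the threshold can only add flags. A model that is
never a near-complete match to a near-complete gene is treated as a
sub-domain and excluded from candidacy.

**Set consolidation.** Domain catalogues contain near-duplicate models.
Two models are linked when, on at least half the genes either hits
(`similarity_min = 0.5`), they have alignments whose gene intervals agree
with Jaccard ≥ 0.8; consolidated sets are the single-linkage connected
components of this graph (computed with igraph), and models without hits
form singletons. The procedure was an open design point: no published
definition of "similar alignments" exists for this step, so we chose a
footprint-based similarity that is directly testable against a brute-force
oracle, and exposed both constants.

**Candidate selection.** Among a gene's alignments to full-gene models
covering at least `domain_coverage_min = 0.5` of their model, the caller
selects a maximum-cardinality pairwise-disjoint subset by dynamic
programming over end-sorted intervals. Ties between equal-cardinality
solutions are broken by larger summed alignment length, then by
lexicographically smallest model-id sequence; determinism here is what
makes regression tests byte-stable. A gene with three disjoint domains is
one candidate with two gaps, not several pairwise candidates.

**The eight filter criteria.** Each is evaluated on measured values kept
in the output table:

| criterion | default | biological meaning |
|---|---|---|
| protein length > 600 aa | strict | fusions are longer than single-domain proteins |
| combined alignment ≥ 40 % of gene | ≥ | fused domains should cover the gene |
| every alignment ≥ 50 aa | ≥ | domains should not be fragments |
| gap midpoint ≥ 60 aa and ≥ 10 % of length from both termini | both floors | the fusion point is internal, not a terminal decoration |
| ≥ 2 distinct consolidated sets | ≥ | the two domains must not be the same model twice |
| < 50 % of the gene's hits cross a gap | strict | a fusion is two domains, not one domain split by the partition |
| each model co-occurs with < 1500 sets | strict | promiscuity ceiling |
| each model pair has < 1000 pair matches | strict | the fused domains must differ from one another |

A hit *crosses* a gap when it extends into both flanking selected domains
(`gene_start < gap start` and `gene_end > gap end`). "Pair matches" of two
models is the number of distinct genes where their alignments overlap by
at least half the shorter alignment — a footprint proxy for the two models
being versions of the same domain; what exactly should be counted here was
ambiguous, and this definition was chosen because it matches the
criterion's stated purpose and admits a brute-force oracle. The gap
criterion tests the *midpoint* of each gap against both termini with both
floors, the reading that reproduces the worked two-domain example (gene of
700 aa, domains at 10–190 and 351–650, midpoint 270.5, floors 60 and 70).

The verdict policy is conjunctive by default (`criteria_policy = "all"`).
An `at_least_k` policy is provided deliberately: a strict conjunction with
the 600-residue floor must miss genuine short bifunctional fusions (many
vitamin-pathway enzymes are well under 600 aa), and the relaxed policy
lets a user quantify that trade-off rather than silently inherit it.

## Evaluation semantics

Scoring against a curated training table uses only `confirmed_fusion`
entries; `uncertain` entries are excluded from numerator and denominator
alike. The false-negative rate is `1 - captured/confirmed`. A
false-positive rate has no unambiguous denominator at desk scale, so the
package reports `(predicted - captured)/predicted` within the scored
genome(s) *and* the raw counts, letting any alternative definition be
recomputed.

The *frequently fused* test operationalizes "significantly above the
cohort mean" as a z-score against the mean and SD of per-role fused
proportions — with μ = 0.11 and σ = 0.25 the implied flagging threshold is
0.61 — combined with a one-sided exact binomial test (`stats::binom.test`)
of `n_fused` of `n_genes` against μ at p < 0.05, since no specific test is
prescribed by convention. Roles are counted per gene-role pair, so a
bifunctional gene contributes to both of its roles. A cohort whose
proportions have zero spread flags nothing (with a warning) rather than
erroring: zero spread means no role exhibits an excess, which is a
well-defined null answer.

## The synthetic cohort

The generator's defaults are the package's reference study conditions: 2
genomes × 500 genes, 10 % planted true fusions, 10 % of each decoy class,
seed 42. Gene geometry is built so that planted fusions exercise every
criterion boundary from the passing side: member models are drawn from a
standalone pool (uniform lengths 150–450 aa) with pair sums ≥ 540 aa so
fused proteins exceed 600 aa; inter-domain gaps of 70–120 aa and terminal
margins of 5–20 aa keep gap midpoints central; and every standalone model
is also assigned at least one single-domain parent gene (round-robin over
the pool), which both secures its full-gene flag and provides the
independent standalone occurrence that the Rosetta-stone check requires.
Ten percent of planted fusions join three domains, exercising the
multi-gap path.

Decoys are planted to fail for the *reason their real counterparts fail*:
sub-domain decoys use models of 60–100 aa on genes of ≥ 450 aa, so the
models never reach bidirectional 90 % coverage anywhere and the genes die
at the candidate stage; multifunctional single-domain genes carry one
full-length alignment plus an overlapping partial alignment, so they never
have two disjoint hits; promiscuous modular genes pair members of a small
promiscuous pool on proteins kept under 600 aa, as real two-component and
transporter module proteins typically are, so they reach candidacy and are
removed by the length criterion. The 1500-set promiscuity ceiling cannot
be the operative filter in a thousand-gene cohort — no model can co-occur
with 1500 sets there — and we treat that as a property of scale, not a
defect: the ceiling is still enforced and still monotone, and the
monotonicity suite tightens it like every other threshold.

Optional coverage noise trims up to `coverage_noise_max` (default 3 %) of
the model from each alignment end of fusion and decoy hits. Parent
single-domain alignments are left exact: they model the very genes the
domain models were built from. Gene lengths for single-domain genes are
1.00–1.05 × the model length, keeping bidirectional coverage above 95 %.
All draws come from one seeded stream in a fixed order, so a fixed seed
reproduces the cohort byte-for-byte across platforms.

What the generator does *not* emulate: sequence-level homology, E-value
structure correlated with alignment quality, genuinely ambiguous boundary
cases (alignments hovering at 89–91 % coverage), horizontal heterogeneity
between genomes, and promiscuity at database scale. Passing the planted
recovery tests therefore demonstrates that the machinery implements its
specification, not that these thresholds achieve any particular accuracy
on real genomes.

## Numerical and degenerate-input choices

* Percentages shown at integer precision are rounded half-up
  (`floor(x + 0.5)`), so 48/121 reports as 40 and 21/121 as 17.
* An empty confirmed truth set is an error (rates undefined), not zero.
* A role absent from a genome pool has frequency `NA` ("absent"), never
  0 %.
* An empty call set has precision `NaN`; recall 0.
* Hits violating coordinate invariants (out of range, inverted, unknown
  ids) are dropped with a reported count — large real scans contain edge
  artifacts and should not abort a run — while negative or non-numeric
  coordinates indicate a malformed file and are an error.
* Genome proportionality reports both the pooled fraction and the
  closed-form through-origin least-squares slope `Σxy/Σx²`; tests verify
  the slope against an independent `lm(y ~ 0 + x)` fit.

## Problem sizes used in the test suite

The reference cohort is 1,000 genes with roughly 1,400 hits; the full
pipeline runs in a few seconds on it. Oracle suites use 200 random genes
of up to 15 hits for the partition selector (exhaustive subset search),
50-model instances for set consolidation (brute-force single linkage), and
20-gene datasets for co-occurrence counting. These sizes were chosen so
that every brute-force oracle is exact and the whole suite stays fast
enough to run habitually.

## Known limitations

* The consolidation similarity and the pair-match definition are
  reconstructions of underspecified procedures; both are parameterized so
  alternative readings can be explored.
* The conjunctive default policy is knowingly biased against short
  fusions; use `at_least_k` to explore the trade-off.
* The false-positive rate depends on a denominator choice that cannot be
  fixed canonically; raw counts are always emitted.
* Cohort-scale statistics (frequently fused roles, genome
  proportionality) are only as meaningful as the input annotation's
  consistency; the role filter (≥ 10 genomes, no generic descriptor
  words) removes the worst of it but cannot repair inconsistent role
  naming.
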