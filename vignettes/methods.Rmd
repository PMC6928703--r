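---
title: "Methods: PICO query construction, rigor classification and contextual triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PICO query construction, rigor classification and contextual triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmtriage)
```

`ebmtriage` automates the front half of an evidence-based-practice
literature search: it turns clinical input into a well-built question, runs
and repairs the boolean retrieval, classifies the retrieved articles for
methodological rigor, grades and ranks them under the user's context, and
condenses primary studies into extractive summaries. This vignette explains
each model and procedure, its assumptions, the parameters that matter, and
the design decisions taken where the methodology left the choice open.

## Weighted concept matching (STI)

Clinical terms are matched against a controlled vocabulary (SNOMED-CT/UMLS
in production; a packaged demo fixture here) with a weight-based matcher.
An exact match on a preferred name carries weight 1.0; a whole-name synonym
match or a token-subset partial match carries 0.5; anything else is a
non-match with weight 0. Matching precedence is exact > synonym > partial —
synonym outranks partial because it is still a whole-name match.

Three details are package choices:

* **Normalization.** Lookups lowercase, strip punctuation and collapse
  whitespace, but never stem: vocabulary names are surface forms, and
  stemmed keys would no longer match them. The Porter stemmer participates
  only in duplicate-candidate collapsing and in article featurization.
* **Partial match** is defined as: the normalized term's token set is a
  non-empty proper subset of a concept name's token set (or vice versa),
  sharing at least one token of four or more characters. The length floor
  keeps function-word overlap ("of", "the") from creating spurious partial
  matches.
* **Tie-breaks.** Among same-level candidates the longest matched name
  wins, then the lexicographically smallest concept id; the matcher returns
  a single best match per term, which keeps downstream slot assignment
  deterministic.

## From input to PICO

Free text is whitespace-tokenized, case-folded and stopword-filtered; all
contiguous n-grams up to n = 4 are matched with the STI matcher. Candidates
are accepted greedily — better match level first, longer phrase first,
earlier position first — each consuming its token positions, so an exact
"blood pressure" beats both its unigrams and a longer partial phrase
containing it. Accepted concepts are slotted in text order: population,
disorder and finding types go to P; drug and procedure types are
interventions, the first to I and every later one to C (the comparison
reading of PICO, which also reproduces the published OR-grouping of the two
drugs in the worked scenario); outcome-like types go to O; a type missing
from the mapping table defaults to P with a warning rather than silently
dropping a matched concept. The slot-mapping table ships as editable JSON —
the published account names only two example mappings (population group to
P, chemical-and-drugs to I), so the shipped table is a reconstruction
covering the common semantic types.

Knowledge rules map structurally: data elements to P, the first action
element to I and the rest to C, the rule's purpose (when present) to O — a
production rule without a purpose simply leaves O empty. Structured records
arriving pre-labeled pass through the matcher only for standardization.

The question's purpose ("query type") is inferred from the parents of the
I and C concepts: each parent is translated through a configurable table to
diagnosis, treatment, prognosis or etiology, and the majority vote wins.
Ties resolve by the fixed priority treatment > diagnosis > prognosis >
etiology.

## Boolean retrieval and query repair

Each P term forms its own AND-group, the I and C terms share one OR-group,
and O terms are appended as AND-groups. The plain rendering joins groups
with explicit `AND`; since PubMed treats adjacency as conjunction, query
strings are compared with `query_strings_equivalent()`, which canonicalizes
the implicit-AND convention and punctuation-as-separator. The pubmed
dialect appends a broad clinical-queries filter clause chosen by the query
type; the filter strings live in configuration, not code.

When a query returns fewer than `min_results` hits (default 1 — repair
exists for searches that come back empty), terms are removed one per
iteration: C terms first, then O terms, then the lowest-STI-weight
remaining P/I term. The P/I core is never touched while any C or O term
remains, and the final term is never removed; if even the single-term query
finds nothing, the empty outcome is returned flagged rather than raised.
Within a slot class, the lowest weight goes first and ties drop the most
recently added term. An optional `max_results` only warns — the
too-many-results branch re-adds nothing.

## Featurization

Articles are represented by two disjoint token namespaces, mirroring how
indexing metadata and running text carry different signals:

* **Data features** — title and abstract concatenated, tokenized,
  case-folded, stopword-filtered, Porter-stemmed, and length-filtered
  (2–25 characters by default).
* **Metadata features** — MeSH descriptors and publication types, tokenized
  and case-folded only (no stemming, no stopword removal), prefixed with
  `meta:`.

The stemmer is the original Porter (1980) rule set, implemented in the
package and exercised against the algorithm's canonical example words. The
default term weighting is smoothed TF-IDF (`log((1+n)/(1+df)) + 1`) with L2
row normalization; raw counts and binary indicators are selectable for
ablation. The fitted vocabulary and IDF weights travel with a trained
model, so new articles are always projected onto the training feature
space. An unindexed record with no MeSH terms remains classifiable from its
data features alone.

## The two-level rigor ensemble

The classifier is a binary rigor/nonrigor model organized in two ensemble
levels over seven base learners: naive Bayes, a CART decision tree,
logistic regression, an L2-penalized binomial GLM (kept distinct from the
plain logistic baseline, matching the two entries in the source lineup),
a random forest, gradient boosted trees, and a "deep learning" member
implemented as a two-hidden-layer perceptron (ReLU hidden layers, sigmoid
output, full-batch gradient descent with momentum on weighted
cross-entropy; layer sizes and epochs in configuration — the original used
an opaque vendor automodel whose architecture is undisclosed, so a compact
MLP is this package's stand-in at desk scale).

Level one wraps a base kind in AdaBoost.M1 (default 50 rounds) using case
weights where the base supports them and weighted bootstrap resampling
where it does not; weights are normalized to mean one, so a single round
reproduces the plain base learner exactly. A member with weighted error
zero receives a capped vote and boosting stops. Probability scores are the
alpha-weighted mean of member probabilities.

Level two combines AdaBoost(GBT) and the GLM — the default stack — by soft
voting (mean probability, threshold 0.5); a logistic stacking meta-learner
is an optional mode. Training splits the corpus 70/30 with stratified
sampling (the 0.7 ratio is the source's stated split), and every fit is
seeded: the full train-and-evaluate path is bit-stable for a fixed seed.

Evaluation reports F-measure, precision and accuracy with positive class
rigor, AUC as the Mann–Whitney rank statistic over probabilities (midranks
for ties; absent when the test set has one class), and the 2×2 confusion
table. The identities F = 2PR/(P+R) and accuracy = (TP+TN)/n hold exactly
by construction and are asserted over randomized reports in the tests.

## The synthetic benchmark corpus

The reference gold standard for rigor classification is a licensed,
manually annotated MEDLINE subset that cannot be redistributed, so the
package generates its own labeled corpus and the tests measure *signal
recovery* rather than reproduction of the published benchmark figures. Per
class, tokens are drawn from a multinomial over a Zipf-shaped pseudo-word
vocabulary (400 types by default); a block of 20 signal tokens is
up-weighted by a tilt factor in the rigor class and a disjoint block in the
nonrigor class. Rigor articles additionally receive trial-like metadata —
a randomized-trial publication type and a random-allocation indexing term —
with a separation-dependent probability, so the planted signal lives in
both feature namespaces, as methodological-rigor signal does in real
records (soundness criteria such as random allocation and follow-up
completeness surface in both wording and indexing). The three separation
settings are fixed: high (tilt 6, metadata probability 0.9) supports >0.9
single-learner accuracy and ≥0.95 ensemble accuracy at n = 2000; medium
(2.2, 0.72) leaves headroom for boosting comparisons; low (1.05, 0.52) sits
at chance within ±0.07.

Two generator choices deserve justification:

* **Balance.** The default `rigor_fraction` is 0.5 so the no-information
  rate is 0.5: chance-level checks (the low-separation regime, the
  label-permutation control) are only meaningful against that baseline.
  Real indexed literature is rigor-minority; set the fraction explicitly to
  emulate it.
* **The permutation control uses an association-free shuffle.** A uniform
  permutation of training labels retains a chance association of order
  1/sqrt(n) with the true labels, and on strongly separable
  high-dimensional features a ridge-logistic learner amplifies that
  association along the separating direction — single permutations swing
  test accuracy far from 0.5 in either direction. `shuffle_labels()`
  therefore permutes within true-label groups so the contingency
  association is exactly zero, measuring the permutation null at its
  expectation. All real label–feature association is still destroyed.

What passing these tests shows — and does not. The generator emulates
distributional wording differences and metadata correlates of rigor under
an exchangeable bag-of-tokens model; it does not emulate discourse
structure, section headers, journal-level confounding, label noise, or the
class imbalance of real MEDLINE corpora. Signal recovery at desk scale
demonstrates that the ensemble machinery works end to end, not that the
published benchmark accuracy transfers to any particular corpus.

## Grading, context aggregation and ranking

Evidence grades form the total order H > M > L > U with U the bottom
element. Publication types carry ranks 1–11 with grade bands (H for ranks
1–3, M for 4–7, L for 8–11); an article with several types takes its best
rank, and an unlisted or empty type falls to the bottom row. The shipped
table is editable JSON, with normalized aliases mapping MEDLINE
publication-type strings onto the canonical rows.

User context elements (education, background, goal, interest, learning
style) arrive as pre-graded H/M/L/U cells; mapping raw profiles to grades
is out of scope. For each article the evidence side contributes a
publication-type grade and a recency grade (H within five years of the
newest article in the set, M within ten, L older, U unknown); each matrix
cell is the grade-scale minimum of a user element and an evidence property,
columns are aggregated by majority vote with ties resolved toward the
higher grade, and the article's cross-context grade is the highest column
aggregate. The full sort key is (cross-context grade, publication-type
rank, rigor probability, year), stable for exact ties.

One property the aggregation deliberately does not have: raising a single
cell one step can lower a column aggregate, because a three-way tie
resolves upward to H while the raised cell can create a strict majority at
a middle grade — (L, M, H) aggregates to H, (M, M, H) to M, and the latter
is the published worked example. The invariants that do hold, and are
verified exhaustively over all small columns, are that the aggregate lies
between the worst and best cell and that promoting any cell straight to H
never lowers the aggregate.

## Summarization

Articles are first triaged: any synthesis publication type (systematic
review, meta-analysis and subtypes) marks the article secondary, and
secondary studies keep only their meta information — they are already
evidence. Primary studies are summarized extractively over the abstract
(full-text retrieval is out of scope): each sentence is scored per PICO
element by the summed STI weights of its matched concepts, with C folded
into I since a comparison is itself an intervention; a sentence is
attributed to every element scoring above the threshold (default 0), and
the top three sentences per element are kept in document order. Every
summary sentence is verbatim from the source abstract. Sentence splitting
is rule-based on terminal punctuation with an abbreviation guard list.
Summaries are grouped into evidence by single-linkage over Jaccard
similarity of their token sets (default threshold 0.5); the similarity
measure and linkage are package choices. No quantitative quality target
exists for this stage, so its tests assert structural properties
(verbatim extraction, attribution rules, partition of the input).

## Determinism, problem sizes and numerical choices

Every stochastic component — corpus generation, splitting, every learner,
the shuffles — draws from an explicit integer seed, and the pipeline report
serializes with fixed field order, full precision and no timestamps, so
identical inputs and seed give byte-identical bytes on one machine. All
tree learners run single-threaded for bit-stability.

The test suite and the acceptance script run the benchmark at n = 2000
articles with a 400-type vocabulary and 50 boosting rounds — large enough
for stable accuracy estimates at desk scale while keeping a full run in
tens of seconds; paired learner comparisons use n = 400 at medium
separation over five seeds. Degenerate inputs are defined rather than
exceptional: empty abstracts featurize to empty maps, a single-document
corpus has constant IDF, a one-class test set reports AUC as missing, and
an unsearchable question is a typed condition, not a crash.

## Known limitations

* The vocabulary fixture is a miniature; production use requires a real
  UMLS/SNOMED-CT service behind the same store interface.
* The live NCBI eUtils backend is a thin, untested-by-CI client; offline
  work runs against the fixture backend.
* The slot-mapping and query-type tables are reconstructions from two
  published examples; both ship as editable configuration.
* The "deep" member is a compact MLP; nothing about vendor automodel
  behavior is replicated.
* Extraction quality is untested against human summaries — only structural
  properties are asserted.
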