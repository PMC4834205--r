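---
title: "A crowdsourcing workflow for chemical-induced disease relation extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A crowdsourcing workflow for chemical-induced disease relation extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdcid)
library(dplyr)
```

## The problem

Adverse drug effects are one of the most heavily queried biomedical
relations, and curating chemical-induced disease (CID) assertions from
PubMed abstracts by expert readers does not scale to the literature.
`crowdcid` implements a workflow that replaces the expert reader with many
non-expert judgments: automated named-entity recognition (NER) supplies
chemical and disease mentions normalized to MeSH identifiers, every
chemical x disease identifier pair in an abstract becomes a *candidate*
relation, trivially phrased candidates are accepted by a lexical rule, and
the rest are shown to five workers each, whose votes are aggregated by a
simple threshold.

A relation is a triple (document, chemical MeSH ID, disease MeSH ID).  All
documents are pooled into one prediction set and scored against gold with
micro-averaged precision $P = \mathrm{tp}/(\mathrm{tp}+\mathrm{fp})$,
recall $R = \mathrm{tp}/(\mathrm{tp}+\mathrm{fn})$, and
$F = 2PR/(P+R)$.

Because a live worker platform cannot be part of a reproducible package,
the crowd itself is modeled: a simulator with per-worker accuracy and the
platform's quality gates stands in for the workers, and a synthetic corpus
generator with planted ground truth stands in for the evaluation corpus.
Everything downstream of those two substitutions — candidate generation,
routing, task construction, aggregation, evaluation — is the production
code path a real judgment file would flow through (`tally_votes()` and
`decide_relations()` accept any judgment table with the documented
columns).

## Corpus representation

Input is the PubTator dialect: per document a `id|t|` title line, an
`id|a|` abstract line, tab-separated annotation lines with character
offsets, and `CID` relation lines.  Offsets index the concatenation
`title + " " + abstract`, 0-based and end-exclusive, counted in characters
(the separator choice is the convention of the CDR-style distributions this
dialect comes from).  `parse_pubtator()` validates every span against the
text — an annotation whose surface does not equal the text slice is an
error, not a warning, because every later stage (pattern matching, sentence
assignment, highlighting) depends on exact offsets.  A leading `MESH:`
prefix is stripped at parse time; the unmapped sentinel `-1`,
foreign-ontology IDs such as `CHEBI:16236`, and composite IDs
(`D013390|D012345`, stored as ID lists) are preserved so that downstream
filtering can distinguish them.

## NER post-processing

Two passes clean the annotation table before candidates are formed:

* **Acronym resolution** (`resolve_acronyms()`).  NER tools often locate an
  acronym ("BPA") without attaching an identifier.  Two rules copy IDs from
  mapped annotations in the same document: exact same-surface propagation,
  and parenthetical definition — the acronym wrapped in parentheses at most
  2 characters after the end of a mapped long-form mention resolves every
  unmapped occurrence of that acronym in the document.  A candidate acronym
  must be short (default at most 10 characters), contain an uppercase
  letter, and hold no whitespace.  The published workflow used a rule of
  this kind whose full specification is not public; ours is therefore a
  configurable stand-in (`acronym_rule_config()`) designed to reproduce the
  documented behavior (e.g. unmapped "BPA" mentions resolving to the
  bisphenol A ID via the "bisphenol A (BPA)" definition), not a claimed
  reconstruction.  Conflicting resolvers are broken deterministically in
  favor of the nearest preceding mention.
* **MeSH filtering** (`exclude_non_mesh()`).  Mentions with only `-1` or
  foreign-ontology IDs cannot participate in MeSH-keyed relations and are
  dropped.

## Candidate generation and routing

`generate_candidate_pairs()` forms, per document, the Cartesian product of
distinct chemical and disease MeSH IDs; pairs are keyed by identifier, not
by mention, matching the triple-based evaluation unit.  Each pair is then
assigned exactly one of three scopes:

1. **pattern** — some chemical mention ends at most 15 characters before a
   disease mention and the intervening text contains `induce`
   (case-insensitive substring, so "induced"/"induces" match).  This is the
   phrasing most often used for drug side effects ("cisplatin-induced
   nephrotoxicity"); such pairs are accepted automatically and never shown
   to workers.  The gap is measured from chemical end to disease start, and
   the disease must follow the chemical.  Both the gap (default 15) and the
   trigger are configurable (`pattern_config()`).
2. **sentence** — the pair co-occurs in at least one sentence; every such
   sentence index is recorded and each becomes one judgment task.
3. **abstract** — everything else; one task showing the whole text.

Sentence boundaries come from a deterministic rule-based splitter: a run of
`.!?` followed by whitespace and an uppercase letter or digit, with a fixed
abbreviation list ("e.g.", "i.e.", "vs.", "Fig.", single-letter tokens,
...).  The title is always its own first sentence unit.  A statistical
splitter could be substituted, at the cost of a model dependency; the
abbreviation list means a sentence genuinely ending in a single-letter word
is not split — a deliberate, documented trade-off.  A mention belongs to
the sentence containing its start offset, which fixes the behavior of
boundary-crossing spans.

## Task construction and economics

`build_tasks()` gives sentence tasks three choices — `yes_cid`,
`no_relation`, and `chained_induction` for "chemical-induced intermediate
causes disease" chains, which workers otherwise mislabel as positive —
and abstract tasks two.  `chained_induction` is counted as negative during
aggregation.  All mentions of the pair inside the unit are highlighted;
`render_highlight()` produces markup whose stripping recovers the unit text
exactly, a property the tests enforce.  `max_hourly_pay()` captures the
task-economics closed form `3600 * pay / min_seconds`: 2 cents at a 3 s
floor caps at \$24/h (sentence tasks), 4 cents at 10 s at \$14.40/h
(abstract tasks).  Total-cost accounting beyond `judgments x pay` is
deliberately not modeled: platform fees and test-question economics are not
specified well enough to reproduce.

## The simulated crowd

`simulate_judgments()` models the platform's quality gates: a six-question
admission quiz passed at 5 or more correct (70% of six, rounded up — the
platform publishes the quiz size and the floor but not the pass rule),
hidden test questions interleaved at a 10% rate, and removal once a
worker's running test accuracy falls below 0.70.  A removal check fires
after each test answer but only once at least 4 test answers have
accumulated, so a single early miss cannot eject a worker; all parameters
sit in `sim_config()`.  Removed workers' judgments are all invalidated and
their tasks return to the queue, so every task ends with exactly five
*trusted* judgments — replacement workers supply the shortfall, and the
simulator raises an error naming the unfilled task count if the pool runs
dry.  A worker answers any item correctly with probability equal to their
accuracy; a wrong answer is uniform over the remaining choices.  This
symmetric error model is the simplest one consistent with a single
per-worker accuracy; it has no per-class bias, no fatigue, and no
task-difficulty structure, so simulation results say how the *workflow*
behaves under a given judgment quality, not how real workers behave.
Because removal depends only on test answers, trusted real-task judgments
remain exact Bernoulli draws at the worker's accuracy — a property the
tests verify against the closed-form binomial standard error.

## Aggregation

`tally_votes()` counts `yes_cid` votes per task.  A sentence-scoped pair
may have several tasks; the task with the most positive votes represents
the relation, on the assumption that one supporting sentence makes the
relation true for the abstract.  `decide_relations()` predicts every
relation with at least `vote_threshold` positives (default 4 of 5, the
published peak operating point) and unions the pattern-accepted relations.
Votes are unweighted integers; Bayesian or EM aggregation is intentionally
out of scope.

## Evaluation

Beyond micro P/R/F, the package provides:

* `max_recall()` — the share of gold triples whose pair appears among a
  document's candidates.  Gold relations using an ID never produced by NER
  in that abstract are *unindexable* and bound recall before any judgment
  happens.
* `ner_error_filter()` — keeps a relation (on both sides) only if both its
  IDs are carried by a predicted annotation exactly matching gold in span
  and ID set, isolating judgment quality from recognition quality.
* `roc_points()` / `roc_auc()` — a threshold sweep (6..0) over the judged
  candidates plus unindexable gold injected at zero votes (as if
  unanimously rejected); pattern relations carry the full vote count by
  default, a documented choice exposed as `pattern_votes`.  AUC is the
  trapezoidal rule over points anchored at (0,0) and (1,1).
* `overlap_partition()` — the Venn partition of gold over any number of
  prediction systems, including the region predicted by none.
* `ner_prf()` — annotation scoring at exact-mention or document-concept
  level; `share_of_total()` — exact percentage shares (callers round for
  display).

Degenerate denominators (no predicted positives) yield 0 with a warning
rather than `NaN`, so threshold sweeps stay total.

## The synthetic corpus generator

`generate_corpus()` plants 1-3 true relations per document and expresses
each through one of the three routing branches: an "-induced" sentence
(pattern), a plain co-occurrence sentence, or two separated sentences
(abstract-only).  Defaults (`fixture_config()`): 100 documents, branch mix
0.10 / 0.55 / 0.35 — pattern hits are a small minority and sentence
co-occurrence the most common expression, mirroring the balance of
sentence- and abstract-routed work in the published corpus — 10% of disease
mentions emitted unmapped (`-1`), 15% of chemicals introduced long-form
with a parenthetical acronym and thereafter mentioned by the unmapped
acronym, and two co-occurring distractor (non-relation) pairs per document.
Unmapped disease mentions make their relation unindexable, so
`max_recall()` on a fixture equals the indexable fraction of gold exactly —
a closed form the tests exploit.  Applying the unmapped rate to the disease
mention (rather than both classes) keeps that bookkeeping exact while still
exercising the unindexable-relation path; chemicals instead exercise the
acronym-resolution path.  Concept IDs live in a reserved `D9...` namespace
so collisions with real MeSH descriptors are impossible, and one template
("We examined the effects of X in a controlled cohort.") deliberately
reproduces the objective-statement-without-outcome structure that makes
single-sentence judgments fail in real abstracts.

What the generator does *not* emulate: linguistic variety, anaphora,
conjoined concept lists, MeSH hierarchy (a prediction using a broader term
than gold is simply wrong here), NER false positives with wrong spans, and
correlated worker errors.  A green test suite therefore shows the workflow
machinery is correct and calibrated, not that real crowds on real abstracts
would reach any particular score.

## Worked example

```{r pipeline}
fx <- generate_corpus(fixture_config(n_documents = 30, rng_seed = 7))
res <- run_cid_pipeline(fx$corpus, worker_pool(1000, 0.85),
                        sim = sim_config(rng_seed = 8))
table(res$candidates$scope)
res$prf
c(max_recall = res$max_recall, auc = res$auc)
```

With perfect workers the pipeline recovers exactly the indexable gold plus
the pattern relations; at accuracy 0.85 recall is lost both to unindexable
relations and to out-voted true pairs, and the ROC over vote thresholds
summarizes the trade-off.

## Numerical and design notes

* Problem sizes in tests and examples (tens of documents, worker pools in
  the hundreds) are chosen so the whole suite runs in about a minute on a
  laptop while keeping binomial checks inside three standard errors.
* Printed reference metrics mix rounding and truncation in their final
  digit (576/1211 = 0.4756 is printed 0.475), so worked-example tests
  accept one unit in the last printed digit rather than guessing the
  rounding rule.
* All randomness flows through explicit integer seeds (`rng_seed` in
  `sim_config()` and `fixture_config()`); reruns are byte-identical,
  including every artifact `run_cid_pipeline()` writes.
* Ties need no rule anywhere: maxima and thresholds over integer votes are
  unambiguous.
* The pipeline treats judgment tables as replaceable input, so a real
  platform export with columns `task_id`, `worker_id`, `choice`, `trusted`
  drops into `tally_votes()` unchanged.
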