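---
title: "Mining real-world evidence of genetic testing from clinical notes"
author: "rwegm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining real-world evidence of genetic testing from clinical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwegm)
```

## The problem

Genetic test results — above all BRCA1/2 status in women's cancers — reach
the chart mostly as free text. The same gene mention can mean very
different things depending on clinical context: general patient education,
a risk evaluation based on family history, an insurance discussion, an
order awaiting results, or an actual result (positive, negative, or a
variant of unknown significance, VUS). Any attempt to generate real-world
evidence (RWE) from notes — e.g., does a documented BRCA1/2 mutation lead
to discussion and prescription of PARP inhibitors? — must first resolve
that contextual variability, then face the data-quality reality of notes:
variant details are mostly missing, and documentation sometimes contradicts
itself across time.

`rwegm` implements this pipeline end to end: sentence extraction and
masking, sentence universality scoring, topic-indicator discovery,
rule-based and tree-ensemble topic classification, curation of result
sentences into a clinical-genomics data model, completeness/discrepancy
auditing, patient timelines, and an exact association test. Because real
clinical notes are protected health information, the package also treats
the synthetic cohort generator as a first-class module: it is the test bed
on which every stage's behaviour is verified against known ground truth.

## Text normalization

Sentences are filtered to those containing a target gene symbol
(word-boundary, case-insensitive). Gene mentions come from an editable
HUGO-symbol dictionary; variant mentions from regular-expression families
for cDNA changes (`c.7759C>T`, spaces around `>` tolerated), three-letter
protein changes (`p.Arg149Trp`), shorthand protein changes (`S34F`), and
copy-number/rearrangement words (`amplification`, `deletion`,
`rearrangement`, `truncation`) — the last only when within a configurable
window (default 5 words) of a gene mention, since those are ordinary
English words otherwise. Non-target gene mentions are masked to `GENE` and
syntactic variant mentions to `MUTATION`, so classifiers learn context
rather than memorizing nomenclature; target genes are preserved. Masking is
idempotent.

Tokens are lowercased, stripped of punctuation and digit-only strings,
stopword-filtered and lemmatized by deterministic suffix rules (plural →
singular, `-ing`/`-ed` stripping with a small exception list). We chose
rules over a statistical lemmatizer for byte-level reproducibility and
zero model downloads; the cost is occasional stemming artifacts
(`mutated → mutat`), which is harmless because rule lexicons are passed
through the same lemmatizer at load time. Two deliberate choices:

* **Negation cues are not stopwords.** `no`, `not`, `without` stay in the
  token stream; otherwise the negation-flip rule ("no pathogenic mutation
  in BRCA1" → negative assertion) could never fire.
* **Concept-dictionary filtering is optional.** The original workflow kept
  only concepts recognized by a licensed medical vocabulary; we expose an
  optional plain `vocab_filter` word list instead (default: none), which
  preserves the pipeline shape without a licensing dependency.

Duplicate sentences within a patient (identical *normalized* text — raw
text identity would be defeated by trivial formatting differences) collapse
to the earliest instance; date ties break on the lexicographically smallest
note id. Deduplication never increases counts and is order-invariant.

## Sentence universality: sf-ipf

For sentence $s$ in a cohort of $N$ patients,

$$\mathrm{sf}(s) = \frac{\#s}{\text{total } \# \text{ sentences}},\qquad
\mathrm{ipf}(s) = \frac{\log N}{\#\text{ patients with } s},\qquad
\text{sf-ipf}(s) = \mathrm{sf}(s)\,\mathrm{ipf}(s).$$

Boilerplate shared across many patients scores high; patient-specific
result sentences score low, so reviewing the low-score tail (default
threshold 0.5, configurable — one workflow description also mentions 0.05,
and we follow the main-text value) plus a seeded random sample of the rest
yields a balanced review set. The logarithm is natural by default and
configurable; the cohort size $N$ is an explicit argument because the
sentence list may cover only the documented subset of the cohort.

## Topic-indicating words: PMI

With token counts (a word counted once per sentence) over the word × topic
grid and add-$k$ smoothing (default $k = 0.5$),

$$\mathrm{pmi}(w, t) = \log\frac{P(w,t)}{P(w)\,P(t)}.$$

With $k = 0$ this reduces to $\log(c_{wt} C / (c_w c_t))$; words exclusive
to a topic then score exactly $-\log P(t)$, which is the closed form the
unit tests check. Zero joint counts with $k = 0$ are omitted (log
undefined) with a warning. The "inequality score" used to rank indicator
words is the PMI value itself.

## Rule-based classification

A sentence receives exactly one of seven topics. Result topics take
precedence: positivity (`positive`, `pathogenic`, ...), negativity
(`negative`, `wildtype`, `no mutation`), and VUS (`vus`, `unknown
significance`) indicators each bind to the nearest gene mention by token
distance (ties to the leftmost gene) and the binding is rejected beyond
five intervening tokens — interpreted as strictly more than five normalized
tokens, since the source heuristic does not pin down word-vs-token or
pre/post-normalization counting. A negation cue within three tokens before
a positivity indicator flips it to negativity (the flip window is our
choice; negation handling upstream is only mentioned as preprocessing).
Without a gene-bound assertion, the highest-priority context topic with a
matching primary indicator wins (priority VUS > Positive > Negative >
Insurance > Order > Evaluation > Information — result and rare topics are
more specific), and Information is the fallback, guaranteeing totality.
Conditional indicators fire only alongside a primary indicator of the same
topic and never decide a topic alone.

The shipped lexicons are seeded from reported high-PMI indicator words
(`family`, `history`, `hereditary`, `risk`, `insurance`, `order`, `vus`,
`negative`, `pathogenic`, ...) and are a faithful skeleton rather than a
replica: the fully converged clinical rule set from iterative expert review
was never published. Lexicons are extensible via YAML (`read_ruleset()`).

From result sentences, `extract_variant_record()` curates the
clinical-genomics data model: `HGVS_Short` is the nearest syntactic variant
mention; `Variant_Type` is inferred from syntax (substitution → SNP,
ins/del/dup/frameshift → INDEL, amplification/deletion terms → CNV,
rearrangement terms → Rearrangement); `Variant_Source` only from explicit
`germline`/`somatic` wording; `Variant_Pathogenicity` only from explicit
wording (`pathogenic`/`actionable`/`vus` — a bare "positive" asserts a
result but does not name a pathogenicity, which is exactly the distinction
the completeness audit measures); `Variant_Classification` only from
classification keywords (missense, nonsense, splice site, ...). Empty
fields are the expected outcome, not an error. Wildtype assertions set a
negative flag and leave pathogenicity empty.

## ML classification

Sentences become bag-of-words count vectors over a vocabulary fitted on
training folds only; unseen tokens are ignored at prediction time. The
classifier is a bagged ensemble of randomized CART-style trees: each tree
is grown on a bootstrap sample, evaluating a fresh random subset of
`mtry = floor(sqrt(p))` features at every node under the Gini criterion.
No tree learner ships in this environment, so the ensemble is implemented
in the package; splits are presence splits (`count > 0`), which for
short-sentence token counts loses essentially nothing and keeps split
search a single matrix crossproduct per node. Defaults: 500 trees, no
depth cap (no hyperparameters were reported; these are conventional
random-forest settings). Ten-fold stratified cross-validation reports
out-of-fold per-class precision/recall/F and two "overall" aggregates —
micro and support-weighted macro — because the original aggregation method
is unstated and its printed overalls imply a non-micro average. Feature
importance is mean impurity decrease plus per-token node-usage counts.
The four-topic task collapses Information/Evaluation/Order/Insurance into
Information; with rare Order/Insurance classes the coarse task should
score at least as well, a directional property the acceptance suite
checks. Everything is deterministic given the seed.

## Evaluation metrics

Precision $= TP/(TP+FP)$, recall $= TP/(TP+FN)$,
F $= 2TP/(2TP+FP+FN)$, computed exactly and rounded only on output; zero
denominators yield NaN with a warning. Inter-rater agreement is unweighted
Cohen's kappa (nominal labels; no weighting scheme was specified),
$\kappa = (p_o - p_e)/(1 - p_e)$, returning 1 by convention when both
raters are constant and identical.

## Quality auditing

`completeness()` audits five data-model fields over their expected scopes:
type, pathogenicity, classification and HGVS over Positive + VUS records;
source over Positive + VUS + Negative records (panel type, hence source, is
knowable for negative results too). Percentages are exact fractions rounded
half-up to one decimal — half-up, not banker's, to match how such tables
are conventionally printed (43.8 = 7/16, 20.8 = 5/24). `capture_rate()`
separates a patient-level question (did this reference-report patient's
result reach the notes at all?) from field-level completeness; the lenient
default matches on gene + compatible status, with a strict flag adding the
HGVS string, since whether variant identity must match was left open.
`detect_discrepancies()` flags gene switches (same patient, same status,
different gene) and status flips (pathogenic vs wildtype for one gene),
each with both provenances, and is symmetric under time reversal.
`topic_rank_matrix()` ranks every encounter (not distinct topics — result
mentions recur throughout follow-up) per patient and row-normalizes counts
to percentages; rows are kept at full precision so each sums to exactly
100.

## Association analysis

Therapy discussion is any Information-labeled sentence naming a PARP
inhibitor (class terms, generics, and brand names — including the
"Lyparza" spelling seen in clinical text alongside "Lynparza");
prescription is a generic-name hit in the structured medication table, in
clinical-trial (CDM) report lines, or any term in a "Current Medication"
note section (header regex, configurable). Prescription implies the
combined discussion-plus-prescription class, and a prescription without
any discussion evidence triggers a validation warning rather than an
error. The mutation-status × therapy-status table is tested with an exact
conditional test for r×c tables under the probability-ordering (two-sided)
criterion — sidedness was unstated, and probability ordering is the
standard r×c generalization: conditional on margins, sum the
hypergeometric probabilities of all tables no more probable than the
observed one (relative tolerance 1e-7). Tables are enumerated recursively;
beyond a configurable bound (default 2×10⁶ tables) a seeded Monte-Carlo
estimate over margin-preserving random tables is used with the
$(1+\text{hits})/(1+\text{draws})$ estimator.

## The synthetic world

`cohort_spec()` states the world the generator emulates, and its defaults
are fixed once, not tuned: 196 patients with reference-report mutation
prevalence 12 Mutated / 24 VUS / 160 Negative; 62% of patients documented
in notes at all (122/196); a temporal grammar placing 1–2 Evaluation and
1–2 Information encounters before one Order, an optional Insurance stage
(p = 0.3), then 1–4 repeated result mentions; sentence duplication at 0.42
(reproducing roughly 1179 instances per 682 uniques); field missingness at
one minus the audited completeness rates (0.50, 0.736, 0.562, 0.937,
0.75); a 3% gene-switch discrepancy rate among documented mutated
patients; and therapy effects (discussion 0.9/0.55/0.45 for
Mutated/VUS/Negative, prescription given discussion 0.65/0.10/0.03) chosen
to express the strong mutation→prescription association and the
more-than-half discussion prevalence reported for such cohorts, with
prescription never occurring without discussion. Templates use disjoint
per-topic slot vocabularies drawn from the rule lexicons.

What a green test does and does not establish: the generator's language is
templated, so perfect rule accuracy on it verifies the *mechanics*
(masking, distances, negation, precedence), not clinical coverage of the
lexicons on real prose; the deduplication step slightly enriches
detail-bearing result sentences (plain duplicates collapse more often), so
audited completeness on a generated cohort converges to the specified
rates only within a few percent; and real notes contain section headers,
typos and cross-sentence context the generator does not model.

`table1_fixture()` is a separate, fully deterministic worked-example
cohort engineered so the real pipeline reproduces exact printed fractions:
91 result records of which 16 are Positive/VUS, variant type inferable in
8 (4 via HGVS syntax, 4 via CNV/rearrangement terms), pathogenicity
wording in 7, one splice-site classification, HGVS strings in 4, source
wording in 24 of 91; 9 of 12 reference-positive and 5 of 24 reference-VUS
patients documented. It is labelled synthetic throughout: it mirrors
printed numerators and denominators, not any real text.

## Numerical and design notes

* All randomness flows through explicit seeds via a local-RNG helper that
  restores the caller's stream; same seed ⇒ identical folds, bootstraps,
  samples and Monte-Carlo draws.
* Character offsets are 0-based half-open; token distance is the number of
  tokens strictly between two mentions.
* Dedup ties, classifier ties (priority order; leftmost gene; first factor
  level on vote ties) and rank ties (note-id order on equal dates) are all
  deterministic.
* The worked-example and generator parameters are part of the stated
  world; they are never adjusted to make a test pass.

## Known limitations

No full HGVS grammar validation or genomic-coordinate handling;
negation handling is a cue-window rule, not scope parsing; no
cross-sentence coreference; the shipped lexicons are a starting skeleton;
XGBoost-style boosted baselines and outcome (survival) analysis are out of
scope.
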