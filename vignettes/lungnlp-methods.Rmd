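---
title: "Methods: rule-based abstraction of lung-cancer data elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based abstraction of lung-cancer data elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungnlp)
```

## What the package models

`lungnlp` automates the abstraction of six research variables for
primary lung cancer — overall stage, histological type, tumor grade,
and three boolean therapies (chemotherapy, radiotherapy, surgery) —
from a patient's narrative documents, and scores the automation against
an abstracted reference standard. The pipeline assumes:

* documents carry a patient id, a source type (clinical note,
  pathology report with a subtype, surgery report) and a calendar date;
* each patient has a diagnosis date anchoring all time windows;
* the relevant facts are stated in sentences by keyword ("stage IIIa",
  "adenocarcinoma", "status post lung cancer surgery"), not only
  implied — no inference from TNM components, lab values or imaging is
  attempted.

## Document selection

Clinical notes are used without any time limitation. Pathology and
surgery reports are admitted inside an inclusive window of
`days_before` (default 14) days before to `days_after` days after
diagnosis; stage/histology/grade are conventionally evaluated at 30,
60 and 90 days after, therapies use a 365-day surgery-report window.
Both boundaries are inclusive — "between 14 days before and 90 days
after" is read as a closed interval, which makes the boundary dates
testable. Pathology reports never feed the therapy elements. A
document with a missing date is dropped from the windowed sources but
retained as a clinical note, the conservative reading of the
"no limitation" rule for notes.

## Sentence segmentation

Segmentation is a deterministic rule: a run of `.`/`!`/`?` followed by
whitespace and an uppercase letter or digit ends a sentence, unless the
token before the punctuation is on an abbreviation stop-list ("Dr.",
"vs.", "e.g.", ...) or is a single capital initial. Single capitals
that are Roman-numeral letters (I, V, X) *do* end sentences, because
clinical text routinely ends sentences with "... grade I." Offsets are
0-based with half-open ends. The splitter is intentionally simple and
configurable: incorrect sentence splitting is a known error source for
this kind of system, and a transparent rule is easier to audit than a
learned one.

## Extraction rules and normalization

Rules are external YAML configuration (`extdata/ruleset.yaml`): per
rule an element, a case-insensitive Perl regular expression, the
capture group carrying the value, the sources it applies to, and
exclusion contexts. A rule's matches in a sentence are suppressed when
any of its exclusion expressions also matches that sentence — the
mechanism that stops "family history of prostate adenocarcinoma" from
yielding a lung histology. Overlapping matches within an element
resolve leftmost-longest, so "non-small cell lung cancer" never also
yields an inner "small cell" mention. A short negation cue list ("no
evidence of", "denies") ships disabled by default: the system being
modelled has no general negation detection, but the toggle
(`apply_negation = TRUE`) allows the experiment.

The full institutional keyword inventory behind such systems is never
published; the shipped ruleset encodes the behaviours that are
documented — the Table-style canonical vocabularies, the non-lung
exclusion sites, "status post lung cancer surgery", "combined
modality" as a radiotherapy cue, specific procedure names — plus
common surface variants, and both the ruleset and the normalization
table (`extdata/normalization.csv`) are user-replaceable so site
vocabularies can be swapped without code changes.

Normalization keys are case-folded with hyphens/slashes collapsed, so
"Non-Small Cell" and "non small cell" share one row. Unmapped
histology strings degrade to `OtherUnknown` (the value set has an
explicit other/unknown bucket); unmapped stage or grade strings raise
an error, because stage and grade have no such bucket and an unmapped
capture there means ruleset and table have drifted apart. The numeric
grade crosswalk (1 = well differentiated ... 4 = undifferentiated) is
the standard pathology convention.

## Discordance resolution

Within one source, the modal normalized value wins; frequency is
counted over mentions pooled across all of the patient's eligible
documents in that source, since resolution precedes the cross-source
step. A frequency tie is broken by preferring an exact stage over a
nonexact stage, then the more severe concept. The severity orders are
the clinically standard prognostic ones: Ia < Ib < IIa < IIb < IIIa <
IIIb < IV; early < late; Limited < Extensive; well < moderately <
poorly < undifferentiated. A histology severity order is the least
grounded of these (other/unknown < carcinoid group < NSCLC subtypes <
NSCLC-unspecified < small cell) and is therefore isolated in
configuration (`severity_rank()`); whether the original tie-break was
ever meant to apply to histology is genuinely open, and the package
applies it there for determinism. A stage tie spanning SCLC and NSCLC
values — possible when documents disagree about the disease class —
falls back to whichever class carries more mentions overall, with
NSCLC preferred on a class tie.

Across sources, disagreement resolves by pathology report > clinical
note > surgery report; agreement or a single contributing source
returns that value. The same priority is applied to stage, histology
and grade alike, reading the combination rule as element-generic.
Therapies are simple existence flags over eligible mentions.

## Evaluation

All scoring is at patient level. For one element: A = reference
patients carrying the element, C = those with any extracted value,
B = those whose extracted value is true. Precision1 = B/A,
Precision2 = B/C, Recall = C/A; the identity P1 = P2 × R holds by
construction and is asserted on every result. Patients the system
labels but who lack the element in the reference contribute to none of
the counts — the denominators are reference- and extraction-anchored
only. Matching is hierarchical where the reference is coarser than the
prediction: a predicted NSCLC subtype is a true positive against a
reference that only says non-small cell, and an exact predicted stage
is a true positive against a nonexact reference band via the 4/3
partition Ia/Ib/IIa/IIb → early, IIIa/IIIb/IV → late. The reverse
directions do not match: a nonexact prediction never satisfies an
exact reference. Grade and the therapy flags match exactly. Metrics
are reported rounded to 3 decimals; raw ratios are retained.

## The synthetic cohort generator

Real multi-source EHR corpora with abstracted gold labels are private,
so every stage of the pipeline is exercised on generated cohorts with
ground truth known by construction. Defaults are fixed once and are
not tuned to test outcomes:

* **Histology distribution**: the training-split class shares of a
  2006-patient abstracted cohort (adenocarcinoma 44.7%, squamous
  17.8%, small cell 16.9%, NSCLC-unspecified 17.0%, the rest rare).
* **Stage**: uniform over the seven exact stages for NSCLC patients;
  small-cell patients draw Limited/Extensive (uniform). **Grade**:
  uniform over the four levels.
* **Therapy prevalences**: 1674/2311 chemotherapy, 769/2311
  radiotherapy, 312/2311 surgery, from the same cohort's abstracted
  counts.
* **Documents**: each patient gets `1 + Poisson(2)` clinical notes,
  one pathology report (40% chance of a second) carrying histology,
  grade and stage, and a surgery report iff operated on. Pathology
  offsets default to −14..+30 days, surgery 0..+60, notes −30..+200.
  A real chart has far more notes (a mean near 59 is plausible for a
  longitudinal record), but templated notes carry the same mention
  content per document, so the default trades chart length for speed;
  the count distribution is configurable.
* **Noise dials**: `discordance_rate` replaces a planted categorical
  value with a non-gold value of the same element (same disease class
  for stage); `distractor_rate` inserts a family-history sentence with
  a non-lung primary; `missing_element_rates` silently omits an
  element from a patient's corpus while keeping it in the reference,
  which is how C < A arises in practice when source material is
  inaccessible.

Documents are assembled from a small template library
(`extdata/templates.yaml`) of single-sentence lines, so the generator
records its own sentence boundaries, and the segmentation module is
required to reproduce them exactly. A per-sentence ledger records every
planted value and whether it is gold, giving the round-trip oracle:
with noise off, the multiset of extracted normalized mentions must
equal the planted ones sentence by sentence.

What passing these tests shows — and does not show: the generator's
language is templated, so perfect recovery demonstrates the internal
consistency of rules, normalizer, resolver and evaluator, not
robustness to the diversity of real clinical prose, to section
structure, OCR noise, or institution-specific vocabularies. Those
require site rule tuning, which is why rules and mappings are external
configuration.

## The CNN cross-check

The classifier is the conventional text-CNN: embedding lookup, one
1-D convolution with 128 ReLU filters of width 5, 1-max pooling over
the sequence, a fully connected layer and a softmax sized to the label
set. Embeddings are skip-gram with negative sampling trained on the
corpus itself (the alternative of random initialization is a config
option); both embedding training and the classifier are plain seeded R
numerics, deterministic on a single thread, with embeddings frozen
during classification. Unstated hyperparameters are fixed at
defaults: embedding dimension 50, max sequence 256 tokens, Adagrad,
10 epochs, per-document updates. Documents are classified per patient
by concatenating the patient's eligible documents (document mode;
classifying rule-labelled sentences instead is possible by feeding a
different training frame).

On a separable synthetic corpus — uniform 10-class histology,
canonical surfaces only, no noise — held-out accuracy reaches 1.0,
which is the sanity bar for this architecture on linearly separable
keyword data, not a claim about real documents. `cross_check()`
partitions patients by agreement of rule system, CNN and reference;
the bucket where both systems agree against the reference is the
candidate-reference-error report that motivates running a second,
independent extractor.

## Numerical and degenerate-input choices

* Window arithmetic is whole days on calendar dates; no time of day.
* Empty mention multisets resolve to absent, never to a default value.
* A zero evaluation denominator yields `NA` with a warning rather than
  0 or 1.
* Segmenting an empty document, predicting on empty text, and training
  on a single class are errors; a document that is all
  out-of-vocabulary predicts from padding embeddings with a warning.
* Seeds: every stochastic step (cohort generation, splits, embeddings,
  CNN) takes an explicit integer seed and restores the caller's RNG
  state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their cohorts at
200 patients (clean recovery), 300 (noisy-metric reporting),
500 patients / 100 held out (CNN), and 5000 gold draws (distribution
recovery); these sizes give stable stochastic checks while keeping a
full run in the low minutes on one CPU.

## Known limitations

* No TNM-component extraction and no TNM-to-stage mapping.
* No section detection: a pathology report's "diagnosis" section is
  not distinguished, although stage language concentrates there.
* No general negation or uncertainty handling (the cue list ships
  disabled).
* The shipped vocabulary is a documented-behaviour reconstruction, not
  an institutional inventory; real deployments should expect to edit
  the YAML/CSV configuration.
* Imaging reports and scanned/PDF material are out of scope, which in
  real corpora is exactly what makes recall fall below 1.
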