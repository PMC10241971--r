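---
title: "Methods: registry-linked accuracy evaluation of teledermatoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registry-linked accuracy evaluation of teledermatoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teledermacc)
```

## The evaluation problem

A store-and-forward teledermatoscopy service lets a general practitioner
send dermatoscopic and macroscopic images of a skin lesion to a
dermatologist, who returns an ICD-10 working diagnosis and a management
plan (excision, biopsy, dermatologist visit, a checkup in 1–12 months, or
no action). Whether the service finds melanomas can be evaluated without a
prospective trial when a country keeps a complete histopathology registry:
every excised melanoma eventually produces a histopathology record, so a
melanoma record within an observation window after the examination is a
positive reference test, and the absence of one is a negative reference
test. The price of this design is that the two databases were never built
to be linked: there is no lesion identifier, lesion locations are coded at
different granularities, and one patient may have several examinations and
several histopathology records.

This package implements that evaluation as a deterministic, auditable
pipeline: record validation, three-criterion matching with explicit
worst/best-case handling of ambiguity, outcome classification, and
interval estimation — plus a synthetic-cohort generator so every stage can
be validated against known ground truth.

## Matching model

An index/reference pair is a *candidate* when (1) the histopathology date
falls within `window_days` (default 548, inclusive) after the examination
date, (2) the patient IDs agree, and (3) the locations are compatible.
Compatibility bridges the granularity gap: the service records one of 15
body-map regions, the registry a coarse site text; the packaged table maps
each site to its compatible region set ("Entire skin of abdomen" →
torso front or sides; "Skin tissue" is a wildcard compatible with
everything). The table is a plain CSV so users can extend it; an
unmappable site is an error, never a silent non-match.

Three rules then shrink the candidate set:

1. **Same-lesion deduplication.** Without a lesion identifier, "same
   lesion" is operationalized as same patient and same fine region.
   Within such a group, the earliest examination is kept and later ones
   excluded — unless the earliest carries a checkup plan and has no
   candidate reference, in which case it yields to the follow-up
   examination it presumably triggered. A lone examination is always
   kept.
2. **Duplicate references.** When several references are candidates for
   one index test, the pair with the least examination-to-histopathology
   gap wins; ties break on the smaller record ID (tied references are
   interchangeable for the confusion matrix, which a test verifies by
   exhausting both choices). A losing reference may still match another
   examination; otherwise it is excluded as a duplicate diagnosis.
3. **Scenario resolution.** Residual ambiguity (several examinations
   competing for a reference) is resolved twice over the connected
   components of the candidate graph, by exhaustive enumeration of
   *maximum-cardinality* one-to-one assignments: the worst case picks the
   assignment maximizing false negatives, the best case the one
   minimizing them, with total gap days as tie-break and enumeration
   order as final tie-break, so both runs are fully deterministic.
   Restricting to maximum cardinality means no matchable melanoma record
   is discarded just to improve (or worsen) the score. Components beyond
   `max_component` candidate pairs (default 20) abort with a request for
   manual review rather than risk an unverified search; in both the
   packaged cohort and realistic simulations components contain at most a
   handful of pairs. The worst case is the default reporting scenario: it
   is the conservative bound.

Unmatched references are excluded after matching (as duplicate diagnoses
or simply unmatched); every exclusion at every stage lands in a
reason-coded ledger, and conservation (matched + unmatched + excluded =
loaded) is asserted by tests for both tables.

## Classification and estimation

Index positivity reflects how dermatologists actually code: because a
definitive C43/D03 is rarely assigned without histology, a neoplasm of
uncertain or unknown behaviour (D48.5 or D48) *with an excision or biopsy
plan* counts as positive alongside outright C43/D03. Deferred decisions
("visit dermatologist", 1-month checkup) are valid inconclusive; unusable
images are invalid inconclusive; both stay out of the 2×2 table but enter
the yield denominator accounting. Precedence is invalid > melanoma
diagnosis > D48-with-excision > valid-inconclusive > negative; the
diagnosis-first rule is a deliberate choice for the undocumented corner
where a C43 diagnosis carries a checkup plan. Management of a confirmed
melanoma is correct for excision, biopsy or dermatologist visit,
inconclusive (denominator-excluded) for a 1-month checkup, incorrect
otherwise — so a matched valid-inconclusive examination still contributes
to management accuracy, which is why the two denominators differ (22 vs
21 in the packaged cohort).

Proportions (sensitivity, specificity, prevalence, management accuracy)
carry exact Clopper–Pearson intervals from beta quantiles. Predictive
values use the standard-logit interval with the variance decomposed over
the diseased (n₁) and nondiseased (n₀) strata:

$$\mathrm{logit}(PPV) = \ln\frac{\rho\,Se}{(1-\rho)(1-Sp)},\qquad
\mathrm{Var} = \frac{1-Se}{Se\,n_1} + \frac{Sp}{(1-Sp)\,n_0},$$

and the NPV analogue. The plain single-binomial logit interval on
TP/(TP+FP) does **not** reproduce the published predictive-value
intervals; the stratified form does, which fixed the choice. z is the
exact normal quantile (1.95996…) except where a hand calculation with
1.96 is being reproduced. The Buderer sample-size formula takes the
interval *half*-width W directly: n = ⌈z²·Se(1−Se)/(W²·ρ)⌉, the variant
confirmed by reproducing the planned 2930 cases from Se 0.83, ρ 1.85%,
W 0.10, z 1.96; the returned object also reports which branch
(sensitivity or specificity) drove the requirement. Degenerate inputs are
explicit: Se or Sp of exactly 0 or 1 makes the logit variance infinite,
so the predictive values are reported as not estimable rather than
silently replaced, and a pipeline run with no matched melanoma reports NA
estimates with n₁ = 0 instead of failing.

## The packaged study cohort

`table1_cases()` ships the published matched-case listing verbatim: 23
positive references, the 22 examinations they matched, the coded
day-gaps, morphology codes (superficial spreading melanoma 55320002,
melanoma NOS 2092003, melanoma in Hutchinson freckle 44474009 → C43;
melanoma in situ 77986002, Hutchinson freckle 61217001 → D03) and the
coarse/fine location pairs. Absolute dates are synthetic anchors spaced
through the service period; every published day gap is exact. Two
alternate same-patient examinations reconstruct the two ambiguous
linkages the study reported (they are not printed in the listing but are
implied by its best-case discussion): for patient 2 a positive D03
examination at a sibling region, so the worst case books a false negative
where the best case books a true positive; for patient 7 a 6-month-checkup
examination that loses the gap tie-break in both scenarios.

`study_fixture()` embeds this listing in a full-size cohort: 350 further
unmatched positives, 4375 unmatched negatives (diagnoses and plans drawn
with the published frequency mix — melanocytic nevi 59.3%, seborrheic
keratosis 22.1%, no-action plans 58.5%, and so on), 377 further
valid-inconclusive rows, 91 unusable-image rows and 172 rows failing one
matching criterion each. Only the margins are constrained: individual
filler rows are synthetic and carry no case-level claim. The published
flow counts do not reconcile by simple subtraction, so the fixture is
built self-consistent around the counts the yield formula actually uses
(4748 analyzed; 5389 − 172 − 91 in the denominator). Filler patients
never repeat a body region, because a repeat would trigger the
same-lesion rule and perturb the constrained margins.

## The synthetic generator

`generate_cohort()` draws patients (cases per patient = 1 + a geometric
tail, mean ≈ 1.4), assigns each case a region, an examination date and a
latent melanoma status (default prevalence 0.44%), and then simulates the
reader: an examination is invalid with probability 0.017,
valid-inconclusive with 0.079, otherwise positive-coded with probability
Se_true (0.90) for melanomas and 1 − Sp_true (0.93) for non-melanomas.
Detected melanomas are coded D48.5/D48 + excision with probability 0.75
(the documentation-convention effect) and C43/D03 otherwise. Every
melanoma generates exactly one reference record — reference positivity is
definitional — with a lognormal excision delay (median ≈ 20 days, mean ≈
40, occasional delays near the window edge), a reporting lag, a
morphology code consistent with the in-situ split, and a coarsened
body-site text (optionally the wildcard). The `coarsening` knob swaps in
any region→site map; an injective map emulates exact location coding and
makes linkage unambiguous, which the planted-link recovery test uses.
`n_ambiguous` plants same-patient sibling-region constellations to force
worst/best-case divergence on demand.

What the generator does *not* emulate: image content, lesion growth,
nonmelanoma skin-cancer histopathology, coding drift over time, or
patients seeking care outside the registry. Passing tests therefore show
that the pipeline's logic and intervals behave as specified under the
stated statistical model — not that the service's real databases are free
of linkage artefacts the model does not contain.

## Numerical and validation choices

Problem sizes were chosen to keep the full suite near 100 seconds: the
scenario matcher is checked against a brute-force power-set enumeration on
1000 random instances of up to 12 candidate pairs; Clopper–Pearson
coverage on 2000 binomial draws (n = 50, p = 0.2); parameter recovery on
200 simulated cohorts of ≈ 5000 cases at Se 0.90 / Sp 0.93 / prevalence
0.5%. In that experiment interval coverage for all three parameters sits
near nominal (0.945–0.955), while the worst-case sensitivity *point*
estimate averages below the true value — by design, since under coarse
location coding the worst case deliberately matches a melanoma reference
to a compatible negative sibling examination whenever one exists. It is a
bound, not an unbiased estimator; with injective location coding the
bias disappears and only the (conservative) exact-interval behaviour
remains, with small-n₁ sensitivity coverage rising to ≈ 0.99.

Known limitations: the location vocabulary is the closed set observed in
the published listing plus the body-region tally, so novel site texts
need a table extension; "same lesion" cannot distinguish two true lesions
in the same region of one patient; the exhaustive scenario search is
exponential in component size (capped rather than approximated); and all
dates are whole calendar days.
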