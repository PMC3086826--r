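---
title: "Stepwise deterministic record linkage with limited identifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise deterministic record linkage with limited identifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steplink)
```

## The problem

Cohort studies need complete ascertainment of hospital outcomes, but chasing
medical records does not scale and self-report decays with loss to follow-up.
Record linkage against a state-wide admissions dataset offers passive
follow-up — if the two datasets can be joined reliably. The setting this
package addresses is deliberately hard: the admissions side is de-identified
(no names, no addresses), and the only shared identifiers are

* the first 8 digits of the national health-insurance (Medicare) card number
  (`medicare8`) — present on only ~80% of admissions records, and unique to a
  *family*, not a person;
* a 3-letter suffix of the given name (`suffix`), the only field separating
  family members on one card;
* date-of-birth components, sex, country of birth, and up to four postcodes.

No single field identifies a person. Deterministic linkage — accept a link
only on complete agreement of a chosen identifier combination — is the
appropriate tool when partial identifiers are of high quality, but a single
combination is either too strict (data-entry errors break it) or too loose
(demographic "twins" satisfy it). The method here is a *stepwise* plan: an
ordered sequence of identifier combinations, most stringent first, where
records matched in one iteration are removed before the next.

## The matching rule

For a key specification $S$ (an ordered set of field selectors) and record
$r$, the composite key is the selected values joined with a reserved
separator. Within an iteration, a cohort record $c$ is linked to a hospital
person $h$ iff

1. both keys are present — a record missing *any* selected field is
   ineligible for that iteration (missing never matches missing);
2. the keys are identical; and
3. the key value is unique on *both* sides among the records still
   unmatched.

Rule 3 is the conservative reading of one-to-one deterministic linkage:
key groups of two or more on either side are skipped, logged in an ambiguity
audit trail, and remain eligible for later (usually tighter or differently
anchored) iterations. All matches within an iteration are accepted
simultaneously, so row order never affects results. Matched records are
removed from **both** datasets before the next iteration, which makes the
plan order meaningful: an early loose iteration can consume records a later
iteration would have matched differently. The shipped plans are therefore
frozen as golden configs (`inst/extdata/plans/`) and regression-pinned.

Keys are compared as HMAC-SHA-256 digests under a run-wide secret rather
than as plaintext. This is a design choice beyond the minimum (the source
protocol says only that the composite identifier was "encrypted"): a keyed
digest is deterministic, collision-resistant and useless without the secret,
so the two data custodians can exchange digests instead of reversible
identifiers. Digest-space matching provably coincides with plaintext
matching except for HMAC collisions (probability ~2^-128); the test suite
runs both paths and asserts identity. The separator (`|`) is forbidden
inside field values at normalization, which removes the classic
`("AB","C")` vs `("A","BC")` serialization collision. Per-composite (not
per-field) digesting was chosen because it reveals strictly less: equality
of individual fields across different key specs cannot be inferred.

## The shipped plans

* `plan_v1()` — 10 iterations anchored on the card prefix: full suffix,
  then the three two-letter suffix variants (+sex), then card+birth-year+sex,
  then suffix + full demographics over the four postcode slots, and finally
  demographics only. The suffix variants tolerate single-letter name
  discrepancies (e.g. transcription slips) at the cost of key discriminating
  power, which the added `sex` partially restores.
* `plan_v2()` — 4 iterations of demographics only (DOB + sex + country +
  postcode slot sweep). Usable when insurance numbers are unavailable, but
  exposed to demographic twins.
* `plan_v2_plus_suffix()` — `plan_v2()` with the full suffix added to every
  iteration; the directional fix for twin-driven false positives.
* `plan_final()` — the three-stage production plan, *generated from its
  relaxation rules* rather than hand-listed:
  * **Stage A** (card prefix + suffix, every iteration also carries the full
    demographic block): postcode-slot sweep; the sweep under each of the
    three suffix variants; drop-one over {postcode, country, sex, day,
    month, year}; the variant sweeps under each single drop; drop-two over
    all 2-subsets. Dropping *postcode* collapses the slot sweep to one
    iteration. The stage anchors (card prefix and suffix) are never dropped.
  * **Stage B** (card prefix only): sweep, then drop-one — catches nickname
    and middle-name suffix failures.
  * **Stage C** (suffix only): sweep — catches records with no insurance
    number on either side.

  At most two variables are ever relaxed at once. The generated plan has
  174 iterations; the published step numbering for the same rules ends at
  170 because its drop-two range under-counts the postcode-pair collapse
  (41 steps listed where the rules produce 45). We ship the rule-generated
  expansion: the rules, not the step numbering, are the method. Every
  iteration's selector set is unique, and the expansion order is
  deterministic.

## Validation machinery

**Agreement.** Two runs over the same cohort are compared participant by
participant into five categories (same person, different persons, only-A,
only-B, neither); the *disagreement fraction* is different-persons over the
full cohort size. In the pilot counts shipped with the package
(`pilot_reference_counts()`), 170 disagreements over a 2000-participant
sample give the reported 8.5%. The denominator choice (full sample, not the
doubly-matched subset) reproduces that printed figure.

**Sensitivity.** For participants with an independently confirmed admission,
a link is *correct* if the linked hospital person carries an episode
matching the confirmed hospital name (canonicalized exact comparison) and
dates. "Within ten days" is read as an inclusive ±10-day window applied to
both admission and discharge dates, the strictest reading that still
tolerates abstraction noise; the discharge comparison is skipped when the
confirmed record lacks a discharge date. Sensitivity = correct / confirmed,
with a Wilson score interval (the default because it is well-behaved at
n≈100 and reproduces the reported 86%–97% bounds for 94/101;
Clopper–Pearson is selectable and rounds identically there). The pilot's
non-matched rate is incorrect-links / confirmed.

**Ground truth.** On synthetic data the generator records the true
correspondence, so `ground_truth_metrics()` reports recovery sensitivity,
PPV and false-match rate — the specificity-style evaluation that
de-identified real data cannot support.

## What the generator emulates — and what it does not

`simulate_linkage_world()` produces a cohort roster, a hospital person index
containing one corrupted copy of each cohort member plus distractors, an
episode table, and ground truth. Error-model defaults are fixed to the pilot
data conditions where those were reported, and otherwise to one-time choices
we consider realistic for an Australian cohort of this era:

| knob | default | basis |
|---|---|---|
| hospital card-number missingness | 0.20 | reported availability ~80% |
| cohort card-number missingness | 0 | reported availability 100% |
| day-of-birth error (±2–10 days) | 0.02 | error *magnitudes* reported; rate chosen |
| gross birth-year error (±1–40 y) | 0.005 | magnitudes reported; rate chosen |
| postcode churn (new slot-1 code) | 0.10 | plausible residential mobility over follow-up |
| country-of-birth discrepancy | 0.01 | chosen |
| sex miscode | 0.005 | chosen |
| suffix from middle name | 0.02 | failure mode described; rate chosen |
| family card sharing | 0.10 | chosen; 30% of sharing pairs also share a name prefix |
| demographic twin rate | 0.01 | chosen |
| distractor multiplier | 2 | chosen (desk-scale stand-in for a state population) |

Postcode churn prepends a *new* first postcode (roster codes shift down a
slot), pushing matches to later slot iterations, which is how the slot sweep
earns its keep. Family sharing plus prefix collisions (e.g.
CHRISTOPHER/CHRISTINE → CHR) reproduce the one failure the suffix cannot
fix. Confirmed events copy a real episode with ≤2 days of date jitter and
occasionally a missing discharge date.

Passing tests on these worlds show the *algorithmic* properties — exactness
of the matching rule, one-to-one-ness, conservation, the directional value
of the suffix — not the real-world match proportions. The generator does not
model hospital catchment geography, card-number check digits, card changes
on divorce/remarriage (exposed as a knob, default 0), non-uniform name
frequencies, or correlated errors within families; headline match
proportions from restricted real data (93%/92%/87%) are properties of that
data and are not reproduction targets.

## Numerical and degenerate-input choices

* Missing is encoded as the empty string on disk and `NA` in memory; a key
  touching a missing field is missing as a whole.
* Readers reject rows (invalid dates including non-existent calendar days,
  unknown sex codes, missing/duplicate IDs) into a diagnostics table rather
  than dropping them silently; rows in = records out + diagnostics out.
* Postcode slots compact left (blanks and duplicates removed) so that slot
  *k* means "the k-th distinct postcode known".
* Ambiguity logging records every record in an offending key group with its
  cross-side candidate count, for clerical audit.
* `wilson_ci(0, n)` and `wilson_ci(n, n)` clamp to the [0, 1] endpoints by
  construction; `n = 0` is an error.
* The year-shift corruption rolls an invalid Feb 29 back to Feb 28 rather
  than discarding the record.

## Problem sizes in the test suite

The suite exercises the engine-vs-oracle equivalence on 100 random worlds of
30–120 participants under randomized error models (an independent
field-by-field brute-force matcher, no keys or digests); zero-error recovery
and monotone degradation on worlds of 150–250 over a small seed ensemble;
and rate recovery at n = 2000. These sizes give stable Monte-Carlo behaviour
for fixed seeds while keeping the default test run fast; the acceptance
script runs the full pilot scale (n = 2000, 101 confirmed events).

## Known limitations

* Specificity on real data is out of reach by design (no ground truth on the
  de-identified side); the ground-truth metrics exist only for synthetic
  worlds.
* Iteration order matters and is part of the method; permuting a plan is a
  different plan. The package pins the shipped orders rather than hiding the
  sensitivity.
* No probabilistic (Fellegi–Sunter) scoring, string-similarity, phonetic
  encoding, or clerical-review queue: exact equality on normalized fields
  only.
* One hospital person per participant and vice versa is enforced; settings
  where a cohort member may legitimately claim several person-index entries
  (imperfect internal linkage on the hospital side) are not modelled.
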