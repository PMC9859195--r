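---
title: "A step-wise model for assessing the age of majority"
author: "ageflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A step-wise model for assessing the age of majority}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageflow)
```

## The problem

When a young person arrives without identity documents, authorities may need
to establish whether they have reached 18 years — the age of majority and of
full criminal responsibility in most jurisdictions. Chronological age cannot
be measured directly; what can be staged radiographically is *biological
maturation*, and several skeletal and dental systems mature on known
schedules: hand/wrist ossification completes in mid-adolescence, the roots of
the seven left mandibular teeth (FDI 31–37) close before 17, the third molar
is the only tooth still maturing past 18, and the medial clavicular epiphysis
is the last epiphysis to fuse, never before 19.

`ageflow` implements a step-wise decision model over these systems, together
with a synthetic cohort generator that makes every probabilistic claim of the
model testable without radiographs or personal data. Under the governing
legal principle (*in dubio pro reo*), doubt must always fall in the subject's
favour: the model is built so that the only error it tolerates at any
appreciable rate is calling an adult a minor, never the reverse.

## The decision tree

`classify()` traverses the following gates in order. The traversal is
deterministic, total (every valid input reaches exactly one leaf), and the
returned object carries the full node path for audit.

1. **Physical examination.** Visible signs of abnormal growth (endocrine
   disease, precocious puberty, ...) divert to expert referral:
   `INDETERMINATE`, minor age presumed. Otherwise, if either Tanner
   characteristic is below stage 5, maturation is demonstrably incomplete
   and the subject is a `PRESUMED_MINOR` (no probability is attached — none
   is published for this gate, and none is invented).
2. **Seven left mandibular teeth** (orthopantomogram). Any open apex among
   FDI 31–37 means `MINOR`: in the reference sample every such subject was
   under 16, and root maturation of these teeth completes before 17 in both
   sexes. Without an orthopantomogram the model cannot proceed
   (`INDETERMINATE`): the hand/wrist radiograph carries no additional
   decision-relevant information (see below), so the OPT is required anyway.
3. **Third molar maturity index.** `I3M` is the sum of the distances between
   the inner sides of the open root apices divided by the tooth length,
   exactly 0 once the apices are closed (`compute_i3m()`). Bands:
   * `I3M < 0.08` — proceed to the clavicle. Schmeling stage 4 or 5 (fully
     ossified cartilage / scar no longer visible): **`ADULT` at 99.9 %**.
     Lower stage or clavicle not imaged: **96 %**, still above the default
     declaration threshold (95 %), hence `ADULT`.
   * `0.08 ≤ I3M < 0.15` — adult probability **60 %**: `PRESUMED_MINOR`.
   * `I3M ≥ 0.15` — adult probability **16 %**: `PRESUMED_MINOR`.
4. **Third molar not assessable** (6 % of subjects: agenesis, extraction,
   rotation, position). A fused clavicle still declares `ADULT` at 99.9 %.
   Below stage 4 the default policy is `INDETERMINATE` with minor age
   presumed, because an unfused clavicle covers too wide an age span to
   establish majority (only 46 % of such subjects are adults); a
   configurable alternative (`"apply_96"`) emits the 96 % figure instead,
   which is the other defensible reading of the published model. Both are
   implemented and tested; the conservative one is the default.

The four probabilities are carried verbatim as percentages (99.9, 96, 60,
16) and never re-derived — they are the published calibration of the model,
not quantities this package estimates at classification time.

Two further design points. The boundary value `I3M = 0.08` is assigned to
the *middle* band: the published wording ("less than 0.08", "over 0.08")
leaves it open, and the middle band is the conservative choice. Schmeling
stage 3 (partial fusion) is accepted as input and branches like any stage
below 4, but the outcome carries a note that it is not an approved
estimation stage.

### Why the hand/wrist drops out

Incomplete hand/wrist ossification was only ever observed below age 16, and
at those ages the seven-teeth gate already fires; complete ossification, in
turn, cannot separate 16- and 17-year-olds from adults. The classifier
therefore never consults the hand modality, and the test suite asserts this
by exhaustively pairing hand-present/absent inputs over the other branch
combinations. The carpal geometry is still provided in full (below) because
hand completeness remains a documented input and the Bo/Ca ratio is how it
is measured.

## Carpal geometry: the Bo/Ca ratio

Hand/wrist maturity is quantified as the ratio of the summed areas of the
carpal bones and ulnar/radial epiphyses (Bo) to the carpal region area (Ca),
with the rule that **overlapping bone regions are counted once**. Areas come
from the shoelace formula over digitised polygon outlines (mm); the union
area uses an exact vertical-slab decomposition: the x-axis is cut at every
vertex abscissa and every pairwise edge intersection, and within a slab the
covered vertical length is linear in x, so the midpoint rule integrates
exactly. No rasterisation is involved; the Monte-Carlo point-in-union
estimator exists only in the test suite, as an independent oracle (agreement
within 3 standard errors at 10^6 points, over random overlapping polygon
sets).

Degenerate inputs are rejected at construction: fewer than three vertices,
duplicated vertices, self-intersection, zero area. Whether the ulnar and
radial epiphyses contribute to Bo is the caller's choice — the union is
taken over whatever regions are supplied, which matches the flexibility of
the published description.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: subjects aged 14–24
(uniform by default; a weighted option reproduces the packaged
sample-distribution age mix), with latent maturation-event ages per subject
and observations derived deterministically from true age versus those latent
ages. The defaults encode the published population constraints as *hard
bounds of truncated normal distributions*, enforced at config validation:

| event age | default | hard bound |
|---|---|---|
| hand/wrist complete | N(15.0, 0.8) on [13, 16] | ≤ 16 |
| seven teeth complete | N(15.5, 0.7) on [13.5, 17] | ≤ 17 |
| Tanner stage 5 | N(14.3, 0.9) on [12.5, 16.5] | — |
| clavicle stage 4 | N(21.4, 1.5) on [19, ∞) | ≥ 19 |
| stage-5 delay | N(1.5, 0.5) on [0.5, 3] years | — |

The bounds are what make two of the model's claims *certain by
construction*: a fused clavicle implies age ≥ 19 > 18 (so
P(adult | stage ≥ 4) = 1 in any valid cohort), and incomplete seven-teeth
maturation implies age < 17 < 18 (so that gate can never misclassify an
adult... as anything but a minor, which is the tolerated direction). The
clavicle fusion mean 21.4 was chosen so that the unfused-clavicle group is
about 46 % adult under uniform ages: with fusion age S,
(E[S] − 18)/(E[S] − 14) ≈ 0.46 gives E[S] ≈ 21.4.

Each subject's third molar follows `I3M(age) = i0 · exp(−decay · (age −
14))`, truncated to exactly 0 at a random apex-closure age — the published
data imply only monotone maturation, so the exponential form is this
package's modelling choice, isolated in the config so alternatives can be
swapped. The decay mean 0.53/yr and i0 mean 1.05 place the 0.15-crossing
near age 17.7 and the 0.08-crossing near 18.9, which is what positions the
three I3M bands' adult fractions near 16 %, 60 % and 96 %. Closure and
clavicle fusion ages share a latent maturation factor (Gaussian copula,
ρ = 0.5), keeping the joint event "fused clavicle with I3M > 0.08" at the
sub-percent rarity observed (a single subject, 2 % of the imaged subsample).
Third-molar assessability is Bernoulli(0.06), independent of age (verified
by a chi-square test in the suite).

Randomness follows a strict contract: one seeded Mersenne–Twister stream,
a fixed block of 13 inverse-CDF draws per subject (no rejection sampling
anywhere), laid out row-wise — so the cohort is byte-reproducible for a
given (config, seed) and enlarging the cohort leaves earlier subjects
bit-identical.

What the generator does *not* emulate: radiographic images or polygon
geometry (observations are generated at the flag/index level), sex-specific
maturation offsets (no sex-split figures are published to calibrate
against), inter-rater staging error, and population shifts from
socio-economic or ethnic differences. Passing tests therefore demonstrate
internal consistency of the decision model with the published conditional
structure — not transferability to any real population.

## Calibration

`calibrate_simulator()` tunes six location/spread parameters (I3M decay mean
and spread, i0 mean, closure mean, clavicle fusion mean, teeth completion
mean) by seeded coordinate descent with common random numbers, against the
published conditionals: 96 % adult on the low-I3M/unfused-clavicle branch,
60 % and 16 % in the middle and high bands, 46 % in the
clavicle-below-stage-4 marginal (which is computed over *all* subjects with
an unfused clavicle, irrespective of dental evidence — reported alongside,
not inside, the leaf table). Default: 4 sweeps, 50 000 subjects per
evaluation, ±2 percentage-point tolerance. Unattainable targets produce a
failure report with achieved values, not an error. The decay *spread* is in
the search because the high band's adult share is governed less by the mean
crossing age than by between-subject heterogeneity of the crossing age.

```{r calibration, eval = FALSE}
cal <- calibrate_simulator(n = 50000, seed = 1)
cal
coh <- simulate_cohort(cal$config, n = 50000, seed = 2)
estimate_branch_probabilities(coh)
```

## Estimation and error accounting

`estimate_branch_probabilities()` runs a cohort with known true ages through
the tree and reports, per reached leaf, the adult fraction with Wilson 95 %
bounds (Wilson rather than Wald because several leaves and the joint event
are small-count). `misclassification_report()` counts both error directions
and flags every minor-declared-adult case individually; under the calibrated
defaults that rate is the complement of the 96 % branch (≈ 1.5 % of minors,
all of them 17-year-olds with precociously closed third molars), while
under-classification of adults — the tolerated direction — is dominated by
the 60 % and 16 % leaves.

## Numerical choices and edge cases

* `I3M = 0` is exact when the gap list is empty or all gaps are at or below
  the configurable `closed_epsilon` (default 0): no floating-point residue
  reaches the band comparison.
* Band edges use half-open intervals (`< 0.08`, `[0.08, 0.15)`, `≥ 0.15`).
* The slab-decomposition union is exact for simple polygons; slabs of zero
  width contribute nothing, and the midpoint of each slab can never
  coincide with a vertex abscissa or an edge crossing, which is what makes
  the even-odd crossing count well defined there.
* An ADULT outcome is structurally required to carry a probability at or
  above the declaration threshold; this is asserted in the constructor, so
  a mis-configured tree fails loudly rather than emitting an inconsistent
  outcome.
* Problem sizes in the shipped tests: 20 000-subject cohorts for the
  hard-bound and cohort-rate checks, 50 000 for calibration recovery,
  10^6 Monte-Carlo points per geometry oracle instance. These give
  Monte-Carlo standard errors comfortably below the tolerances being
  asserted (e.g. 0.17 pp for the 6 % assessability rate at 20 000).

## Known limitations

* The branch probabilities are frozen constants from a single Caucasian
  Italian sample aged 14–24; the package deliberately provides no mechanism
  to re-estimate them from the simulator, because simulated data cannot
  validate claims about real populations.
* The conditional probabilities depend on the cohort's age mix; the
  published 96 % figure implicitly conditions on that study's age
  distribution. The simulator treats the age distribution as explicit
  configuration (uniform default, table-weighted option) so this
  sensitivity is inspectable rather than hidden.
* Tanner staging is operationalised as "both characteristics at stage 5";
  sub-stage granularity and examiner disagreement are out of scope.
* No point age or attributable age interval is estimated — the model
  answers only the binary majority question, as published.
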