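---
title: "Scoring pulmonary edema on bedside chest radiographs and evaluating reader studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pulmonary edema on bedside chest radiographs and evaluating reader studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edemascore)
```

## The clinical problem

Bedside chest radiographs (supine, antero-posterior) are the routine
imaging modality for ventilated ICU patients, and one of their most
consequential readings is whether the patient has pulmonary edema.
Unaided assessment of these technically difficult films is known to be
inconsistent across readers.  Transpulmonary thermodilution provides a
quantitative reference — extravascular lung water (EVLW) in mL/kg — but it
is invasive and not available for every patient.  `edemascore` implements
a standardized alternative: a weighted ordinal rubric over nine
radiographic indicators whose sum is compared with a fixed decision
threshold, together with the statistical machinery needed to evaluate
such a rubric in a paired multi-reader study against an EVLW reference.

## The scoring rubric

Each of nine indicators is graded on an ordinal severity scale and
converted to points:

```{r}
edema_rubric()
```

Kerley B lines and micronoduli carry a three-point scale (absent plus two
present grades); all other indicators a four-point scale.  The "missing"
grade always scores zero, and point values rise strictly with severity.
The weights encode how specifically each finding represents extravascular
water: enlarged hilar vessels have many possible causes and top out at 3
points, whereas extensive perihilar haze and a diffuse density increase
are direct manifestations of lung water and reach 15.  The maximum total
is 88.  A total **strictly greater than 15** is classified as pulmonary
edema; the boundary itself (total = 15) is classified as no edema.  This
single strict comparison lives in `classify_score()` so the decision rule
is auditable in one place.

Two representational choices deserve a note.  First, severity levels are
stored *positionally* (0 = missing, then ascending severity); display
labels are cosmetic.  For the three-point indicators the two present
grades are simply labelled "lower"/"higher", which sidesteps any
ambiguity about whether the 4-point grade is "mild" or "moderate" — the
points (0/4/8) are unambiguous either way.  Second, the three hilar-vessel
findings are modelled as three independent indicators because each has
its own point vector, even though a reporting radiologist may think of
them as one family of findings.

The rubric is configurable (`read_rubric()` loads weights and threshold
from YAML) so sensitivity-to-weights experiments are possible, but the
default is frozen and checksummed (`rubric_checksum()`); every report
records the checksum of the rubric that produced it.  Rating sheets are
all-or-nothing: every indicator must be graded, and no "not assessable"
state is modelled — a partially graded sheet is a validation error rather
than a silently imputed zero.

## The reference standard

EVLW of at most 8 mL/kg is taken as no pulmonary edema, at least
15 mL/kg as pulmonary edema, and the 9–14 mL/kg band as borderline.
Borderline cases are loaded and flagged, excluded from every accuracy
computation, and listed in the fitted study object — never dropped
silently.  Because the device reports integer values, non-integer input
is rounded half-up before banding (8.49 is no edema, 8.5 is borderline);
half-up rather than banker's rounding keeps the mapping monotone in the
raw value.

## Evaluating a paired reader study

`edema_study()` is the package's central fit.  Its inputs are two
readers-by-cases call matrices — the same readers reading the same cases
under the score-based and the unaided ("standard") approach — and the
EVLW reference.  For each arm it computes:

* pooled confusion counts over all reader-by-case readings, and the four
  diagnostic proportions (sensitivity, specificity, PPV, NPV) on the
  percentage scale with binomial confidence intervals;
* the mean pairwise inter-reader agreement `P0` (per case, the fraction
  of concordant reader pairs; averaged over cases) and the free-marginal
  multirater kappa `(P0 - 1/k)/(1 - 1/k)`, which for two categories is
  `2 * P0 - 1`.  The free-marginal form is the right chance correction
  when readers face no quota on how many cases they may assign to each
  category, as in any diagnostic reading session;
* per-reader correct-call counts with their across-reader mean and
  standard deviation.

Across arms it computes the binary net reclassification index from the
paired readings: among true-edema readings, reclassifications from
`no_edema` to `edema` count up and the reverse down; among
true-non-edema readings the directions are mirrored, and

$$\mathrm{NRI} = \frac{\mathit{up}_{ev} - \mathit{down}_{ev}}{n_{ev}}
  + \frac{\mathit{down}_{ne} - \mathit{up}_{ne}}{n_{ne}},$$

which is algebraically the change in sensitivity plus the change in
specificity.  The standard error uses the asymptotic variance of the two
paired-difference proportions,
`(p_up + p_down - (p_up - p_down)^2)/n` summed over the event and
nonevent strata, with a Wald interval and a normal-approximation
two-sided p-value.  When the arms are identical nothing is reclassified,
the standard error is zero and the p-value is reported as `NA` rather
than a fabricated number.  The raw up/down counts are always exposed in
the output so alternative variance estimators can be applied downstream.

```{r}
s <- example_reader_study()
fit <- edema_study(s$calls_score, s$calls_standard, s$reference)
fit
```

`summary()` adds the per-reader table, `coef()`/`confint()` extract the
point estimates and intervals, and `plot()` draws each reader's paired
operating points.

### Confidence-interval method

Proportion intervals default to Clopper–Pearson (beta-quantile closed
form), with Wilson available; the method name is recorded in every
report.  The exact interval is deliberately conservative — its coverage
is at least nominal for every true proportion, which matters at the
degenerate corners (70/70 correct calls) that small reader studies
actually produce.  Published reader studies do not always state their
interval method, and printed bounds cannot generally be matched without
knowing it; this package treats point estimates as the reproducible
surface and intervals as method-tagged output.  (It is worth noting that
the package's NRI Wald intervals do reproduce the published pooled NRI
interval of the motivating study to display precision.)

### The packaged fixture

`example_reader_study()` reconstructs a seven-reader, twenty-case paired
study from published per-reader correct-call counts.  Two aspects of the
reconstruction are conventions, not data: the per-case assignment of
which calls were correct (the first *k* cases in each truth group are
marked correct) and the EVLW values (synthetic placeholders cycling
through each group's reported range).  All pooled and per-reader
confusion counts, diagnostic metrics and NRI point estimates are
invariant to both conventions.  Raw-call statistics are not: the
agreement proportion and kappa computed from these reconstructed calls do
not equal the published ones, because the true per-case calls were never
published.  `free_marginal_kappa()` applied to the *published* agreement
proportions is the reproducible route for those.

## The synthetic study generator

The generator emulates the study design, not radiographic biology:

* `simulate_cohort()` draws integer EVLW values uniformly within each
  group's band (defaults 15–21 for edema, 4–8 for no edema, 9–14 for
  borderline; default sizes 10/10/0, the classic two-group design).
* `severity_model()` is the generative link from true status to
  indicator severities — one probability vector per indicator per
  status.  The `"separable"` preset is degenerate (edema shows every
  indicator severe, non-edema none) and is used for contract tests where
  the score arm must be perfect.  The `"paper_like"` preset was
  calibrated once, by exact convolution of the per-indicator point
  distributions, so that the latent total crosses the threshold with
  probability 0.766 for edema cases and 0.0006 for non-edema cases —
  i.e. score-based reading operates near 77% sensitivity at essentially
  100% specificity.  The calibrated values are frozen in the preset; no
  biological claim is attached to them.
* `reader_profiles()` gives each reader a rating-noise probability (each
  indicator independently mis-graded by one level, symmetric and clamped
  to the scale — the simplest perturbation respecting the ordinal
  structure; default 0.05) and an operating point for the unaided call
  (defaults: sensitivity 0.5714, specificity 0.90, the pooled unaided
  performance of experienced radiologists on bedside films).
* `run_virtual_study()` scores the simulated sheets for the score arm,
  draws Bernoulli unaided calls for the standard arm, and fits
  `edema_study()`.  Borderline cases, if simulated, draw their latent
  severities from a 50/50 mixture of the two conditionals and are
  excluded by the evaluation stage like any borderline case.

All randomness flows through R's global generator seeded once per
simulation call; the same seed reproduces a study bit-for-bit
(arguments are forced before seeding so inline and precomputed inputs
give identical streams).

What passing simulation tests shows — and does not.  The generator
reproduces the *design*: two-group cohorts, paired arms, configurable
operating points.  It does not reproduce correlated indicator
expression, reader-specific bias, case difficulty, or any dependence of
severity on the continuous EVLW value within a band.  Tests built on it
therefore validate the statistical machinery, not the clinical rubric.

## Numerical and testing choices

Rating-sheet scoring is integer arithmetic throughout, so score
equalities in tests are exact.  The test suite checks the rubric against
a brute-force enumeration of all 147,456 level combinations, the
Clopper–Pearson implementation against the independent exact-test oracle
in `stats::binom.test()` (coverage additionally verified by simulation at
n = 70 with 10,000 replicates per true proportion), Wilson against
`stats::prop.test(correct = FALSE)`, and the NRI's pair-counting route
against the independent confusion-matrix route on random studies.  The
Monte-Carlo recovery test uses 7 readers on 2,000 cases (14,000 readings
per arm), large enough that pooled proportions sit within a fraction of a
percentage point of their targets while the whole suite runs in well
under a minute.

## Limitations

The package scores human-entered severity grades; it performs no image
analysis and does not attempt to distinguish the etiology of edema
(cardiogenic, renal, injury).  Multi-category NRI, ROC analysis (the
design makes binary calls only) and corrections for the clustering of
readings within readers beyond the pooled/per-reader split are out of
scope.  The per-reader NRI p-values inherit the normal approximation,
which is optimistic at n = 10 readings per group; the exposed
reclassification counts allow exact alternatives.
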