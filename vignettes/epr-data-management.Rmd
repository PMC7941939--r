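---
title: "Managing multi-site electronic patient record data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing multi-site electronic patient record data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprlink)
```

## The problem

Trials that take their outcome data from routinely collected electronic
patient records (EPRs) face a data-management problem that bedside data
collection does not: the same clinical fact arrives from many hospitals in
many source systems, under different variable names, category vocabularies,
units and date formats, keyed by identifiers that must never leave the
hospital. eprlink implements a complete, testable pipeline for this setting,
modelled on the data management of a large cluster-randomised maternity
trial: per-site pseudonymisation, staged quality checks, dictionary-driven
harmonisation, deterministic linkage of neonatal, ultrasound and
hospital-activity records onto a maternity spine, a clinician-consensus
outlier policy, and multiple imputation by chained equations.

Because real hospital extracts cannot be shared, the package carries a
synthetic multi-site EPR generator with known ground truth. Every pipeline
stage is exercised against that truth; nothing in the test suite needs any
download.

## Pseudonymisation

Each woman's study identifier is a pure function of her NHS number and date
of birth: characters 1–19 are the decimal rendering of an HMAC-SHA256
digest keyed by a secret salt, character 20 is a check letter. The design
properties are:

* **Determinism.** The same (NHS number, DOB, salt) always yields the same
  identifier, so one woman keeps one identifier across extracts and across
  pregnancies. The delivery date is deliberately excluded from the inputs.
* **Irreversibility.** The digest is keyed; without the salt or the key
  file, the identifier does not reveal any identifier substring. The key
  file linking identifiers to pseudonyms is written only to a separate key
  sink and stays with the site.
* **Collision resistance at trial scale.** 19 digits carry roughly 63 bits;
  at 10^5 women the birthday bound puts the collision probability near
  5×10⁻¹⁰. The bundled simulation (`simulate_collisions()`) checks this
  empirically at 100,000 women with deliberately narrow date ranges.
* **Error detection.** The check letter is the weighted character sum
  modulo 26. The weights are 1–12 and 14–20: a weight divisible by 13
  would let a single-digit substitution with an even difference slip
  through (13·Δ ≡ 0 mod 26), so position 13 carries weight 20 instead.
  With these weights every single-position digit substitution changes the
  check letter.

Women lacking the required identifiers receive a *manual* identifier
(`make_manual_id()`), namespaced by a leading `M` so the two identifier
families can never collide; a manual identifier denotes a unique pregnancy,
never a woman.

The NHS numbers the generator produces carry genuine modulus-11 check
digits (weights 10…2, remainder mapped with "no number has check 10"), so
the validator in the pseudonymisation path is exercised against the real
national scheme.

## The synthetic generator as study design

The generator (`site_config()`, `generate_bundle()`) defines the study
conditions, and its defaults are fixed rather than tuned:

* Delivery dates uniform over the configured trial window
  (2017-01-01–2018-11-30 by default, matching the collision-simulation
  ranges); maternal DOB 1978–2003.
* Gestational age in completed days, range 154–301: a 93/7 mixture of a
  term component (mean 281 d, sd 8) and a preterm tail (mean 245 d, sd 25).
* Birthweight from a quadratic-in-log gestational-age median curve with a
  ±2.5% sex effect and proportional spread (11% of the median); twins are
  shifted down 15%. The 10th centile of this model doubles as the bundled
  *synthetic* stand-in for the external customised-centile calculator,
  which is pluggable (`centile_fn`) and out of scope.
* Maternal height Normal(1.64 m, 0.07); weight derived from a log-normal
  BMI draw (median 24.5, log-sd 0.18, clipped to 17–54) times height², so
  every *true* value lies strictly inside the plausibility limits and only
  injected defects can fall outside — this is what makes exact
  removal-count accounting possible.
* Twin rate 1.5%, neonatal admission 10%, 4% of women with a second
  in-window pregnancy, 10%/8% of pregnancies with no ultrasound/activity
  records (care received elsewhere), so linkage rates are genuinely below
  100% for the satellites and low for neonatal records, as they should be.

Three source-system dialects render the same facts differently: `alpha`
(ISO dates, "40+2" gestation, centimetres, `Em LSCS`-style categories),
`bravo` (DD/MM/YYYY, decimal weeks, "5ft 4in", "10st 6lb"), and `charlie`
(spreadsheet serial dates, integer days, affirmative-only binary flags, and
parity available only as nulliparous/multiparous — the case that motivates
the parity rule below). Rendering quantises (nearest inch, nearest pound);
the truth tables store the quantised canonical value so harmonisation can
be held to exact equality.

Defects are injected at configured rates and logged cell-by-cell:
duplicated maternity rows, per-pregnancy (first-twin-only) reporting,
out-of-window event dates, implausible values strictly outside the
consensus limits, and affirmative-only blanking of recorded negatives.
Missingness is MCAR or MAR; MAR follows
`logit(p) = logit(rate) + site_shift + β·z(driver)` with the coefficients
recorded in the truth object so tests can recompute expected rates. The
default site shift is +0.5 and the default driver slope β = 0.5 — a
moderate, realistic selection strength. A MAR driver must be an observed
variable: two variables whose missingness drives each other are jointly
missing-not-at-random, which no MAR-based method should be expected to
undo (the test suite's recovery cohort therefore uses MCAR height and
weight MAR-on-height).

What the generator does **not** emulate: clinically realistic joint
distributions beyond what the pipeline needs (no parity–age structure, no
seasonality, no site case-mix differences), free-text noise beyond fixed
vocabularies, or intervention effects. Passing tests therefore demonstrate
the pipeline's correctness contracts, not clinical realism.

## Harmonisation

The data dictionary has one row per (harmonised variable, site); names
follow `<source>_<stage>_<name>` with source `mat`/`neo`/`uss`/`act` and
stage `r` (raw), `h` (harmonised), `c` (calculated) — e.g. `mat_r_height`,
`mat_h_height`, `mat_c_bmi`. The loader validates the nomenclature, the
category closure of every recode map, and duplicate entries.

The engine (`harmonise_bundle()`) realises each entry: unit conversion
(feet-and-inches, stones-and-pounds, centimetres, the three gestational-age
renderings, the three date formats), many-to-one category recoding, the two
binary-missingness rules (affirmative-only sources have missing set to the
explicit negative; full sources keep missing), any-positive multi-source
merging (used for epidural recorded in either the labour or the birth
analgesia field), and calculated variables (BMI to 2 d.p. from harmonised
weight and height). Three contracts are enforced by tests:

* **Raw retention** — every single-source harmonised column has an `_r_`
  twin holding the untouched raw values.
* **Idempotence** — the engine on its own output is a no-op.
* **Audit completeness** — every change is appended to an audit trail, and
  replaying the trail on the raw input reproduces the engine output
  bit-for-bit.

Unmapped raw categories become missing but are logged distinctly from true
missingness. The "missing ≈ negative when prevalence matches external
audit" situation is an analysis-time decision, not an imputation, and is
left to the analyst. A variable with no raw source at a site is emitted
fully missing and reported, which is exactly how site-level gaps surface in
the quality reports.

## Linkage

Linkage is deterministic, within site, and uses three rules on the
harmonised tables:

1. Episodes: per woman, distinct delivery dates in ascending order receive
   suffixes `_1, _2, …`; rows sharing a delivery date (multiple births)
   share an episode.
2. Neonatal records attach to the episode with the same study identifier
   whose delivery date lies within 7 days of the neonatal date of birth.
3. Ultrasound and activity events attach to the episode whose pregnancy
   window contains the event date, with the window `[EDC, DOD]` and
   EDC = delivery date − gestational age + 14 days, all in exact calendar
   arithmetic on completed days. Postnatal events never link.

Both interval endpoints are inclusive — "between conception and delivery"
is ambiguous, and the closed interval lets a scan or admission on the day
of delivery count. Ties (an event date in two windows, or a neonatal date
within 7 days of two deliveries) are data errors; they resolve
deterministically (latest conception date; smallest date difference then
earlier episode) and are logged as ambiguous. Within a twin episode a
neonatal row picks its baby row by sex match, then nearest birthweight,
then first unclaimed row. The engine is held equal, row for row, to
brute-force all-pairs oracles on synthetic sites.

## Quality checks and outliers

The first-download checklist runs seven checks: dataset presence, duplicate
study identifiers (classified as multiple births vs true duplicates, with
the ultrasound fetal count overriding toward singleton), cross-dataset
identifier matching, presence of requested variables, completeness,
distribution summaries (range, median, 5th/25th/75th/95th centiles, linear
interpolation between order statistics — the convention is stated in the
report), and date ranges against the requested window (event tables may
legitimately predate the window by up to 300 days of pregnancy). The
second-download checklist re-evaluates the first download's failures and
runs the focused duplicate, key-variable completeness, distribution,
categorical-value and date-range checks. Problems are report content, never
exceptions.

Outlier handling is two-staged, mirroring clinical practice: screening
(±3/4/5 sample SDs, 1st/99th centiles) only *highlights* candidates;
conversion to missing happens solely under the consensus limits —
age 13–60 y, height 1.20–2.00 m (canonical metres, though the consensus
table is conventionally printed in centimetres), weight 30–200 kg,
BMI 13–70, blood loss 1–15,000 mL, birthweight 100–6,000 g. "Outside" is
strict, so boundary values survive; the operation is idempotent and never
alters a retained value.

## Multiple imputation

The chained-equations engine produces *m* = 10 completed datasets by
default. Conditional models per variable type: linear regression with
predictive mean matching (type-0 matching, 5 donors) for continuous
variables, the same with rounding and a floor of zero for ordinal counts,
logistic draws for binaries, multinomial draws for categories. Ten
burn-in cycles per imputation; each (imputation, cycle, variable, site)
tuple draws from its own deterministically derived random stream, which
gives two properties worth having in a cluster trial: exact
reproducibility under a seed, and *site isolation* — for a within-cluster
variable, permuting one site's rows can never change another site's
imputed values.

Variables are scoped **within cluster** by default (site characteristics
differ); variables that some site cannot supply at all (parity at the
binary-parity dialect; height and weight in the trial this mirrors) must be
scoped **across clusters** — a within-cluster variable that is 100% missing
in any site is a hard error naming the variable and site, not a silent
fallback. Across-cluster fits pool all sites and exclude the site factor
from the design (a site with no observed rows would make the site contrast
rank-deficient).

The three-category primary outcome (SGA detected antenatally / SGA not
detected / not SGA) participates in the chains like any other variable, so
other variables can borrow strength from it; but the outcome used for
analysis is recomputed in every completed dataset from its imputed
components through the pluggable centile function, overwriting the chained
draw. Finally, the parity rule: at sites that report only a
nulliparous/multiparous flag, an imputed parity of zero for a known
multiparous woman is replaced by the pre-specified value one.

Summary pooling for the observed-vs-imputed comparison tables is a simple
average of per-imputation statistics (median, IQR, category percentages);
Rubin's-rules inference pooling is out of scope because the package stops
at the data resource, before effect estimation.

## Numerical and degenerate-input choices

* Percentiles: linear interpolation (R type 7) everywhere, stated in
  reports.
* Dates: ISO, DD/MM/YYYY and spreadsheet serial (days since 1899-12-30)
  are all accepted; unparseable dates become missing.
* Gestational-age strings: `"40+2"` → 282; decimal values below 50 are
  weeks (×7, rounded); values ≥ 50 are already days.
* BMI is rounded to 2 d.p.; non-positive height gives missing BMI plus an
  audit note.
* Empty maternity spine: all satellite rows drop, with a warning. Missing
  delivery dates: rows are flagged unlinkable and excluded from episode
  numbering. All-missing columns yield empty distribution summaries,
  flagged.
* PMM donor search uses a sorted-prediction window, so imputation is
  O(n log n) per variable per cycle.

## Problem sizes

The test suite runs the generator at 120–2,000 women per site and the
imputation-recovery study at 5,000 women (two sites, m = 10, ten cycles);
the collision simulation runs at the full 100,000. These sizes were chosen
so the whole suite completes in a few minutes on one CPU while keeping
every binomial/Monte-Carlo check well-powered.

## Known limitations

* The pseudonymisation algorithm is this package's own design satisfying
  the published contract (deterministic, salted, 20 characters, check
  character, collision-free at 10^5); the original trial tool's internal
  algorithm was deliberately never published, and no attempt is made to
  reproduce it or its intermediate refinement rounds.
* The bundled dictionary covers the three synthetic dialects, not any real
  hospital system; real deployments must supply their own dictionary rows
  in the same schema.
* The centile function is a synthetic stand-in; analyses of real data need
  the external customised-centile implementation plugged in.
* Writers emit CSV; XLSX is supported on the read side (via readxl).
* The imputation engine targets this pipeline's structure (scoping,
  outcome recomputation, parity rule) rather than full generality: no
  passive imputation, no interactions beyond what the predictor columns
  encode, no inference pooling.
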