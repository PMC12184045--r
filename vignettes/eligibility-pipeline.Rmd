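---
title: "Methods: autopsy-anchored eligibility screening for amyloid immunotherapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autopsy-anchored eligibility screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amyelig)
```

# Scope and model

`amyelig` estimates, in a cohort with both clinical baseline data and
post-mortem neuropathology, who would have been eligible for treatment with
aducanumab, lecanemab or donanemab under the respective phase-3 trial or
appropriate-use-recommendation (AUR) criteria. The pipeline is purely
descriptive — a deterministic rule cascade, no inferential statistics — and
every probabilistic statement in this package concerns its *synthetic*
cohort generator, never a patient.

The cascade has five stages, applied in reporting order:

1. *Base population*: the amnestic AD syndrome at baseline — global CDR 0.5
   (MCI) or 1 (mild dementia), memory-box impairment at or above a
   threshold, and a clinician etiologic AD diagnosis. All
   "% of the full sample" percentages use this set as denominator; the
   package encodes that as a named denominator (`full_sample`) so the
   autopsy cohort size can never silently take its place.
2. *Clinical inclusion rules* (age, MMSE, CDR windows) per criteria profile.
3. *Amyloid step*: amyloid positivity defined from the autopsy Thal phase,
   either as Thal 3–5 (the PET-equivalent definition; imaging–autopsy
   correlation studies place the PET detection threshold at about Thal 3)
   or Thal > 0 (any amyloid, a sensitivity definition). The two modes are
   nested: PET-equivalent positivity implies any-amyloid positivity, so
   widening the definition can only add participants.
4. *Tau step* (optional): intermediate tau spread, Braak 3–4. Disabled by
   default in every bundled profile: tau spreads during the symptomatic
   years between baseline and autopsy, so a Braak 3–4 requirement *at
   autopsy* mostly measures time-to-death, not baseline eligibility. The
   step remains switchable for sensitivity analyses.
5. *Exclusion rules* (comorbidity/medication flags).

The amyloid and tau steps are dedicated stages rather than ordinary rules so
that funnel counts align with the conventional reporting order
(inclusion → amyloid → eligible).

## ABC staging

Neuropathologic AD change is staged with the NIA-AA ABC score: A bins the
Thal amyloid phase (0→0, 1–2→1, 3→2, 4–5→3), B bins the Braak
neurofibrillary-tangle stage (0→0, 1–2→1, 3–4→2, 5–6→3), C is the CERAD
neuritic plaque score. The three scores combine through a 64-cell lookup
matrix into *not / low / intermediate / high*; *intermediate* and *high*
are interpreted as full AD pathology. The matrix ships as an editable CSV
(`inst/extdata/abc_matrix.csv`), transcribed from the staging guideline and
extended to all 64 cells (the guideline's A0 row lists only C0, since no
amyloid implies no neuritic plaques; all A0 cells are "not"). The loader
revalidates completeness, the A0 rule, and three-way monotonicity on every
load, so a locally edited matrix cannot silently break the invariants. A
useful consistency consequence: PET-equivalent amyloid positivity (Thal ≥ 3)
forces A ≥ 2, hence an eligible participant can never be staged "not".

## Missing data

Staging and positivity functions propagate `NA`; nothing is imputed.
Resolution happens only in the eligibility engine via `missing_policy`:
under `fail_closed` (default) an unevaluable rule or step counts against the
participant — an inclusion criterion that cannot be confirmed, or an
exclusion that cannot be ruled out, keeps them out, mirroring selection of
participants with *documented* findings. `fail_open` treats unevaluable as
pass and exists for sensitivity analysis. The syndrome classifier is always
fail-closed (`missing_data` is reported as a failed component).

# Design choices where the design was open

* **Memory-impairment threshold.** "At least mild memory impairment" is
  ambiguous between memory box ≥ 0.5 and ≥ 1. The default is 0.5
  (questionable-or-worse), because CDR-global-0.5 participants typically
  carry a 0.5 memory box and must be includable; the threshold is a
  parameter of `classify_syndrome()`, and raising it provably never adds
  base members (property-tested).
* **Criteria content is data, not code.** The exact operationalization of
  each trial's criteria against any given source dataset is
  dataset-specific. The bundled JSON profiles encode the publicly known
  windows — EMERGE/ENGAGE: age 50–85, MMSE 24–30, CDR = 0.5;
  CLARITY-AD: age 50–90, MMSE 22–30, CDR ∈ {0.5, 1}; TRAILBLAZER-ALZ 2:
  age 60–85, MMSE 20–28, CDR ∈ {0.5, 1}; the AUR variants relax the
  aducanumab CDR restriction — plus generic comorbidity/medication
  exclusions, each rule carrying a provenance label. They are labelled
  best-effort stand-ins; the engine's correctness is established on fixture
  profiles independent of the bundled content. MRI-dependent exclusions
  (microhemorrhages, siderosis) are representable in the rule schema but
  deliberately absent from the bundled profiles, since such variables are
  typically unavailable in harmonized clinical datasets.
* **Percentage rounding.** Integer percent, halves away from zero. Every
  printed pair checked in the acceptance suite is consistent with this
  convention (none distinguishes it from half-even), so the simpler rule is
  fixed. A zero denominator yields an undefined-percent marker (`NA`),
  never an error.
* **Co-pathology denominators.** Not-reported states stay in the
  denominator and out of the numerator (missingness in such reports is
  typically ≤ 2 %); `complete_case = TRUE` switches to reported-only
  denominators for sensitivity.
* **Euler output.** Exact region counts by membership signature; rendering
  an area-proportional diagram is out of scope. The counts satisfy two
  invariants — regions partition the union, and per-set marginals are
  recovered — both property-tested against a brute-force oracle.
* **Trace stages.** A profile with the tau step enabled can fail at a stage
  that is neither amyloid nor exclusion; traces therefore use five
  `stage_reached` levels (`failed_inclusion`, `failed_amyloid`,
  `failed_tau`, `failed_exclusion`, `eligible`).

# The synthetic cohort generator

The generator emulates the *joint* clinical–neuropathological structure the
analysis depends on; it never claims to reproduce any real cohort's absolute
counts.

A participant is drawn from a two-component mixture: "affected" (latent AD,
weight 0.55 — autopsy research cohorts are heavily AD-enriched) or
"unaffected". A single latent severity scalar (affected ~ N(3.2, 1),
unaffected ~ N(−0.3, 1)) drives Thal, Braak and CERAD through monotone
threshold maps with independent ±1 ordinal jitter (probability 0.12 each
way). This single-factor construction was chosen over independent marginals
because the facts the pipeline must reproduce — roughly 90 % amyloid
positivity among clinical includees and ≥ 95 % (empirically 98–99 %)
full-AD-pathology among amyloid-positive eligibles — require strongly
positively dependent Thal/Braak/CERAD. It also yields, as a testable side
effect, mean Braak and CERAD that are non-decreasing in Thal phase, and the
realistic consequence that eligible participants are predominantly Braak
5–6 at autopsy (which is why the tau step, when enabled, eliminates most of
them).

Clinical variables are conditioned on the mixture component: CDR level
distributions (affected participants concentrate at CDR 0.5–1), memory-box
distributions given CDR (unaffected impairment spares memory more often),
an etiologic AD diagnosis for 88 % of impaired affected vs 15 % of impaired
unaffected participants (clinical misdiagnosis), MMSE ~ N(mean | CDR, 2.5)
rounded and clamped to [0, 30], age ~ N(73, 8) clamped to [50, 100], 52 %
female. Comorbidity/medication exclusion flags and the seven co-pathology
flags are independent Bernoulli draws; co-pathology defaults (Lewy body
0.52, hippocampal sclerosis 0.18, infarcts/lacunes 0.11, old hemorrhages
0.02, FTLD-tau 0.05, Pick's 0.005, other tauopathy 0.03, not-reported rate
0.015) match prevalences typical of amyloid-positive autopsy series. The
exclusion-flag rates are illustrative: they produce a realistic aggregate
exclusion-stage attrition (~25–30 %), but no per-criterion attrition is
claimed.

**Calibration.** The configuration declares
`target_p_amyloid_given_inclusion = 0.90`. The structural defaults
(mixture means, the Thal-phase-3 threshold at severity 1.35, the
misdiagnosis rate) were set once so that the realized
P(Thal ≥ 3 | clinical inclusion) at n = 20,000 is within 3 binomial SE of
0.90 for every bundled profile, and then frozen. `calibration_report()`
recomputes realized-vs-configured values with 3-SE tolerances at any time.

**What a green test does not establish.** The generator has no longitudinal
progression (no tau spread between baseline and autopsy — death-date and
baseline-date are decorative), no mortality or selection-into-autopsy
model, no severity-linked co-pathologies (a hook exists in the design but
the default is independence), and no missing data by default (tests inject
missingness explicitly). Green acceptance tests therefore validate the
*engine* and the *calibration machinery*, not any real-world eligible-patient
count: absolute counts from access-controlled cohorts are out of reach by
construction, and the acceptance suite substitutes property-based
guarantees (funnel monotonicity, amyloid-mode containment, CDR purity of
the aducanumab-trial set, Euler-oracle equality, ABC-matrix invariants).

# Numerical and degenerate-input conventions

* Ordinal inputs are validated (`stop()`) when out of range and propagated
  when `NA`; tri-state co-pathology flags treat `not_reported` as missing
  for rule evaluation.
* Rule `range` predicates default to closed ends; `lo > hi` is rejected at
  construction.
* Rules within a phase are order-insensitive for the eligible set
  (property-tested); only trace ordering follows profile order.
* Non-monotone funnel counts in `build_funnel_report()` are a hard error by
  design: they can only arise from an engine bug, never from data.
* Cohort I/O round-trips exactly, including missing values (configurable
  missing token, default empty field); value decoding for source dialects
  (e.g. numeric missing codes) lives entirely in the codebook.

# Known limitations

* Bundled profiles approximate trial criteria that were never fully
  itemized in machine-readable form; users analysing real data should
  review and edit them.
* The comorbidity/medication flag vocabulary is open-ended by design;
  profiles and codebooks must agree on flag names.
* `fail_closed` makes eligibility estimates conservative in proportion to
  missingness; with heavily incomplete data the fail_closed/fail_open gap
  should be reported, not just the default.
* The single-severity-factor generator cannot represent discordant
  amyloid/tau profiles (e.g. primary age-related tauopathy); it is a test
  harness, not a disease model.
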