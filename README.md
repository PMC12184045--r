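# amyelig

Eligibility screening for amyloid-targeting immunotherapies (aducanumab,
lecanemab, donanemab) from joint clinical baseline and post-mortem
neuropathology records.

## The problem

Amyloid-beta antibodies are indicated for *early symptomatic* Alzheimer's
disease, and each compound's phase-3 trial and appropriate use
recommendations (AUR) define eligibility differently. Estimating how many
patients in a real-world cohort would qualify — and how the eligible groups
for the different antibodies overlap — requires chaining several
operationalizations:

1. **Amnestic AD syndrome** at baseline: global CDR ∈ {0.5, 1} (MCI or mild
   dementia), at least mild memory impairment on the CDR memory box, and a
   clinician etiologic AD diagnosis. This set is the *full sample*
   denominator for all percentages.
2. **Clinical inclusion criteria** per antibody (age, MMSE and CDR windows).
3. **Amyloid positivity** anchored in autopsy: Thal phase 3–5 is treated as
   equivalent to a positive amyloid PET in life (`pet_equivalent`); Thal > 0
   is the any-amyloid sensitivity definition (`any_amyloid`).
4. Optionally, **intermediate tau spread** (Braak stage 3–4).
5. **Exclusion criteria** (comorbidities, medications).

Neuropathologic AD is staged with the NIA-AA **ABC score**: A from Thal
phase (0→0, 1–2→1, 3→2, 4–5→3), B from Braak stage (0→0, 1–2→1, 3–4→2,
5–6→3), C = the CERAD neuritic plaque score (0–3), combined by a 64-cell
lookup matrix into *not / low / intermediate / high* AD neuropathologic
change; *intermediate/high* counts as full AD pathology.

`amyelig` implements this pipeline as a declarative rule engine with a
per-rule audit trail, plus funnel, Euler-overlap and co-pathology analytics,
and a calibrated synthetic cohort generator so everything is testable
without access-controlled patient data.

## Worked example

```r
library(amyelig)

cfg    <- synthetic_cohort_config(n = 20000, seed = 1)
cohort <- generate_cohort(cfg)
base   <- base_population(cohort)          # amnestic AD syndrome at baseline
length(base)
#> [1] 6559

profile <- load_profile("clarity_ad_lecanemab")
counts  <- funnel_counts(profile, cohort, base)
build_funnel_report(counts, c(full_sample = length(base)))
#>       stage count pct_of_previous pct_of_full_sample
#> 1      base  6559              NA                100
#> 2 inclusion  5377              82                 82
#> 3   amyloid  4848              90                 74
#> 4  eligible  3502              72                 53
```

Reading: 5377 base members pass the trial's clinical inclusion window, 90 %
of those are amyloid positive (Thal 3–5 at autopsy; the generator is
calibrated to 0.90), and 3502 (53 % of the full sample) survive the
exclusion criteria. Per-participant audit trails come from
`apply_profile()`; `euler_regions()` gives exact region counts for the
overlap of eligible sets; `copathology_prevalence()`, `cdr_composition()`
and `full_ad_pathology_share()` reproduce the standard descriptive tables.
Five criteria profiles ship as editable JSON
(`bundled_profiles()`): the three phase-3 trials and the aducanumab and
lecanemab AUR — best-effort stand-ins for criteria that are configurable
data, not code.

A command-line front end lives at `inst/cli/amyelig`
(`validate`, `classify-syndrome`, `select`, `funnel`, `overlap`,
`copathology`, `generate`, `report`).

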