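Package: amyelig
Title: Eligibility Screening for Amyloid-Targeting Immunotherapies from
    Joint Clinical and Neuropathology Records
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A rule engine and analytics toolkit for estimating patient
    eligibility for amyloid-beta targeting antibodies (aducanumab,
    lecanemab, donanemab) from harmonized clinical baseline records joined
    with post-mortem neuropathology reports. Implements amnestic
    Alzheimer's disease syndrome classification from Clinical Dementia
    Rating scores, NIA-AA ABC neuropathologic staging (Thal phase, Braak
    stage, CERAD neuritic plaque score), Thal-phase based amyloid-PET
    equivalence, declarative trial and appropriate-use-recommendation
    criteria profiles with per-rule audit trails, selection-funnel and
    Euler-overlap reporting, co-pathology prevalence tables, and a
    calibrated synthetic cohort generator emulating the joint structure of
    clinical/autopsy research datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
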