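# Fixture builders shared across test files. Everything is built in code;
# nothing is read from disk except package-installed config files.

make_clinical <- function(id, age = 72L, sex = "female", mmse = 26L,
                          cdr = 0.5, mem = 0.5, dx = TRUE,
                          anticoag = FALSE, stroke = FALSE) {
  data.frame(participant_id = id, age_years = age, sex = sex, mmse = mmse,
             cdr_global = cdr, cdr_memory_box = mem, etiologic_ad_dx = dx,
             baseline_date = as.Date("2010-01-01"),
             comorbidity_stroke_or_tia = stroke,
             medication_anticoagulant_use = anticoag,
             stringsAsFactors = FALSE)
}

make_neuropath <- function(id, thal = 4L, braak = 5L, cerad = 3L,
                           lewy = "absent") {
  data.frame(participant_id = id, thal_phase = thal, braak_stage = braak,
             cerad_score = cerad, death_date = as.Date("2016-01-01"),
             copath_lewy_body = lewy, stringsAsFactors = FALSE)
}

make_cohort <- function(n = 3, ...) {
  ids <- paste0("P", seq_len(n))
  new_cohort(make_clinical(ids, ...), make_neuropath(ids), "fixture")
}

# The 6-record engine fixture with hand-computed expectations (see
# test-eligibility.R for the trace-by-trace derivation).
make_engine_fixture <- function() {
  cl <- rbind(
    make_clinical("P1", mmse = 26L, cdr = 0.5),
    make_clinical("P2", mmse = 20L, cdr = 0.5),
    make_clinical("P3", mmse = 25L, cdr = 1),
    make_clinical("P4", mmse = 28L, cdr = 0.5, anticoag = TRUE),
    make_clinical("P5", mmse = 24L, cdr = 2),
    make_clinical("P6", mmse = 30L, cdr = 1)
  )
  np <- rbind(
    make_neuropath("P1", thal = 4L),
    make_neuropath("P2", thal = 5L),
    make_neuropath("P3", thal = 2L),
    make_neuropath("P4", thal = 5L),
    make_neuropath("P5", thal = 4L),
    make_neuropath("P6", thal = 3L)
  )
  new_cohort(cl, np, "engine-fixture")
}

make_toy_profile <- function(amyloid_mode = "pet_equivalent",
                             tau_rule_enabled = FALSE,
                             inclusion = NULL, exclusion = NULL) {
  if (is.null(inclusion)) inclusion <- list(
    criterion_rule("mmse_window", "inclusion", "mmse",
                   list(type = "range", lo = 22, hi = 30)),
    criterion_rule("cdr_stage", "inclusion", "cdr_global",
                   list(type = "in_set", values = c(0.5, 1)))
  )
  if (is.null(exclusion)) exclusion <- list(
    criterion_rule("no_anticoagulants", "exclusion",
                   "medication_flags.anticoagulant_use",
                   list(type = "flag_false"))
  )
  criteria_profile("toy", inclusion, exclusion, amyloid_mode,
                   tau_rule_enabled)
}

# One default-config cohort at calibration scale, generated once per run.
big_cohort_cache <- new.env()
get_big_cohort <- function() {
  if (is.null(big_cohort_cache$cohort)) {
    big_cohort_cache$config <- synthetic_cohort_config(n = 20000, seed = 1)
    big_cohort_cache$cohort <- generate_cohort(big_cohort_cache$config)
  }
  big_cohort_cache
}
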