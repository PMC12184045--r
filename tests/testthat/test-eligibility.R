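test_that("rule construction validates predicates and field paths", {
  expect_error(criterion_rule("r", "inclusion", "mmse",
                              list(type = "range", lo = 30, hi = 24)),
               "lo <= hi")
  expect_error(criterion_rule("r", "inclusion", "nonsense_field",
                              list(type = "flag_true")), "unknown field_path")
  expect_error(criterion_rule("r", "inclusion", "mmse",
                              list(type = "between")), "predicate type")
  expect_error(criterion_rule("r", "inclusion", "mmse",
                              list(type = "in_set", values = numeric(0))),
               "non-empty")
  r <- criterion_rule("ok", "exclusion", "comorbidity_flags.seizures",
                      list(type = "flag_false"))
  expect_s3_class(r, "amyelig_rule")
})

test_that("bundled profiles load with the expected CDR scope", {
  expect_setequal(bundled_profiles(),
                  c("emerge_engage_aducanumab", "clarity_ad_lecanemab",
                    "trailblazer_alz2_donanemab", "aur_aducanumab",
                    "aur_lecanemab"))
  lec <- load_profile("clarity_ad_lecanemab")
  cdr_rule <- Filter(function(r) r$rule_id == "cdr_stage", lec$inclusion_rules)[[1]]
  expect_identical(cdr_rule$predicate$type, "in_set")
  expect_setequal(cdr_rule$predicate$values, c(0.5, 1))

  adu <- load_profile("emerge_engage_aducanumab")
  cdr_rule <- Filter(function(r) r$rule_id == "cdr_stage", adu$inclusion_rules)[[1]]
  expect_identical(cdr_rule$predicate$type, "equals")
  expect_identical(cdr_rule$predicate$value, 0.5)
  # donanemab's tau step is representable but off by default
  expect_false(load_profile("trailblazer_alz2_donanemab")$tau_rule_enabled)
  expect_error(load_profile("no_such_profile"), "bundled profiles")
})

test_that("evaluate_rule: predicates, boundaries, unevaluable on missing", {
  rec <- joined_records(make_cohort(1))
  rng <- criterion_rule("m", "inclusion", "mmse",
                        list(type = "range", lo = 22, hi = 30))
  expect_identical(evaluate_rule(rng, rec), "pass")     # mmse = 26
  rec2 <- rec; rec2$mmse <- 22L
  expect_identical(evaluate_rule(rng, rec2), "pass")    # closed lower end
  rec2$mmse <- 21L
  expect_identical(evaluate_rule(rng, rec2), "fail")
  rec2$mmse <- NA_integer_
  expect_identical(evaluate_rule(rng, rec2), "unevaluable")

  excl <- criterion_rule("a", "exclusion", "medication_flags.anticoagulant_use",
                         list(type = "flag_false"))
  rec3 <- rec; rec3$medication_anticoagulant_use <- TRUE
  expect_identical(evaluate_rule(excl, rec3), "fail")
  expect_identical(evaluate_rule(excl, rec), "pass")

  copa <- criterion_rule("l", "exclusion", "copathology_flags.lewy_body",
                         list(type = "flag_false"))
  rec4 <- rec; rec4$copath_lewy_body <- "not_reported"
  expect_identical(evaluate_rule(copa, rec4), "unevaluable")
})

test_that("6-record fixture reproduces the hand-computed traces and funnel", {
  # Hand evaluation under the toy profile (mmse 22-30, cdr {0.5,1}; amyloid
  # pet-equivalent Thal>=3; exclusion: no anticoagulants):
  #   P1 mmse26 cdr0.5 thal4 -> eligible
  #   P2 mmse20            -> failed_inclusion (mmse_window)
  #   P3 thal2             -> failed_amyloid
  #   P4 anticoagulant     -> failed_exclusion
  #   P5 cdr2              -> failed_inclusion (cdr_stage)
  #   P6 mmse30 cdr1 thal3 -> eligible
  co <- make_engine_fixture()
  prof <- make_toy_profile()
  base <- cohort_ids(co)
  res <- apply_profile(prof, co, base)
  expect_identical(res$traces$stage_reached,
                   c("eligible", "failed_inclusion", "failed_amyloid",
                     "failed_exclusion", "failed_inclusion", "eligible"))
  expect_identical(res$eligible, c("P1", "P6"))
  expect_identical(res$traces$failing_rule_ids,
                   c("", "mmse_window", "amyloid_step", "no_anticoagulants",
                     "cdr_stage", ""))
  expect_identical(funnel_counts(prof, co, base),
                   c(base = 6L, inclusion = 4L, amyloid = 3L, eligible = 2L))
})

test_that("zero-rule profile with any_amyloid keeps every Thal>=1 base member", {
  prof <- criteria_profile("vacuous", amyloid_mode = "any_amyloid")
  co <- make_cohort(4)  # all thal 4
  res <- apply_profile(prof, co, cohort_ids(co))
  expect_identical(res$eligible, cohort_ids(co))
  counts <- funnel_counts(prof, co, cohort_ids(co))
  expect_true(all(counts == 4L))
})

test_that("fail_closed vs fail_open differ by exactly the missing-data case", {
  co <- make_engine_fixture()
  co$clinical$mmse[6] <- NA_integer_   # P6 otherwise eligible
  prof <- make_toy_profile()
  base <- cohort_ids(co)
  closed <- apply_profile(prof, co, base, "fail_closed")
  open <- apply_profile(prof, co, base, "fail_open")
  expect_identical(setdiff(open$eligible, closed$eligible), "P6")
  expect_identical(closed$eligible, "P1")
  # under fail_closed the unevaluable inclusion rule is the named failure
  tr6 <- closed$traces[closed$traces$participant_id == "P6", ]
  expect_identical(tr6$stage_reached, "failed_inclusion")
  expect_identical(tr6$failing_rule_ids, "mmse_window")
})

test_that("tau step gates eligibility only when enabled", {
  co <- make_engine_fixture()  # braak 5 everywhere
  prof_off <- make_toy_profile()
  prof_on <- make_toy_profile(tau_rule_enabled = TRUE)
  base <- cohort_ids(co)
  expect_identical(apply_profile(prof_off, co, base)$eligible, c("P1", "P6"))
  res_on <- apply_profile(prof_on, co, base)
  expect_identical(res_on$eligible, character(0))
  expect_true(all(res_on$traces$stage_reached[
    res_on$traces$participant_id %in% c("P1", "P6")] == "failed_tau"))
  co$neuropath$braak_stage[1] <- 4L
  expect_identical(apply_profile(prof_on, co, base)$eligible, "P1")
  counts <- funnel_counts(prof_on, co, base)
  expect_identical(names(counts),
                   c("base", "inclusion", "amyloid", "tau", "eligible"))
  expect_true(all(diff(counts) <= 0))
})

test_that("permuting rules within a phase never changes the eligible set", {
  set.seed(21)
  co <- generate_cohort(synthetic_cohort_config(n = 300, seed = 21))
  base <- base_population(co)
  prof <- load_profile("clarity_ad_lecanemab")
  ref <- apply_profile(prof, co, base)$eligible
  for (i in 1:3) {
    perm <- prof
    perm$inclusion_rules <- sample(perm$inclusion_rules)
    perm$exclusion_rules <- sample(perm$exclusion_rules)
    expect_setequal(apply_profile(perm, co, base)$eligible, ref)
  }
})

test_that("widening the amyloid definition only adds participants", {
  co <- generate_cohort(synthetic_cohort_config(n = 500, seed = 5))
  base <- base_population(co)
  for (id in bundled_profiles()) {
    pet <- load_profile(id)
    any <- pet; any$amyloid_mode <- "any_amyloid"
    e_pet <- apply_profile(pet, co, base)$eligible
    e_any <- apply_profile(any, co, base)$eligible
    expect_true(all(e_pet %in% e_any))
    c_pet <- funnel_counts(pet, co, base)
    c_any <- funnel_counts(any, co, base)
    expect_true(all(c_any[c("amyloid", "eligible")] >=
                      c_pet[c("amyloid", "eligible")]))
  }
})

test_that("base must be a subset of the cohort and reserved ids are rejected", {
  co <- make_cohort(2)
  expect_error(apply_profile(make_toy_profile(), co, c("P1", "ZZ")),
               "not in the cohort")
  expect_error(criteria_profile("p", inclusion_rules = list(
    criterion_rule("amyloid_step", "inclusion", "mmse",
                   list(type = "range", lo = 0, hi = 30)))), "reserved")
})
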