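## Declarative eligibility criteria and their application with a per-rule
## audit trail. Criteria content is data, not code: bundled profiles encode
## best-effort stand-ins for the phase-3 trial and AUR windows and can be
## edited; the engine itself is criteria-agnostic.

PREDICATE_TYPES <- c("equals", "in_set", "range", "flag_true", "flag_false")

known_field_paths <- function() {
  c("age_years", "sex", "mmse", "cdr_global", "cdr_memory_box",
    "etiologic_ad_dx", "thal_phase", "braak_stage", "cerad_score")
}

#' Construct a criterion rule
#'
#' One atomic inclusion or exclusion criterion: a predicate over a single
#' canonical field. Exclusion-phase rules are phrased as conditions that must
#' hold for the participant to stay in (e.g. `flag_false` on
#' `medication_flags.anticoagulant_use`).
#'
#' @param rule_id unique id within a profile.
#' @param phase "inclusion" or "exclusion".
#' @param field_path canonical field name, or a namespaced flag such as
#'   `comorbidity_flags.stroke_or_tia`, `medication_flags.anticoagulant_use`,
#'   `copathology_flags.lewy_body`.
#' @param predicate list with element `type` in equals/in_set/range/flag_true/
#'   flag_false, plus `value` (equals), `values` (in_set), or `lo`/`hi` with
#'   optional `closed_lo`/`closed_hi` (range; default closed ends).
#' @param provenance free-text citation label.
#' @return object of class `amyelig_rule`.
#' @export
criterion_rule <- function(rule_id, phase, field_path, predicate,
                           provenance = "") {
  phase <- match.arg(phase, c("inclusion", "exclusion"))
  if (!is.list(predicate) || is.null(predicate$type) ||
      !predicate$type %in% PREDICATE_TYPES)
    stop("rule '", rule_id, "': predicate type must be one of ",
         paste(PREDICATE_TYPES, collapse = "/"))
  ok_path <- field_path %in% known_field_paths() ||
    grepl("^(comorbidity_flags|medication_flags|copathology_flags)\\.[a-z0-9_]+$",
          field_path)
  if (!ok_path) stop("rule '", rule_id, "': unknown field_path '", field_path, "'")
  if (predicate$type == "range") {
    if (is.null(predicate$lo) || is.null(predicate$hi) ||
        predicate$lo > predicate$hi)
      stop("rule '", rule_id, "': range predicate requires lo <= hi")
    if (is.null(predicate$closed_lo)) predicate$closed_lo <- TRUE
    if (is.null(predicate$closed_hi)) predicate$closed_hi <- TRUE
  }
  if (predicate$type == "equals" && is.null(predicate$value))
    stop("rule '", rule_id, "': equals predicate requires a value")
  if (predicate$type == "in_set" &&
      (is.null(predicate$values) || length(predicate$values) == 0))
    stop("rule '", rule_id, "': in_set predicate requires a non-empty set")
  structure(list(rule_id = rule_id, phase = phase, field_path = field_path,
                 predicate = predicate, provenance = provenance),
            class = "amyelig_rule")
}

#' Construct a criteria profile
#'
#' A named, declarative criteria set: ordered inclusion rules, an amyloid
#' positivity mode, an optional intermediate-tau-spread step, and ordered
#' exclusion rules, applied in that order by [apply_profile()].
#'
#' @param profile_id unique profile id.
#' @param inclusion_rules,exclusion_rules lists of [criterion_rule()]s with
#'   the matching phase.
#' @param amyloid_mode "pet_equivalent" (Thal 3-5) or "any_amyloid" (Thal > 0).
#' @param tau_rule_enabled if TRUE, participants must additionally show
#'   intermediate tau spread (Braak 3-4). Default FALSE.
#' @param label,provenance free-text descriptors.
#' @return object of class `amyelig_profile`.
#' @export
criteria_profile <- function(profile_id, inclusion_rules = list(),
                             exclusion_rules = list(),
                             amyloid_mode = c("pet_equivalent", "any_amyloid"),
                             tau_rule_enabled = FALSE, label = profile_id,
                             provenance = "") {
  amyloid_mode <- match.arg(amyloid_mode)
  for (r in inclusion_rules)
    if (!inherits(r, "amyelig_rule") || r$phase != "inclusion")
      stop("inclusion_rules must be inclusion-phase amyelig_rule objects")
  for (r in exclusion_rules)
    if (!inherits(r, "amyelig_rule") || r$phase != "exclusion")
      stop("exclusion_rules must be exclusion-phase amyelig_rule objects")
  ids <- vapply(c(inclusion_rules, exclusion_rules), `[[`, "", "rule_id")
  if (anyDuplicated(ids))
    stop("duplicate rule_id within profile: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(ids %in% c("amyloid_step", "tau_step")))
    stop("rule ids 'amyloid_step' and 'tau_step' are reserved")
  structure(list(profile_id = profile_id, label = label,
                 inclusion_rules = inclusion_rules,
                 exclusion_rules = exclusion_rules,
                 amyloid_mode = amyloid_mode,
                 tau_rule_enabled = isTRUE(tau_rule_enabled),
                 provenance = provenance),
            class = "amyelig_profile")
}

#' @export
print.amyelig_profile <- function(x, ...) {
  cat("<amyelig_profile> ", x$profile_id, " (", x$label, ")\n",
      "  ", length(x$inclusion_rules), " inclusion rules; amyloid mode ",
      x$amyloid_mode, "; tau step ",
      if (x$tau_rule_enabled) "enabled" else "disabled", "; ",
      length(x$exclusion_rules), " exclusion rules\n", sep = "")
  invisible(x)
}

#' Names of the bundled criteria profiles
#' @return character vector of profile ids loadable by [load_profile()].
#' @export
bundled_profiles <- function() {
  dir <- system.file("extdata", "profiles", package = "amyelig")
  sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
}

#' Load a criteria profile from JSON
#'
#' @param id_or_path a bundled profile id (see [bundled_profiles()]) or a path
#'   to a JSON profile file. Malformed predicates, duplicate rule ids, unknown
#'   field paths and unknown top-level keys are hard errors.
#' @return an `amyelig_profile`.
#' @export
load_profile <- function(id_or_path) {
  path <- if (file.exists(id_or_path)) id_or_path else
    system.file("extdata", "profiles", paste0(id_or_path, ".json"),
                package = "amyelig")
  if (!nzchar(path) || !file.exists(path))
    stop("no such profile: '", id_or_path, "'; bundled profiles: ",
         paste(bundled_profiles(), collapse = ", "))
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  allowed <- c("profile_id", "label", "amyloid_mode", "tau_rule_enabled",
               "provenance", "inclusion_rules", "exclusion_rules")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) stop("unknown profile field(s): ",
                          paste(extra, collapse = ", "))
  if (is.null(cfg$profile_id)) stop("profile file lacks profile_id")
  mk <- function(r, phase) {
    pred <- r$predicate
    if (!is.null(pred$values)) pred$values <- unlist(pred$values)
    criterion_rule(r$rule_id, phase, r$field_path, pred,
                   provenance = if (is.null(r$provenance)) "" else r$provenance)
  }
  criteria_profile(
    profile_id = cfg$profile_id,
    inclusion_rules = lapply(cfg$inclusion_rules, mk, phase = "inclusion"),
    exclusion_rules = lapply(cfg$exclusion_rules, mk, phase = "exclusion"),
    amyloid_mode = if (is.null(cfg$amyloid_mode)) "pet_equivalent"
                   else cfg$amyloid_mode,
    tau_rule_enabled = isTRUE(cfg$tau_rule_enabled),
    label = if (is.null(cfg$label)) cfg$profile_id else cfg$label,
    provenance = if (is.null(cfg$provenance)) "" else cfg$provenance
  )
}

resolve_field <- function(record, field_path) {
  col <- if (grepl("^comorbidity_flags\\.", field_path))
    sub("^comorbidity_flags\\.", "comorbidity_", field_path)
  else if (grepl("^medication_flags\\.", field_path))
    sub("^medication_flags\\.", "medication_", field_path)
  else if (grepl("^copathology_flags\\.", field_path))
    sub("^copathology_flags\\.", "copath_", field_path)
  else field_path
  if (!col %in% names(record)) return(NA)
  v <- record[[col]]
  ## tri-state co-pathology: not_reported is missing for rule purposes
  if (grepl("^copath_", col)) {
    v <- as.character(v)
    v <- if (is.na(v) || v == "not_reported") NA else (v == "present")
  }
  v
}

#' Evaluate one rule against one joined participant record
#'
#' @param rule an `amyelig_rule`.
#' @param record one-row data.frame as produced by [joined_records()].
#' @return "pass", "fail", or "unevaluable" (field missing).
#' @export
evaluate_rule <- function(rule, record) {
  v <- resolve_field(record, rule$field_path)
  if (length(v) != 1 || is.na(v)) return("unevaluable")
  p <- rule$predicate
  ok <- switch(p$type,
    equals = isTRUE(all.equal(v, p$value, check.attributes = FALSE)) ||
             identical(as.character(v), as.character(p$value)),
    in_set = any(vapply(p$values, function(s)
      isTRUE(all.equal(v, s, check.attributes = FALSE)) ||
      identical(as.character(v), as.character(s)), logical(1))),
    range = {
      v <- as.numeric(v)
      lo_ok <- if (p$closed_lo) v >= p$lo else v > p$lo
      hi_ok <- if (p$closed_hi) v <= p$hi else v < p$hi
      lo_ok && hi_ok
    },
    flag_true = isTRUE(v),
    flag_false = identical(v, FALSE)
  )
  if (isTRUE(ok)) "pass" else "fail"
}

effective <- function(outcome, missing_policy) {
  ## unevaluable collapses to fail (fail_closed) or pass (fail_open)
  if (outcome != "unevaluable") return(outcome)
  if (missing_policy == "fail_closed") "fail" else "pass"
}

#' Apply a criteria profile to the base population of a cohort
#'
#' Evaluation order mirrors funnel reporting: clinical inclusion rules, then
#' the amyloid-positivity step under the profile's mode, then (if enabled) the
#' intermediate-tau step, then exclusion rules. Every rule is evaluated for
#' every base member so the trace is a complete audit trail; `stage_reached`
#' records the first failing stage.
#'
#' Under `fail_closed` (default) an unevaluable rule or step behaves as a
#' failure — the criterion cannot be confirmed, or the exclusion cannot be
#' ruled out; under `fail_open` both behave as passes.
#'
#' @param profile an `amyelig_profile`.
#' @param cohort an `amyelig_cohort`.
#' @param base character vector of base-population ids (default:
#'   [base_population()] of the cohort).
#' @param missing_policy "fail_closed" or "fail_open".
#' @return list with `traces` (data.frame: participant_id, profile_id,
#'   stage_reached in failed_inclusion/failed_amyloid/failed_tau/
#'   failed_exclusion/eligible, failing_rule_ids comma-separated, plus a
#'   list-column `rule_outcomes`) and `eligible` (character vector of ids).
#' @export
apply_profile <- function(profile, cohort, base = base_population(cohort),
                          missing_policy = c("fail_closed", "fail_open")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(profile, "amyelig_profile"))
  if (!all(base %in% cohort_ids(cohort)))
    stop("base population contains ids not in the cohort")
  rec <- joined_records(cohort, base)
  n <- nrow(rec)

  rule_set <- c(profile$inclusion_rules, profile$exclusion_rules)
  rule_ids <- vapply(rule_set, `[[`, "", "rule_id")

  stage <- character(n)
  failing <- character(n)
  outcomes <- vector("list", n)
  for (i in seq_len(n)) {
    row <- rec[i, , drop = FALSE]
    out <- vapply(rule_set, evaluate_rule, character(1), record = row)
    names(out) <- rule_ids

    amy <- amyloid_positive(row$thal_phase, profile$amyloid_mode)
    out[["amyloid_step"]] <- if (is.na(amy)) "unevaluable"
                             else if (amy) "pass" else "fail"
    if (profile$tau_rule_enabled) {
      tau <- tau_intermediate(row$braak_stage)
      out[["tau_step"]] <- if (is.na(tau)) "unevaluable"
                           else if (tau) "pass" else "fail"
    }
    eff <- vapply(out, effective, character(1), missing_policy = missing_policy)

    incl_ids <- vapply(profile$inclusion_rules, `[[`, "", "rule_id")
    excl_ids <- vapply(profile$exclusion_rules, `[[`, "", "rule_id")
    incl_fail <- incl_ids[eff[incl_ids] == "fail"]
    excl_fail <- excl_ids[eff[excl_ids] == "fail"]
    amy_fail <- eff[["amyloid_step"]] == "fail"
    tau_fail <- profile$tau_rule_enabled && eff[["tau_step"]] == "fail"

    stage[i] <- if (length(incl_fail)) "failed_inclusion"
      else if (amy_fail) "failed_amyloid"
      else if (tau_fail) "failed_tau"
      else if (length(excl_fail)) "failed_exclusion"
      else "eligible"
    fails <- c(incl_fail, if (amy_fail) "amyloid_step",
               if (tau_fail) "tau_step", excl_fail)
    failing[i] <- paste(fails, collapse = ",")
    outcomes[[i]] <- out
  }

  traces <- data.frame(participant_id = rec$participant_id,
                       profile_id = profile$profile_id,
                       stage_reached = stage, failing_rule_ids = failing,
                       stringsAsFactors = FALSE)
  traces$rule_outcomes <- outcomes
  list(traces = traces,
       eligible = traces$participant_id[traces$stage_reached == "eligible"])
}

#' Ordered funnel stage counts for a profile
#'
#' Cumulative attrition counts in reporting order: base population, clinical
#' inclusion passers, of those the amyloid-positive, of those (when the tau
#' step is enabled) the intermediate-tau, and the post-exclusion eligible set.
#'
#' @inheritParams apply_profile
#' @return named integer vector (base, inclusion, amyloid, \[tau,\] eligible),
#'   weakly decreasing.
#' @export
funnel_counts <- function(profile, cohort, base = base_population(cohort),
                          missing_policy = c("fail_closed", "fail_open")) {
  missing_policy <- match.arg(missing_policy)
  res <- apply_profile(profile, cohort, base, missing_policy)
  st <- res$traces$stage_reached
  n_base <- length(base)
  n_incl <- sum(st != "failed_inclusion")
  n_amy <- sum(!st %in% c("failed_inclusion", "failed_amyloid"))
  n_elig <- sum(st == "eligible")
  counts <- c(base = n_base, inclusion = n_incl, amyloid = n_amy)
  if (profile$tau_rule_enabled)
    counts <- c(counts, tau = sum(st %in% c("failed_exclusion", "eligible")))
  c(counts, eligible = n_elig)
}
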