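#' @keywords internal
"_PACKAGE"

## Canonical field vocabulary -------------------------------------------------

CDR_LEVELS <- c(0, 0.5, 1, 2, 3)
SEX_LEVELS <- c("female", "male", "other_unknown")
COPATH_STATES <- c("present", "absent", "not_reported")

#' Standard co-pathology keys
#'
#' The autopsy co-pathologies tracked by the harmonized data model: Lewy body
#' pathology, hippocampal sclerosis, infarcts and lacunes, single/multiple old
#' hemorrhages, FTLD with tau pathology, the FTLD-tau Pick's disease subtype,
#' and other tauopathies.
#'
#' @return Character vector of canonical co-pathology keys.
#' @export
copathology_keys <- function() {
  c("lewy_body", "hippocampal_sclerosis", "infarcts_lacunes",
    "old_hemorrhages", "ftld_tau", "ftld_tau_picks", "other_tauopathy")
}

clinical_scalar_fields <- function() {
  c("participant_id", "age_years", "sex", "mmse", "cdr_global",
    "cdr_memory_box", "etiologic_ad_dx", "baseline_date")
}

neuropath_scalar_fields <- function() {
  c("participant_id", "thal_phase", "braak_stage", "cerad_score", "death_date")
}

flag_columns <- function(df, prefix) {
  grep(paste0("^", prefix, "_"), names(df), value = TRUE)
}

## Cohort container -----------------------------------------------------------

#' Construct a cohort of joined clinical and neuropathology records
#'
#' A cohort pairs one clinical baseline record with one autopsy record per
#' participant, joined 1:1 on `participant_id`. Clinical comorbidity and
#' medication flags live in columns prefixed `comorbidity_` / `medication_`;
#' co-pathology tri-state flags ("present", "absent", "not_reported") live in
#' columns prefixed `copath_`.
#'
#' @param clinical data.frame with columns `participant_id`, `age_years`,
#'   `sex`, `mmse`, `cdr_global`, `cdr_memory_box`, `etiologic_ad_dx`,
#'   optionally `baseline_date`, plus flag columns.
#' @param neuropath data.frame with columns `participant_id`, `thal_phase`,
#'   `braak_stage`, `cerad_score`, optionally `death_date`, plus `copath_*`
#'   columns.
#' @param provenance free-text source label.
#' @param unmatched optional list with elements `clinical` and `neuropath`
#'   naming ids present on only one side (recorded by [read_cohort()]; a
#'   cohort itself always holds the 1:1 joined part).
#' @return An object of class `amyelig_cohort`.
#' @export
new_cohort <- function(clinical, neuropath, provenance = "unspecified",
                       unmatched = list(clinical = character(0),
                                        neuropath = character(0))) {
  stopifnot(is.data.frame(clinical), is.data.frame(neuropath))
  for (f in setdiff(clinical_scalar_fields(), "baseline_date"))
    if (!f %in% names(clinical))
      clinical[[f]] <- rep(NA, nrow(clinical))
  for (f in setdiff(neuropath_scalar_fields(), "death_date"))
    if (!f %in% names(neuropath))
      neuropath[[f]] <- rep(NA, nrow(neuropath))

  cid <- as.character(clinical$participant_id)
  nid <- as.character(neuropath$participant_id)
  if (anyDuplicated(cid))
    stop("duplicate participant_id in clinical table: ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "))
  if (anyDuplicated(nid))
    stop("duplicate participant_id in neuropathology table: ",
         paste(unique(nid[duplicated(nid)]), collapse = ", "))
  if (!setequal(cid, nid))
    stop("clinical and neuropathology ids do not match 1:1; ",
         "use read_cohort() for inner-join-with-report semantics")
  neuropath <- neuropath[match(cid, nid), , drop = FALSE]
  rownames(clinical) <- rownames(neuropath) <- NULL
  clinical$participant_id <- cid
  neuropath$participant_id <- cid

  structure(
    list(clinical = clinical, neuropath = neuropath,
         provenance = provenance, unmatched = unmatched),
    class = "amyelig_cohort"
  )
}

#' @export
print.amyelig_cohort <- function(x, ...) {
  cat("<amyelig_cohort> ", nrow(x$clinical), " participants (",
      x$provenance, ")\n", sep = "")
  n_un <- length(x$unmatched$clinical) + length(x$unmatched$neuropath)
  if (n_un > 0)
    cat("  ", n_un, "unmatched ids recorded at read time\n")
  invisible(x)
}

#' Number of participants in a cohort
#' @param x an `amyelig_cohort`.
#' @return integer count.
#' @export
length.amyelig_cohort <- function(x) nrow(x$clinical)

#' Participant ids of a cohort
#' @param cohort an `amyelig_cohort`.
#' @return character vector of ids.
#' @export
cohort_ids <- function(cohort) cohort$clinical$participant_id

#' Joined one-row-per-participant view of a cohort
#'
#' Merges the clinical and neuropathology tables on `participant_id` into a
#' single data.frame, the record shape consumed by rule evaluation.
#'
#' @param cohort an `amyelig_cohort`.
#' @param ids optional subset of participant ids (order preserved).
#' @return data.frame with one row per participant.
#' @export
joined_records <- function(cohort, ids = NULL) {
  np <- cohort$neuropath[, setdiff(names(cohort$neuropath), "participant_id"),
                         drop = FALSE]
  out <- cbind(cohort$clinical, np)
  if (!is.null(ids)) {
    idx <- match(ids, out$participant_id)
    if (anyNA(idx))
      stop("ids not in cohort: ", paste(ids[is.na(idx)], collapse = ", "))
    out <- out[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

## Validation -----------------------------------------------------------------

violation <- function(id, table, field, message) {
  data.frame(participant_id = id, table = table, field = field,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a cohort against the data-model invariants
#'
#' Report-only: returns a data.frame of violations (zero rows when the cohort
#' is valid). Checked invariants: non-empty unique ids; CDR global and memory
#' box restricted to \{0, 0.5, 1, 2, 3\}; MMSE in \[0, 30\]; age >= 0; sex in
#' the canonical set; Thal in \[0, 5\]; Braak in \[0, 6\]; CERAD in \[0, 3\];
#' each co-pathology flag in \{present, absent, not_reported\}.
#'
#' @param cohort an `amyelig_cohort`.
#' @return data.frame with columns participant_id, table, field, message.
#' @export
validate_cohort <- function(cohort) {
  cl <- cohort$clinical
  np <- cohort$neuropath
  ids <- cl$participant_id
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v

  bad <- which(is.na(ids) | !nzchar(ids))
  for (i in bad) add(violation("<row>", "clinical", "participant_id",
                               sprintf("empty participant_id at row %d", i)))

  check_range <- function(x, lo, hi, table, field, levels = NULL) {
    for (i in seq_along(x)) {
      if (is.na(x[i])) next
      ok <- if (!is.null(levels)) x[i] %in% levels else (x[i] >= lo && x[i] <= hi)
      if (!ok)
        add(violation(ids[i], table, field,
                      sprintf("value %s out of range", format(x[i]))))
    }
  }
  check_range(cl$mmse, 0, 30, "clinical", "mmse")
  check_range(cl$age_years, 0, Inf, "clinical", "age_years")
  check_range(cl$cdr_global, NA, NA, "clinical", "cdr_global", CDR_LEVELS)
  check_range(cl$cdr_memory_box, NA, NA, "clinical", "cdr_memory_box", CDR_LEVELS)
  check_range(as.character(cl$sex), NA, NA, "clinical", "sex", SEX_LEVELS)
  check_range(np$thal_phase, 0, 5, "neuropath", "thal_phase")
  check_range(np$braak_stage, 0, 6, "neuropath", "braak_stage")
  check_range(np$cerad_score, 0, 3, "neuropath", "cerad_score")
  for (col in flag_columns(np, "copath")) {
    x <- as.character(np[[col]])
    for (i in seq_along(x)) {
      if (is.na(x[i]) || !x[i] %in% COPATH_STATES)
        add(violation(ids[i], "neuropath", col,
                      sprintf("co-pathology state '%s' not one of %s",
                              x[i], paste(COPATH_STATES, collapse = "/"))))
    }
  }
  for (col in c(flag_columns(cl, "comorbidity"), flag_columns(cl, "medication"))) {
    x <- cl[[col]]
    if (!is.logical(x))
      add(violation("<all>", "clinical", col, "flag column is not logical"))
  }

  if (length(out) == 0)
    return(data.frame(participant_id = character(0), table = character(0),
                      field = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
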