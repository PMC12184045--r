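## Amnestic AD syndrome at baseline: the base population for all eligibility
## funnels. Three components: (i) global CDR 0.5 (MCI) or 1 (mild dementia),
## (ii) at least mild memory impairment on the CDR memory box, (iii) the
## clinician's etiologic AD diagnosis. Missing data fail closed.

#' Classify the amnestic AD syndrome at baseline
#'
#' A participant carries the syndrome iff the global CDR is 0.5 or 1, the CDR
#' memory box is at least `memory_threshold`, and the physician rated AD the
#' most likely etiology. Any required field missing makes the participant
#' unclassifiable and therefore not syndromic (fail-closed), recorded as the
#' `missing_data` component.
#'
#' @param records an `amyelig_cohort` or a clinical data.frame with columns
#'   `participant_id`, `cdr_global`, `cdr_memory_box`, `etiologic_ad_dx`.
#' @param memory_threshold minimum CDR memory box level counting as "at least
#'   mild memory impairment"; default 0.5 (questionable-or-worse), since MCI
#'   participants typically carry a 0.5 memory box. Set to 1 for a stricter
#'   reading.
#' @return data.frame: participant_id, is_amnestic_ad, stage (one of "mci",
#'   "mild_dementia", "not_applicable"), failed_components (comma-separated
#'   subset of cdr_stage, memory_impairment, etiologic_dx, missing_data; empty
#'   iff is_amnestic_ad).
#' @export
classify_syndrome <- function(records, memory_threshold = 0.5) {
  cl <- if (inherits(records, "amyelig_cohort")) records$clinical else records
  stopifnot(memory_threshold %in% CDR_LEVELS)
  n <- nrow(cl)
  cdr <- cl$cdr_global
  mem <- cl$cdr_memory_box
  dx <- cl$etiologic_ad_dx

  failed <- vector("list", n)
  for (i in seq_len(n)) {
    f <- character(0)
    if (is.na(cdr[i]) || is.na(mem[i]) || is.na(dx[i])) f <- c(f, "missing_data")
    if (!is.na(cdr[i]) && !cdr[i] %in% c(0.5, 1)) f <- c(f, "cdr_stage")
    if (!is.na(mem[i]) && mem[i] < memory_threshold) f <- c(f, "memory_impairment")
    if (!is.na(dx[i]) && !isTRUE(dx[i] == TRUE)) f <- c(f, "etiologic_dx")
    failed[[i]] <- f
  }
  stage <- rep("not_applicable", n)
  stage[!is.na(cdr) & cdr == 0.5] <- "mci"
  stage[!is.na(cdr) & cdr == 1] <- "mild_dementia"
  data.frame(
    participant_id = cl$participant_id,
    is_amnestic_ad = lengths(failed) == 0L,
    stage = stage,
    failed_components = vapply(failed, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Base population: ids with the amnestic AD syndrome
#'
#' The denominator for every "% of the full sample" figure downstream.
#'
#' @param cohort an `amyelig_cohort`.
#' @param memory_threshold see [classify_syndrome()].
#' @return character vector of participant ids.
#' @export
base_population <- function(cohort, memory_threshold = 0.5) {
  res <- classify_syndrome(cohort, memory_threshold)
  res$participant_id[res$is_amnestic_ad]
}
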