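## Reporting: rounded-percentage funnel reports, Euler-region overlaps,
## co-pathology prevalence, CDR composition, full-AD-pathology shares.

#' Integer percentage, halves rounded away from zero
#'
#' The reporting convention used throughout: `round(100 * num / den)` to the
#' nearest integer with ties going away from zero (e.g. 83/887 -> 9,
#' 8/83 -> 10). A zero denominator yields NA (undefined-percent marker),
#' never an error.
#'
#' @param num,den non-negative counts (vectorized, recycled).
#' @return integer vector in \[0, 100\] (NA where den == 0).
#' @export
percent_int <- function(num, den) {
  stopifnot(all(num >= 0, na.rm = TRUE), all(den >= 0, na.rm = TRUE))
  out <- ifelse(den == 0, NA_real_, floor(100 * num / den + 0.5))
  as.integer(out)
}

#' Build a funnel report from ordered stage counts
#'
#' Annotates each stage with its percent of the previous stage and its percent
#' of the named full-sample denominator (the amnestic-syndrome base
#' population — never the autopsy cohort).
#'
#' @param counts named integer vector as from [funnel_counts()]; must be
#'   weakly decreasing (a violation signals an engine bug and is a hard
#'   error).
#' @param denominators named numeric vector; must contain `full_sample`.
#' @param profile_id label stored on the report.
#' @return data.frame of class `amyelig_funnel_report`: stage, count,
#'   pct_of_previous, pct_of_full_sample.
#' @export
build_funnel_report <- function(counts, denominators, profile_id = "") {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of funnel stages")
  if (any(diff(counts) > 0))
    stop("funnel counts are not weakly decreasing: ",
         paste(counts, collapse = " -> "))
  if (!"full_sample" %in% names(denominators))
    stop("denominators must name full_sample")
  full <- denominators[["full_sample"]]
  prev <- c(NA, counts[-length(counts)])
  out <- data.frame(
    stage = names(counts),
    count = as.integer(counts),
    pct_of_previous = percent_int(counts, prev),
    pct_of_full_sample = percent_int(counts, rep(full, length(counts))),
    stringsAsFactors = FALSE
  )
  attr(out, "profile_id") <- profile_id
  attr(out, "denominators") <- denominators
  class(out) <- c("amyelig_funnel_report", "data.frame")
  out
}

#' Exact Euler-region counts for named eligible sets
#'
#' Partitions the union of 1-5 id sets by membership signature: each
#' participant is assigned to exactly the subset of profiles containing them.
#' Region counts therefore sum to the union size, and the regions containing
#' a profile sum to that profile's set size.
#'
#' @param sets named list of character id vectors (1-5 sets).
#' @return data.frame of class `amyelig_overlap`: one row per non-empty
#'   subset of set names, columns `region` (names joined by "&"), `count`.
#' @export
euler_regions <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, length(sets) <= 5,
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, nm))
  sig <- apply(member, 1, function(m) paste(nm[m], collapse = "&"))

  k <- length(nm)
  subsets <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(nm, sz, paste, collapse = "&")))
  count <- vapply(subsets, function(s) sum(sig == s), integer(1))
  out <- data.frame(region = subsets, count = unname(count),
                    stringsAsFactors = FALSE)
  attr(out, "union_size") <- length(ids)
  attr(out, "set_sizes") <- vapply(sets, length, integer(1))
  class(out) <- c("amyelig_overlap", "data.frame")
  out
}

#' Co-pathology prevalence table for a participant group
#'
#' Per co-pathology: counts of present / absent / not-reported states and the
#' integer percent present. By default the denominator is the full group
#' (not-reported states stay in the denominator but never in the numerator);
#' `complete_case = TRUE` switches to reported-only denominators for
#' sensitivity analysis.
#'
#' @param group character vector of participant ids.
#' @param cohort an `amyelig_cohort`.
#' @param complete_case use reported-only denominators (default FALSE).
#' @return data.frame: copathology, present, absent, not_reported,
#'   percent_present; attribute `group_size`.
#' @export
copathology_prevalence <- function(group, cohort, complete_case = FALSE) {
  np <- cohort$neuropath
  idx <- match(group, np$participant_id)
  if (anyNA(idx)) stop("group contains ids not in the cohort")
  cols <- flag_columns(np, "copath")
  rows <- lapply(cols, function(col) {
    x <- as.character(np[[col]][idx])
    pres <- sum(x == "present", na.rm = TRUE)
    abs_ <- sum(x == "absent", na.rm = TRUE)
    nr <- sum(is.na(x) | x == "not_reported")
    den <- if (complete_case) pres + abs_ else length(group)
    data.frame(copathology = sub("^copath_", "", col), present = pres,
               absent = abs_, not_reported = nr,
               percent_present = percent_int(pres, den),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "group_size") <- length(group)
  out
}

#' CDR composition of a group
#'
#' Share of the group at the MCI stage (global CDR 0.5); participants with a
#' missing global CDR are counted and reported separately, never folded into
#' either stage.
#'
#' @param group character vector of participant ids.
#' @param cohort an `amyelig_cohort`.
#' @return list: n, n_cdr_05, n_cdr_1, n_missing, percent_cdr_05.
#' @export
cdr_composition <- function(group, cohort) {
  cl <- cohort$clinical
  idx <- match(group, cl$participant_id)
  if (anyNA(idx)) stop("group contains ids not in the cohort")
  cdr <- cl$cdr_global[idx]
  list(n = length(group),
       n_cdr_05 = sum(!is.na(cdr) & cdr == 0.5),
       n_cdr_1 = sum(!is.na(cdr) & cdr == 1),
       n_missing = sum(is.na(cdr)),
       percent_cdr_05 = percent_int(sum(!is.na(cdr) & cdr == 0.5),
                                    length(group)))
}

#' Count and share of a group with full AD pathology
#'
#' Full AD pathology means an ABC summary of "intermediate" or "high".
#' Members whose staging is incomplete (missing Thal, Braak or CERAD) are
#' counted separately.
#'
#' @param group character vector of participant ids.
#' @param cohort an `amyelig_cohort`.
#' @return list: n, n_full_ad, n_unstaged, percent_full_ad.
#' @export
full_ad_pathology_share <- function(group, cohort) {
  st <- stage_cohort(cohort)
  idx <- match(group, st$participant_id)
  if (anyNA(idx)) stop("group contains ids not in the cohort")
  path <- st$ad_pathology[idx]
  list(n = length(group),
       n_full_ad = sum(path, na.rm = TRUE),
       n_unstaged = sum(is.na(path)),
       percent_full_ad = percent_int(sum(path, na.rm = TRUE), length(group)))
}
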