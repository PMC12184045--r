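## NIA-AA ABC neuropathologic staging and the autopsy-based amyloid/tau
## operationalizations. Missing scores propagate as NA; resolution of
## missingness is the eligibility layer's job.

ABC_LEVELS <- c("not", "low", "intermediate", "high")

.amyelig_env <- new.env(parent = emptyenv())

#' A score from Thal amyloid phase
#'
#' Thal phase (0-5, anatomical spread of amyloid-beta plaques) binned to the
#' NIA-AA A score: 0 -> 0, 1-2 -> 1, 3 -> 2, 4-5 -> 3.
#'
#' @param thal_phase integer vector in \[0, 5\]; NA propagates.
#' @return integer vector in \[0, 3\].
#' @export
a_score <- function(thal_phase) {
  chk_range(thal_phase, 0, 5, "thal_phase")
  unname(c(0L, 1L, 1L, 2L, 3L, 3L)[thal_phase + 1L])
}

#' B score from Braak neurofibrillary tangle stage
#'
#' Braak stage (0-6) binned to the NIA-AA B score: 0 -> 0, 1-2 -> 1,
#' 3-4 -> 2, 5-6 -> 3.
#'
#' @param braak_stage integer vector in \[0, 6\]; NA propagates.
#' @return integer vector in \[0, 3\].
#' @export
b_score <- function(braak_stage) {
  chk_range(braak_stage, 0, 6, "braak_stage")
  unname(c(0L, 1L, 1L, 2L, 2L, 3L, 3L)[braak_stage + 1L])
}

#' C score from the CERAD neuritic plaque score
#'
#' Identity on the canonical 0-3 coding (none/sparse/moderate/frequent).
#'
#' @param cerad integer vector in \[0, 3\] or labels
#'   none/sparse/moderate/frequent; NA propagates.
#' @return integer vector in \[0, 3\].
#' @export
c_score <- function(cerad) {
  if (is.character(cerad) || is.factor(cerad)) {
    labels <- c(none = 0L, sparse = 1L, moderate = 2L, frequent = 3L)
    cerad <- unname(labels[as.character(cerad)])
  }
  chk_range(cerad, 0, 3, "cerad")
  as.integer(cerad)
}

chk_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi | x != floor(x))
  if (any(bad))
    stop(what, " out of range [", lo, ", ", hi, "]: ",
         paste(unique(x[bad]), collapse = ", "))
  invisible(x)
}

#' The ABC combination matrix
#'
#' Loads (and caches) the 64-cell lookup combining A, B, and C scores into the
#' four-level AD-neuropathologic-change summary, shipped as an editable CSV.
#' The loader enforces completeness (all 64 cells), the A0 -> "not" rule, and
#' three-way monotonicity.
#'
#' @param path optional path to an alternative matrix file.
#' @return data.frame with columns a_score, b_score, c_score, level.
#' @export
abc_matrix <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.amyelig_env$abc_matrix)) return(.amyelig_env$abc_matrix)
    path <- system.file("extdata", "abc_matrix.csv", package = "amyelig",
                        mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("a_score", "b_score", "c_score", "level") %in% names(m)))
  key <- paste(m$a_score, m$b_score, m$c_score)
  full <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  if (nrow(m) != 64 || !setequal(key, paste(full$a, full$b, full$c)))
    stop("ABC matrix must contain exactly the 64 (A,B,C) cells")
  if (!all(m$level %in% ABC_LEVELS))
    stop("ABC matrix levels must be in ", paste(ABC_LEVELS, collapse = "/"))
  lev <- function(a, b, c) m$level[key == paste(a, b, c)]
  if (!all(m$level[m$a_score == 0] == "not"))
    stop("ABC matrix violates the A0 -> 'not' rule")
  ord <- function(l) match(l, ABC_LEVELS)
  for (i in seq_len(64)) {
    a <- m$a_score[i]; b <- m$b_score[i]; c <- m$c_score[i]
    for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      a2 <- a + d[1]; b2 <- b + d[2]; c2 <- c + d[3]
      if (a2 > 3 || b2 > 3 || c2 > 3) next
      if (ord(lev(a2, b2, c2)) < ord(m$level[i]))
        stop("ABC matrix is not monotone at cell (", a, ",", b, ",", c, ")")
    }
  }
  if (cache) .amyelig_env$abc_matrix <- m
  m
}

#' Four-level ABC summary of AD neuropathologic change
#'
#' @param a,b,c integer vectors of A, B, C scores in \[0, 3\]; a missing input
#'   score yields a missing summary (never guessed).
#' @param matrix combination matrix as returned by [abc_matrix()].
#' @return character vector over \{not, low, intermediate, high\}.
#' @export
abc_summary <- function(a, b, c, matrix = abc_matrix()) {
  chk_range(a, 0, 3, "a_score"); chk_range(b, 0, 3, "b_score")
  chk_range(c, 0, 3, "c_score")
  n <- max(length(a), length(b), length(c))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  key <- paste(matrix$a_score, matrix$b_score, matrix$c_score)
  out <- matrix$level[match(paste(a, b, c), key)]
  out[is.na(a) | is.na(b) | is.na(c)] <- NA_character_
  out
}

#' Does an ABC summary indicate full AD pathology?
#'
#' "intermediate" and "high" AD neuropathologic change count as presence of
#' AD pathology; "low" and "not" as absence.
#'
#' @param summary character vector over \{not, low, intermediate, high\}.
#' @return logical vector; NA propagates.
#' @export
has_ad_pathology <- function(summary) {
  bad <- !is.na(summary) & !summary %in% ABC_LEVELS
  if (any(bad)) stop("unknown ABC summary level: ",
                     paste(unique(summary[bad]), collapse = ", "))
  ifelse(is.na(summary), NA, summary %in% c("intermediate", "high"))
}

#' Amyloid positivity from the post-mortem Thal phase
#'
#' Two operationalizations: `pet_equivalent` treats Thal 3-5 as corresponding
#' to a positive amyloid PET in life; `any_amyloid` counts any amyloid
#' (Thal > 0) as positive, a sensitivity definition.
#'
#' @param thal_phase integer vector in \[0, 5\]; NA propagates (participant not
#'   classifiable; resolved by the eligibility engine's missing-data policy).
#' @param mode "pet_equivalent" (default) or "any_amyloid".
#' @return logical vector.
#' @export
amyloid_positive <- function(thal_phase,
                             mode = c("pet_equivalent", "any_amyloid")) {
  mode <- match.arg(mode)
  chk_range(thal_phase, 0, 5, "thal_phase")
  thal_phase >= if (mode == "pet_equivalent") 3L else 1L
}

#' Intermediate tau spread (Braak 3-4)
#'
#' Operationalizes a tau-PET criterion of intermediate tau spread by a
#' post-mortem Braak stage of 3 or 4.
#'
#' @param braak_stage integer vector in \[0, 6\]; NA propagates.
#' @return logical vector.
#' @export
tau_intermediate <- function(braak_stage) {
  chk_range(braak_stage, 0, 6, "braak_stage")
  ifelse(is.na(braak_stage), NA, braak_stage %in% c(3L, 4L))
}

#' Per-participant ABC staging of a cohort
#'
#' @param cohort an `amyelig_cohort`.
#' @return data.frame: participant_id, a_score, b_score, c_score, summary,
#'   ad_pathology.
#' @export
stage_cohort <- function(cohort) {
  np <- cohort$neuropath
  a <- a_score(np$thal_phase)
  b <- b_score(np$braak_stage)
  c <- c_score(np$cerad_score)
  s <- abc_summary(a, b, c)
  data.frame(participant_id = np$participant_id, a_score = a, b_score = b,
             c_score = c, summary = s, ad_pathology = has_ad_pathology(s),
             stringsAsFactors = FALSE)
}
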