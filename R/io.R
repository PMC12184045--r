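## Codebook-driven delimited-text I/O.
##
## Source dialects (e.g. NACC-style numeric missing codes) are handled entirely
## by the codebook; in-memory records always use canonical names and values.

#' Construct a codebook
#'
#' A codebook maps source columns to canonical fields and source codes to
#' canonical values, per table. Canonical fields absent from both the column
#' map and the source header are treated as declared-absent (all missing)
#' unless `strict_fields` lists them, in which case their absence is a hard
#' error.
#'
#' @param clinical,neuropath per-table list with elements `column_map` (named
#'   character: canonical name -> source column) and `value_map` (named list:
#'   canonical field -> named vector mapping source code string -> canonical
#'   value; the special target `"missing"` maps a code to NA).
#' @param missing_token token representing missingness in files (default: the
#'   empty field).
#' @param strict_fields canonical fields that must be resolvable (default:
#'   participant_id only).
#' @return object of class `amyelig_codebook`.
#' @export
codebook <- function(clinical = list(column_map = character(0), value_map = list()),
                     neuropath = list(column_map = character(0), value_map = list()),
                     missing_token = "",
                     strict_fields = "participant_id") {
  norm <- function(tab) {
    if (is.null(tab$column_map)) tab$column_map <- character(0)
    if (is.null(tab$value_map)) tab$value_map <- list()
    tab$column_map <- unlist(tab$column_map)
    tab
  }
  structure(list(clinical = norm(clinical), neuropath = norm(neuropath),
                 missing_token = missing_token, strict_fields = strict_fields),
            class = "amyelig_codebook")
}

#' Identity codebook (canonical column names, empty-string missing token)
#' @return an `amyelig_codebook`.
#' @export
codebook_default <- function() codebook()

#' Load a codebook from a JSON file
#' @param path JSON file with keys `clinical`, `neuropath`, `missing_token`,
#'   `strict_fields` as in [codebook()].
#' @return an `amyelig_codebook`.
#' @export
load_codebook <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  codebook(
    clinical = if (is.null(cfg$clinical)) list() else cfg$clinical,
    neuropath = if (is.null(cfg$neuropath)) list() else cfg$neuropath,
    missing_token = if (is.null(cfg$missing_token)) "" else cfg$missing_token,
    strict_fields = if (is.null(cfg$strict_fields)) "participant_id"
                    else cfg$strict_fields
  )
}

## field typing for coercion after value-map application
coerce_field <- function(x, field) {
  if (field %in% c("age_years", "mmse", "thal_phase", "braak_stage",
                   "cerad_score"))
    return(suppressWarnings(as.integer(round(as.numeric(x)))))
  if (field %in% c("cdr_global", "cdr_memory_box"))
    return(suppressWarnings(as.numeric(x)))
  if (field == "etiologic_ad_dx" || grepl("^(comorbidity|medication)_", field))
    return(as.logical(x))
  if (field %in% c("baseline_date", "death_date"))
    return(as.Date(as.character(x)))
  as.character(x)
}

apply_codebook_table <- function(df, tab_map, canonical_fields, flag_prefixes,
                                 strict_fields) {
  cmap <- tab_map$column_map
  ## rename mapped source columns to canonical names
  for (canon in names(cmap)) {
    src <- cmap[[canon]]
    if (!src %in% names(df))
      stop("codebook maps '", canon, "' to source column '", src,
           "' which is not in the table")
    names(df)[names(df) == src] <- canon
  }
  for (f in intersect(strict_fields, canonical_fields)) {
    if (!f %in% names(df))
      stop("required field '", f, "' is neither mapped nor present")
  }
  ## value-map translation (codes compared as strings)
  for (f in names(tab_map$value_map)) {
    if (!f %in% names(df)) next
    vm <- tab_map$value_map[[f]]
    x <- as.character(df[[f]])
    hit <- x %in% names(vm)
    x[hit] <- vapply(x[hit], function(code) {
      v <- vm[[code]]
      if (identical(v, "missing")) NA_character_ else as.character(v)
    }, character(1))
    df[[f]] <- x
  }
  keep <- c(intersect(canonical_fields, names(df)),
            unlist(lapply(flag_prefixes, flag_columns, df = df)))
  df <- df[, keep, drop = FALSE]
  for (f in setdiff(names(df), "participant_id"))
    df[[f]] <- coerce_field(df[[f]], f)
  for (f in setdiff(canonical_fields, names(df)))
    df[[f]] <- coerce_field(rep(NA_character_, nrow(df)), f)
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Read a cohort from two delimited-text tables
#'
#' Applies the codebook's column and value maps, coerces fields to canonical
#' types, inner-joins on `participant_id` and records (never silently drops)
#' unmatched ids on either side. Row-level range violations are collected into
#' the `validation` attribute of the result; structural problems (missing id
#' column, duplicate ids) are hard errors.
#'
#' @param clinical_table,neuropath_table paths to delimited text files with a
#'   header row.
#' @param codebook an `amyelig_codebook` (default: identity).
#' @param sep field separator ("," default, "\t" selectable).
#' @param provenance source label stored on the cohort.
#' @return an `amyelig_cohort`; unmatched ids in `$unmatched`, row-level
#'   violations in `attr(, "validation")`.
#' @export
read_cohort <- function(clinical_table, neuropath_table,
                        codebook = codebook_default(), sep = ",",
                        provenance = clinical_table) {
  rd <- function(path) {
    utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                      na.strings = codebook$missing_token, quote = "\"",
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  cl <- apply_codebook_table(rd(clinical_table), codebook$clinical,
                             clinical_scalar_fields(),
                             c("comorbidity", "medication"),
                             codebook$strict_fields)
  np <- apply_codebook_table(rd(neuropath_table), codebook$neuropath,
                             neuropath_scalar_fields(),
                             "copath", codebook$strict_fields)
  if (anyDuplicated(cl$participant_id))
    stop("duplicate participant_id in clinical table: ",
         paste(unique(cl$participant_id[duplicated(cl$participant_id)]),
               collapse = ", "))
  if (anyDuplicated(np$participant_id))
    stop("duplicate participant_id in neuropathology table: ",
         paste(unique(np$participant_id[duplicated(np$participant_id)]),
               collapse = ", "))
  only_cl <- setdiff(cl$participant_id, np$participant_id)
  only_np <- setdiff(np$participant_id, cl$participant_id)
  shared <- intersect(cl$participant_id, np$participant_id)
  cohort <- new_cohort(cl[cl$participant_id %in% shared, , drop = FALSE],
                       np[np$participant_id %in% shared, , drop = FALSE],
                       provenance = provenance,
                       unmatched = list(clinical = only_cl, neuropath = only_np))
  attr(cohort, "validation") <- validate_cohort(cohort)
  cohort
}

#' Write a cohort to two delimited-text files
#'
#' Inverse of [read_cohort()] under the identity codebook: writing then
#' reading reproduces the cohort field-for-field, including missing values
#' (encoded with `missing_token`).
#'
#' @param cohort an `amyelig_cohort`.
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @param missing_token file token for missing values.
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir, sep = ",", missing_token = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    for (f in names(df)) {
      x <- df[[f]]
      df[[f]] <- ifelse(is.na(x), missing_token,
                        if (inherits(x, "Date")) format(x, "%Y-%m-%d")
                        else as.character(x))
    }
    df
  }
  paths <- c(clinical = file.path(dir, "clinical.csv"),
             neuropath = file.path(dir, "neuropath.csv"))
  utils::write.table(fmt(cohort$clinical), paths["clinical"], sep = sep,
                     row.names = FALSE, quote = FALSE, na = missing_token)
  utils::write.table(fmt(cohort$neuropath), paths["neuropath"], sep = sep,
                     row.names = FALSE, quote = FALSE, na = missing_token)
  invisible(paths)
}
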