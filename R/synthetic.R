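## Synthetic cohort generator emulating the joint clinical/autopsy structure
## the eligibility analysis assumes. A single latent AD-severity scalar drives
## Thal, Braak and CERAD through monotone threshold maps (plus independent
## ordinal jitter), producing the strong positive dependence needed for the
## calibration targets: ~90% amyloid positivity among clinical includees and
## >=95% full AD pathology among eligibles. Co-pathology and clinical
## exclusion flags are independent Bernoulli draws by default.

#' Default synthetic cohort configuration
#'
#' All knobs of the generator with field-realistic defaults. The default `n`
#' is 3343, the size of an autopsy-confirmed research cohort; co-pathology
#' prevalences default to values typical of amyloid-positive autopsy series
#' (Lewy body 0.52, hippocampal sclerosis 0.18, infarcts/lacunes 0.11, old
#' hemorrhages 0.02, FTLD-tau 0.05, Pick's 0.005, other tauopathy 0.03).
#'
#' @param n cohort size (>= 0).
#' @param seed integer RNG seed; generation is bit-reproducible given
#'   config + seed.
#' @param p_affected mixture weight of the latent-AD ("affected") component.
#' @param severity_affected,severity_unaffected mean/sd of the latent severity
#'   scalar in each mixture component.
#' @param thal_cuts,braak_cuts,cerad_cuts increasing severity thresholds
#'   mapping severity to Thal (0-5), Braak (0-6) and CERAD (0-3).
#' @param ordinal_jitter probability of each of +1 / -1 ordinal jitter applied
#'   independently to each staging score (clamped to range).
#' @param cdr_probs_affected,cdr_probs_unaffected global-CDR level
#'   probabilities (levels 0, 0.5, 1, 2, 3) per component.
#' @param memory_box_model nested list (affected/unaffected, then CDR level as
#'   character) of memory-box level probabilities.
#' @param p_ad_dx_affected,p_ad_dx_unaffected probability of a clinician
#'   etiologic AD diagnosis given cognitive impairment (CDR > 0), per
#'   component; participants with CDR 0 are never diagnosed.
#' @param mmse_model list: `means` named by CDR level, `sd`; integer-rounded,
#'   clamped to \[0, 30\].
#' @param age_model list: mean, sd, min, max (years, integer-rounded).
#' @param p_female probability of female sex.
#' @param target_p_amyloid_given_inclusion calibration target for
#'   P(Thal 3-5 | clinical inclusion); default 0.90. Stored alongside the
#'   structural parameters so [calibration_report()] can compare realized
#'   against configured values.
#' @param copathology_prevalences named probabilities over
#'   [copathology_keys()].
#' @param not_reported_rate probability a co-pathology state is not reported
#'   (<= 0.02 by convention).
#' @param comorbidity_prevalences,medication_prevalences named Bernoulli rates
#'   for the clinical exclusion flags.
#' @return list of class `amyelig_synth_config`.
#' @export
synthetic_cohort_config <- function(
    n = 3343, seed = 1,
    p_affected = 0.55,
    severity_affected = c(mean = 3.2, sd = 1.0),
    severity_unaffected = c(mean = -0.3, sd = 1.0),
    thal_cuts = c(0.5, 1.0, 1.35, 2.2, 3.0),
    braak_cuts = c(0.2, 0.6, 1.0, 1.4, 2.1, 2.8),
    cerad_cuts = c(0.7, 1.2, 1.8),
    ordinal_jitter = 0.12,
    cdr_probs_affected = c("0" = 0.05, "0.5" = 0.35, "1" = 0.30,
                           "2" = 0.20, "3" = 0.10),
    cdr_probs_unaffected = c("0" = 0.55, "0.5" = 0.28, "1" = 0.12,
                             "2" = 0.04, "3" = 0.01),
    memory_box_model = default_memory_box_model(),
    p_ad_dx_affected = 0.88, p_ad_dx_unaffected = 0.15,
    mmse_model = list(means = c("0" = 29, "0.5" = 26.5, "1" = 22.5,
                                "2" = 16, "3" = 8), sd = 2.5),
    age_model = list(mean = 73, sd = 8, min = 50, max = 100),
    p_female = 0.52,
    target_p_amyloid_given_inclusion = 0.90,
    copathology_prevalences = c(lewy_body = 0.52, hippocampal_sclerosis = 0.18,
                                infarcts_lacunes = 0.11, old_hemorrhages = 0.02,
                                ftld_tau = 0.05, ftld_tau_picks = 0.005,
                                other_tauopathy = 0.03),
    not_reported_rate = 0.015,
    comorbidity_prevalences = c(stroke_or_tia = 0.07, seizures = 0.03,
                                bleeding_disorder = 0.02,
                                unstable_psychiatric = 0.05,
                                cancer_active = 0.04),
    medication_prevalences = c(anticoagulant_use = 0.10)) {
  cfg <- as.list(environment())
  class(cfg) <- "amyelig_synth_config"
  validate_synth_config(cfg)
  cfg
}

default_memory_box_model <- function() {
  list(
    affected = list(
      "0" = c("0" = 0.85, "0.5" = 0.15),
      "0.5" = c("0" = 0.05, "0.5" = 0.70, "1" = 0.25),
      "1" = c("0.5" = 0.15, "1" = 0.70, "2" = 0.15),
      "2" = c("1" = 0.30, "2" = 0.60, "3" = 0.10),
      "3" = c("2" = 0.30, "3" = 0.70)
    ),
    unaffected = list(
      "0" = c("0" = 0.90, "0.5" = 0.10),
      "0.5" = c("0" = 0.35, "0.5" = 0.55, "1" = 0.10),
      "1" = c("0" = 0.20, "0.5" = 0.30, "1" = 0.50),
      "2" = c("0.5" = 0.20, "1" = 0.30, "2" = 0.50),
      "3" = c("1" = 0.20, "2" = 0.30, "3" = 0.50)
    )
  )
}

validate_synth_config <- function(cfg) {
  probs <- c(cfg$p_affected, cfg$ordinal_jitter, cfg$p_ad_dx_affected,
             cfg$p_ad_dx_unaffected, cfg$p_female,
             cfg$target_p_amyloid_given_inclusion,
             cfg$copathology_prevalences, cfg$not_reported_rate,
             cfg$comorbidity_prevalences, cfg$medication_prevalences,
             cfg$cdr_probs_affected, cfg$cdr_probs_unaffected)
  if (any(probs < 0 | probs > 1))
    stop("synthetic config: all probabilities must be in [0, 1]")
  if (cfg$n < 0) stop("synthetic config: n must be >= 0")
  for (cuts in list(cfg$thal_cuts, cfg$braak_cuts, cfg$cerad_cuts))
    if (is.unsorted(cuts, strictly = FALSE))
      stop("synthetic config: threshold maps must be monotone (sorted cuts)")
  if (abs(sum(cfg$cdr_probs_affected) - 1) > 1e-8 ||
      abs(sum(cfg$cdr_probs_unaffected) - 1) > 1e-8)
    stop("synthetic config: CDR level probabilities must sum to 1")
  if (!setequal(names(cfg$copathology_prevalences), copathology_keys()))
    stop("synthetic config: copathology_prevalences must cover exactly ",
         paste(copathology_keys(), collapse = ", "))
  if (any(cfg$copathology_prevalences + cfg$not_reported_rate > 1))
    stop("synthetic config: prevalence + not_reported_rate exceeds 1")
  invisible(cfg)
}

sev_to_ordinal <- function(sev, cuts, jitter, max_level) {
  raw <- vapply(sev, function(s) sum(s >= cuts), integer(1))
  u <- stats::runif(length(sev))
  raw <- raw + (u < jitter) - (u > 1 - jitter)
  as.integer(pmin(pmax(raw, 0L), max_level))
}

sample_level <- function(probs_by_key, keys) {
  vapply(keys, function(k) {
    p <- probs_by_key[[k]]
    as.numeric(sample(names(p), 1, prob = p))
  }, numeric(1))
}

#' Generate a synthetic cohort
#'
#' Deterministic given config + seed (the caller's RNG state is preserved).
#' Every generated record passes [validate_cohort()] and feeds every other
#' module without special-casing.
#'
#' @param config an `amyelig_synth_config` from [synthetic_cohort_config()].
#' @return an `amyelig_cohort` with provenance "synthetic".
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  validate_synth_config(config)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  }
  set.seed(config$seed)
  n <- config$n
  ids <- sprintf("SYN%06d", seq_len(n))

  affected <- stats::runif(n) < config$p_affected
  sev <- ifelse(affected,
                stats::rnorm(n, config$severity_affected["mean"],
                             config$severity_affected["sd"]),
                stats::rnorm(n, config$severity_unaffected["mean"],
                             config$severity_unaffected["sd"]))

  thal <- sev_to_ordinal(sev, config$thal_cuts, config$ordinal_jitter, 5L)
  braak <- sev_to_ordinal(sev, config$braak_cuts, config$ordinal_jitter, 6L)
  cerad <- sev_to_ordinal(sev, config$cerad_cuts, config$ordinal_jitter, 3L)

  cdr_levels <- c(0, 0.5, 1, 2, 3)
  cdr <- numeric(n)
  if (n > 0) {
    cdr[affected] <- sample(cdr_levels, sum(affected), replace = TRUE,
                            prob = config$cdr_probs_affected)
    cdr[!affected] <- sample(cdr_levels, sum(!affected), replace = TRUE,
                             prob = config$cdr_probs_unaffected)
  }
  mem <- numeric(n)
  for (i in seq_len(n)) {
    model <- config$memory_box_model[[if (affected[i]) "affected" else "unaffected"]]
    p <- model[[as.character(cdr[i])]]
    mem[i] <- as.numeric(sample(names(p), 1, prob = p))
  }
  impaired <- cdr > 0
  dx <- impaired & (stats::runif(n) <
    ifelse(affected, config$p_ad_dx_affected, config$p_ad_dx_unaffected))

  mmse <- as.integer(pmin(30, pmax(0, round(
    stats::rnorm(n, config$mmse_model$means[as.character(cdr)],
                 config$mmse_model$sd)))))
  age <- as.integer(pmin(config$age_model$max, pmax(config$age_model$min,
    round(stats::rnorm(n, config$age_model$mean, config$age_model$sd)))))
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")

  clinical <- data.frame(
    participant_id = ids, age_years = age, sex = sex, mmse = mmse,
    cdr_global = cdr, cdr_memory_box = mem, etiologic_ad_dx = dx,
    baseline_date = as.Date("2005-06-01") +
      sample.int(5900, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  for (flag in names(config$comorbidity_prevalences))
    clinical[[paste0("comorbidity_", flag)]] <-
      stats::runif(n) < config$comorbidity_prevalences[[flag]]
  for (flag in names(config$medication_prevalences))
    clinical[[paste0("medication_", flag)]] <-
      stats::runif(n) < config$medication_prevalences[[flag]]

  neuropath <- data.frame(
    participant_id = ids, thal_phase = thal, braak_stage = braak,
    cerad_score = cerad,
    death_date = clinical$baseline_date +
      pmax(30, round(stats::rnorm(n, 6.8 * 365.25, 3.4 * 365.25))),
    stringsAsFactors = FALSE
  )
  for (flag in copathology_keys()) {
    p <- config$copathology_prevalences[[flag]]
    u <- stats::runif(n)
    neuropath[[paste0("copath_", flag)]] <-
      ifelse(u < p, "present",
             ifelse(u < p + config$not_reported_rate, "not_reported", "absent"))
  }
  if (n == 0) {
    clinical$baseline_date <- as.Date(character(0))
    neuropath$death_date <- as.Date(character(0))
    for (flag in copathology_keys())
      neuropath[[paste0("copath_", flag)]] <- character(0)
  }

  new_cohort(clinical, neuropath, provenance = "synthetic")
}

#' Calibration report: realized vs configured proportions
#'
#' For each supplied criteria profile, reports P(amyloid-positive | clinical
#' inclusion), P(full AD pathology | eligible), the CDR-0.5 share among
#' eligibles, and co-pathology prevalence among eligibles, side by side with
#' the configured targets and a 3-binomial-SE sampling tolerance.
#'
#' @param cohort a generated `amyelig_cohort`.
#' @param profiles list of `amyelig_profile` objects (default: all bundled).
#' @param config the `amyelig_synth_config` used for generation (supplies the
#'   targets).
#' @return data.frame: profile_id, quantity, target, realized, n_denominator,
#'   tol_3se, within_tol (NA where no target is configured).
#' @export
calibration_report <- function(cohort,
                               profiles = lapply(bundled_profiles(), load_profile),
                               config = synthetic_cohort_config()) {
  base <- base_population(cohort)
  rows <- list()
  add <- function(profile_id, quantity, target, realized, n) {
    tol <- if (!is.na(target) && n > 0)
      3 * sqrt(target * (1 - target) / n) else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      profile_id = profile_id, quantity = quantity, target = target,
      realized = realized, n_denominator = n, tol_3se = tol,
      within_tol = if (is.na(target) || is.na(tol)) NA
                   else abs(realized - target) <= tol,
      stringsAsFactors = FALSE)
  }
  for (profile in profiles) {
    res <- apply_profile(profile, cohort, base)
    st <- res$traces$stage_reached
    incl <- res$traces$participant_id[st != "failed_inclusion"]
    amy <- res$traces$participant_id[!st %in% c("failed_inclusion", "failed_amyloid")]
    elig <- res$eligible
    add(profile$profile_id, "p_amyloid_given_inclusion",
        config$target_p_amyloid_given_inclusion,
        if (length(incl)) length(amy) / length(incl) else NA_real_,
        length(incl))
    fad <- full_ad_pathology_share(elig, cohort)
    add(profile$profile_id, "p_full_ad_given_eligible", NA_real_,
        if (fad$n) fad$n_full_ad / fad$n else NA_real_, fad$n)
    comp <- cdr_composition(elig, cohort)
    add(profile$profile_id, "p_cdr_05_given_eligible", NA_real_,
        if (comp$n) comp$n_cdr_05 / comp$n else NA_real_, comp$n)
    prev <- copathology_prevalence(elig, cohort)
    for (j in seq_len(nrow(prev)))
      add(profile$profile_id,
          paste0("p_copath_", prev$copathology[j], "_given_eligible"),
          config$copathology_prevalences[[prev$copathology[j]]],
          if (length(elig)) prev$present[j] / length(elig) else NA_real_,
          length(elig))
  }
  do.call(rbind, rows)
}
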