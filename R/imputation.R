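#' Interpolate missing retinopathy grades within patients
#'
#' Internal runs of missing grades flanked by two observed sub-STR grades
#' are filled: equal flanks fill with that grade; differing flanks fill
#' each missing visit with a draw from a continuous uniform between the two
#' flanking grades, rounded to the nearest integer (half away from zero).
#' Runs whose right flank is an STR grade (>= 3) are left missing: they are
#' the onset gap handled by [assign_str_onset()]. Runs after the first STR
#' grade and leading/trailing runs are also left untouched.
#'
#' One global seed governs the stochastic fills, split into per-patient
#' substreams (derived from a hash of the patient id) so results do not
#' depend on which other patients are present.
#'
#' @param cohort A `retscreen_cohort`.
#' @param seed Integer seed.
#' @return The cohort with interpolated grades; non-missing values are
#'   never altered.
#' @export
interpolate_grades <- function(cohort, seed = 1L) {
  fac <- factor(cohort$patient_id, levels = unique(cohort$patient_id))
  parts <- split(seq_len(nrow(cohort)), fac)
  grade <- cohort$grade
  for (pid in names(parts)) {
    rows <- parts[[pid]]
    g <- grade[rows]
    obs <- which(!is.na(g))
    if (length(obs) < 2L) next
    seeded <- FALSE
    for (k in seq_len(length(obs) - 1L)) {
      a_i <- obs[k]; b_i <- obs[k + 1L]
      if (b_i - a_i < 2L) next
      a <- g[a_i]; b <- g[b_i]
      if (a >= 3L || b >= 3L) next        # onset gap / post-STR: scenario territory
      gap <- (a_i + 1L):(b_i - 1L)
      if (a == b) {
        g[gap] <- a
      } else {
        if (!seeded) { set.seed(patient_substream(seed, pid)); seeded <- TRUE }
        u <- runif(length(gap), min(a, b), max(a, b))
        g[gap] <- as.integer(round_half_up(u))
      }
    }
    grade[rows] <- g
  }
  cohort$grade <- grade
  cohort
}

# deterministic per-patient substream seed below 2^31, with multiplicative
# mixing so that consecutive patient ids land on well-separated seeds
patient_substream <- function(seed, patient_id) {
  codes <- utf8ToInt(patient_id)
  h <- sum(codes * seq_along(codes) * 131) %% 65011
  as.integer((as.numeric(seed) + h * 33029) %% .Machine$integer.max)
}

#' Impute missing covariates by grade-conditional means
#'
#' Each missing HbA1c, systolic BP or diabetes-duration value is replaced
#' by the cohort-wide mean of that variable over visits sharing the same
#' (possibly interpolated) retinopathy grade. Visits whose grade is itself
#' missing, and grade strata without any observed value, fall back to the
#' overall mean (with a warning for empty strata).
#'
#' @param cohort A `retscreen_cohort`, ideally after [interpolate_grades()].
#' @return The cohort with covariates completed; observed values untouched.
#' @export
impute_covariates <- function(cohort) {
  for (col in c("hba1c_mmol_mol", "sbp_mmhg", "duration_years")) {
    x <- cohort[[col]]
    if (!anyNA(x)) next
    overall <- mean(x, na.rm = TRUE)
    if (!is.finite(overall))
      stop(sprintf("no observed values of %s anywhere in the cohort", col), call. = FALSE)
    stratum_mean <- tapply(x, cohort$grade, mean, na.rm = TRUE)
    fill <- overall
    miss <- which(is.na(x))
    g_miss <- as.character(cohort$grade[miss])
    m <- stratum_mean[g_miss]
    empty <- !is.na(g_miss) & !is.finite(m)
    if (any(empty, na.rm = TRUE))
      warning(sprintf("grade stratum(s) %s have no observed %s; falling back to overall mean",
                      paste(unique(g_miss[empty]), collapse = ", "), col), call. = FALSE)
    m[is.na(g_miss) | !is.finite(m)] <- fill
    x[miss] <- as.numeric(m)
    cohort[[col]] <- x
  }
  cohort
}

#' Assign STR onset times under a progression scenario
#'
#' For each patient whose grades reach STR (>= 3): let `T` be the time of
#' the first observed STR grade and `S` the last earlier visit with an
#' observed (sub-STR) grade. Under the `"fast"` progression assumption STR
#' is taken to have developed at the first possible time point, the first
#' missing-grade visit after `S`; under `"slow"`, at the last possible time
#' point, `T` itself. With no missing-grade gap both scenarios return `T`.
#' Patients never reaching STR get `NA`.
#'
#' @param cohort A `retscreen_cohort` after [interpolate_grades()].
#' @param scenario `"fast"` or `"slow"`.
#' @return Data frame with columns `patient_id`, `onset_months` (`NA` for
#'   non-STR patients) and `str_visit_months` (time of the first observed
#'   STR grade).
#' @export
assign_str_onset <- function(cohort, scenario = c("fast", "slow")) {
  scenario <- match.arg(scenario)
  fac <- factor(cohort$patient_id, levels = unique(cohort$patient_id))
  parts <- split(seq_len(nrow(cohort)), fac)
  ids <- names(parts)
  onset <- rep(NA_real_, length(parts))
  str_t <- rep(NA_real_, length(parts))
  for (j in seq_along(parts)) {
    rows <- parts[[j]]
    g <- cohort$grade[rows]
    t <- cohort$t_months[rows]
    obs <- which(!is.na(g))
    i3 <- obs[which(g[obs] >= 3L)[1]]
    if (is.na(i3) || !length(i3)) next
    if (obs[1] == i3)
      stop(sprintf("patient %s has STR at the first observed grade; baseline-STR patients must be excluded upstream",
                   ids[j]), call. = FALSE)
    s_i <- max(obs[obs < i3])
    str_t[j] <- t[i3]
    onset[j] <- if (scenario == "slow" || i3 - s_i == 1L) t[i3] else t[s_i + 1L]
  }
  data.frame(patient_id = ids, onset_months = onset, str_visit_months = str_t,
             stringsAsFactors = FALSE)
}

#' Run the full imputation chain under a scenario
#'
#' Grades are interpolated first, covariates then imputed conditional on
#' the (possibly interpolated) grades, and STR onsets assigned under the
#' chosen fast/slow progression scenario.
#'
#' @param cohort A selected `retscreen_cohort`.
#' @param scenario `"fast"` or `"slow"` STR-progression assumption.
#' @param seed Seed for the stochastic grade fills.
#' @return A list of class `imputed_cohort`: `cohort` (completed data),
#'   `onsets` (from [assign_str_onset()]), `scenario`, `seed`.
#' @export
impute_cohort <- function(cohort, scenario = c("fast", "slow"), seed = 1L) {
  scenario <- match.arg(scenario)
  out <- interpolate_grades(cohort, seed = seed)
  out <- impute_covariates(out)
  onsets <- assign_str_onset(out, scenario)
  structure(list(cohort = out, onsets = onsets, scenario = scenario, seed = seed),
            class = "imputed_cohort")
}

#' @export
print.imputed_cohort <- function(x, ...) {
  cat(sprintf("Imputed cohort (%s STR progression): %d patients, %d STR cases\n",
              x$scenario, length(unique(x$cohort$patient_id)),
              sum(!is.na(x$onsets$onset_months))))
  invisible(x)
}
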