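#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a Dutch primary-care type 2 diabetes screening cohort:
#' roughly annual visits over 0--18 years of follow-up, a baseline
#' retinopathy grade mix of 93.8/5.1/1.1% over grades 0/1/2, per-grade
#' covariate distributions (HbA1c, systolic BP, age, diabetes duration),
#' and routine-care missingness (12.2% of grade records in patients who
#' never develop sight-threatening retinopathy, a masked pre-onset gap in
#' 22% of STR cases, 1--2% of covariate values). The STR-onset hazard is a
#' Weibull proportional-hazards model over the same covariates the interval
#' engine uses, so the generating parameters are recoverable from the truth
#' channel.
#'
#' @param n_patients Number of patients (>= 1).
#' @param follow_up_years_range Range of per-patient follow-up, years.
#' @param visit_spacing_months Spacing of scheduled visits, months.
#' @param baseline_grade_probs Probabilities of baseline grades 0, 1, 2
#'   (must sum to 1).
#' @param covariates Per-grade baseline distributions: a list with
#'   `hba1c_mean`, `hba1c_sd`, `sbp_mean`, `sbp_sd`, `age_mean`, `age_sd`
#'   (length-3 vectors, grades 0/1/2), and `duration_median`,
#'   `duration_iqr` (length-3 vector / 2x3 matrix) for the log-normal
#'   diabetes-duration distribution.
#' @param male_fraction Probability of male sex per baseline grade.
#' @param progression_params A [risk_model_params()] object: the true
#'   STR-onset hazard of the generated data.
#' @param grade_drift Annual probability scale of sub-STR grade progression
#'   (0 to 1 transitions; 1 to 2 transitions use half of it).
#' @param pre_str_ramp_months Length of the pre-onset retinopathy ramp:
#'   visits within this window before STR onset show at least grade 1 (at
#'   least grade 2 in the final year), reflecting that severe retinopathy
#'   develops out of milder grades.
#' @param covariate_walk_sd Annual random-walk SDs for `hba1c` and `sbp`.
#' @param missingness Fractions: `grade_non_str` (grade records of non-STR
#'   patients), `str_case` (fraction of STR cases with a masked pre-onset
#'   gap), `duration`, `hba1c`, `sbp` (covariate records).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          follow_up_years_range = c(0, 18),
                          visit_spacing_months = 12L,
                          baseline_grade_probs = c(0.938, 0.051, 0.011),
                          covariates = list(
                            hba1c_mean = c(55.7, 60.9, 70.4),
                            hba1c_sd = c(17.1, 19.7, 19.4),
                            sbp_mean = c(142.5, 145.2, 149.1),
                            sbp_sd = c(20.1, 22.3, 20.5),
                            age_mean = c(60.3, 61.2, 60.0),
                            age_sd = c(10.8, 10.8, 9.9),
                            duration_median = c(0.8, 2.11, 5.8),
                            duration_iqr = rbind(c(0.2, 2.9), c(0.3, 7.1), c(1.5, 13.6))),
                          male_fraction = c(0.539, 0.546, 0.627),
                          progression_params = default_progression_params(),
                          grade_drift = 0.03,
                          pre_str_ramp_months = 36,
                          covariate_walk_sd = c(hba1c = 4, sbp = 6),
                          missingness = c(grade_non_str = 0.122, str_case = 0.22,
                                          duration = 0.010, hba1c = 0.017, sbp = 0.020),
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop_config("n_patients", "must be a single integer >= 1")
  if (length(follow_up_years_range) != 2L || follow_up_years_range[1] < 0 ||
      diff(follow_up_years_range) < 0)
    stop_config("follow_up_years_range", "must be an increasing non-negative pair")
  if (abs(sum(baseline_grade_probs) - 1) > 1e-12 || any(baseline_grade_probs < 0) ||
      length(baseline_grade_probs) != 3L)
    stop_config("baseline_grade_probs", "must be 3 non-negative probabilities summing to 1")
  miss_names <- c("grade_non_str", "str_case", "duration", "hba1c", "sbp")
  missingness <- unlist(missingness)
  if (!all(miss_names %in% names(missingness)) ||
      any(missingness[miss_names] < 0) || any(missingness[miss_names] > 1))
    stop_config("missingness", sprintf("must contain fractions in [0,1] named %s",
                                       paste(miss_names, collapse = ", ")))
  if (any(unlist(covariates[c("hba1c_sd", "sbp_sd", "age_sd")]) <= 0))
    stop_config("covariates", "standard deviations must be positive")
  if (any(male_fraction < 0) || any(male_fraction > 1))
    stop_config("male_fraction", "must be probabilities in [0,1]")
  if (!inherits(progression_params, "risk_model_params"))
    stop_config("progression_params", "must be a risk_model_params object")
  if (visit_spacing_months < 1)
    stop_config("visit_spacing_months", "must be at least 1 month")
  structure(list(n_patients = as.integer(n_patients),
                 follow_up_years_range = follow_up_years_range,
                 visit_spacing_months = as.integer(visit_spacing_months),
                 baseline_grade_probs = baseline_grade_probs,
                 covariates = covariates,
                 male_fraction = rep_len(male_fraction, 3L),
                 progression_params = progression_params,
                 grade_drift = grade_drift,
                 pre_str_ramp_months = pre_str_ramp_months,
                 covariate_walk_sd = covariate_walk_sd,
                 missingness = missingness[miss_names],
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default true STR-onset hazard of the generator
#'
#' Same Weibull proportional-hazards family as the interval engine, with a
#' lower baseline hazard (intercept -26.0 vs -23.2), so that roughly 3% of
#' an analysis cohort develops STR over follow-up, the order of magnitude
#' seen in well-controlled primary-care populations, and markedly less risk
#' than the interval engine predicts (screening models calibrated on
#' higher-incidence populations over-predict in such cohorts).
#'
#' @return A `risk_model_params` object.
#' @export
default_progression_params <- function() {
  risk_model_params(shape = 1.3,
                    coefficients = c(intercept = -26.0, male = 0.2,
                                     log_duration = 0.3, log_hba1c = 2.0,
                                     log_sbp = 1.5, retinopathy_present = 1.2))
}

# log-normal (meanlog, sdlog) matched to a median and IQR
lnorm_from_median_iqr <- function(median, iqr_lo, iqr_hi) {
  meanlog <- log(median)
  sdlog <- log(iqr_hi / iqr_lo) / (2 * stats::qnorm(0.75))
  c(meanlog = meanlog, sdlog = max(sdlog, 1e-6))
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws baseline grades, covariates and follow-up, evolves covariates as a
#' small random walk and sub-STR grades (0--2) as a monotone discrete-time
#' Markov chain with HbA1c-dependent upward drift, draws the latent STR
#' onset time from the configured Weibull hazard at baseline covariates,
#' and records STR (grade >= 3, escalating thereafter) from the first visit
#' at or after the latent onset. Complete data are generated first; grades
#' and covariates are then masked per the configured missingness, the
#' complete copy being retained as a truth channel.
#'
#' @param config A [cohort_config()] object.
#' @return A `retscreen_cohort` data frame with attributes `truth` (the
#'   complete-data copy), `onset_true` (per patient: `onset_months` on the
#'   visit grid, `onset_latent` in continuous months, `NA` when STR is not
#'   reached in follow-up), `patients` (baseline table incl. age) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n <- config$n_patients
  cv <- config$covariates
  spacing <- config$visit_spacing_months

  fu_months <- as.integer(floor(runif(n, config$follow_up_years_range[1],
                                      config$follow_up_years_range[2]) * 12))
  n_visits <- fu_months %/% spacing + 1L
  g0 <- sample(0:2, n, replace = TRUE, prob = config$baseline_grade_probs)
  sex <- ifelse(rbinom(n, 1L, config$male_fraction[g0 + 1L]) == 1L, "male", "female")
  hba1c0 <- round(pmax(rnorm(n, cv$hba1c_mean[g0 + 1L], cv$hba1c_sd[g0 + 1L]), 20), 1)
  sbp0 <- round(pmax(rnorm(n, cv$sbp_mean[g0 + 1L], cv$sbp_sd[g0 + 1L]), 80), 1)
  age0 <- round(pmax(rnorm(n, cv$age_mean[g0 + 1L], cv$age_sd[g0 + 1L]), 25), 1)
  ln <- vapply(1:3, function(k) lnorm_from_median_iqr(cv$duration_median[k],
                                                      cv$duration_iqr[k, 1],
                                                      cv$duration_iqr[k, 2]),
               numeric(2))
  dur0 <- round(pmax(rlnorm(n, ln["meanlog", g0 + 1L], ln["sdlog", g0 + 1L]), 0.1), 2)

  # latent STR onset from the configured hazard at baseline covariates
  lp <- linear_predictor(data.frame(sex = sex, duration_years = dur0,
                                    hba1c_mmol_mol = hba1c0, sbp_mmhg = sbp0,
                                    retinopathy_present = g0 >= 1L),
                         config$progression_params)
  u <- runif(n)
  onset_latent <- (-log(u) / exp(lp))^(1 / config$progression_params$shape)
  # recorded onset = first visit at or after the latent time, if within follow-up
  onset_visit <- ceiling(onset_latent / spacing) * spacing
  last_visit <- (n_visits - 1L) * spacing
  onset_months <- ifelse(onset_visit <= last_visit, onset_visit, NA_real_)

  # long skeleton
  pid <- sprintf("P%05d", seq_len(n))
  id_long <- rep(pid, n_visits)
  visit_no <- sequence(n_visits)
  t_long <- (visit_no - 1L) * spacing
  idx <- rep(seq_len(n), n_visits)

  # covariate random walks around baseline (no step at the first visit)
  step_scale <- sqrt(spacing / 12)
  z_h <- rnorm(length(idx), 0, config$covariate_walk_sd[["hba1c"]] * step_scale)
  z_s <- rnorm(length(idx), 0, config$covariate_walk_sd[["sbp"]] * step_scale)
  z_h[visit_no == 1L] <- 0
  z_s[visit_no == 1L] <- 0
  hba1c <- round(pmax(hba1c0[idx] + ave(z_h, idx, FUN = cumsum), 20), 1)
  sbp <- round(pmax(sbp0[idx] + ave(z_s, idx, FUN = cumsum), 80), 1)
  duration <- round(dur0[idx] + t_long / 12, 2)

  # sub-STR grade chain: monotone on {0,1,2}, upward drift grows with HbA1c
  grade <- integer(length(idx))
  grade[visit_no == 1L] <- g0
  p_step <- config$grade_drift * (spacing / 12)
  for (v in 2L:max(n_visits)) {
    cur <- which(visit_no == v)
    prev <- cur - 1L
    p_up <- pmin(p_step * exp(0.02 * (hba1c[prev] - 55)), 0.5)
    p_up[grade[prev] >= 1L] <- p_up[grade[prev] >= 1L] / 2
    up <- rbinom(length(cur), 1L, p_up)
    grade[cur] <- pmin(grade[prev] + up, 2L)
  }
  # overwrite with STR grades from recorded onset onward, escalating slowly
  # (grade 3 at the first STR visit, +1 with prob 0.15 per later visit, cap 5)
  row0 <- c(0L, cumsum(n_visits))[seq_len(n)]  # row offset per patient
  post <- !is.na(onset_months[idx]) & t_long >= onset_months[idx]
  esc <- rbinom(length(idx), 1L, 0.15)
  esc[!post] <- 0L
  cum_esc <- ave(esc, idx, FUN = cumsum)
  str_i <- which(!is.na(onset_months))
  first_str_row <- row0[str_i] + onset_months[str_i] %/% spacing + 1L
  base_esc <- numeric(n)
  base_esc[str_i] <- cum_esc[first_str_row]
  grade[post] <- pmin(3L + cum_esc[post] - base_esc[idx][post], 5L)
  # pre-onset retinopathy ramp: severe retinopathy is preceded by milder
  # grades, so visits in the run-up to onset show grade >= 1 (>= 2 in the
  # final year) -- the signal screening policies react to. Baseline visits
  # are left as sampled so the entry cross-section matches the configured
  # grade mix.
  ramp <- !is.na(onset_months[idx]) & t_long > 0 & t_long < onset_months[idx] &
    t_long >= onset_months[idx] - config$pre_str_ramp_months
  grade[ramp] <- pmax(grade[ramp], 1L)
  ramp2 <- ramp & t_long >= onset_months[idx] - 12
  grade[ramp2] <- pmax(grade[ramp2], 2L)

  truth <- data.frame(patient_id = id_long, sex = sex[idx], t_months = t_long,
                      grade = grade, hba1c_mmol_mol = hba1c, sbp_mmhg = sbp,
                      duration_years = duration, follow_up_months = fu_months[idx],
                      stringsAsFactors = FALSE)

  # masking: complete data stay in the truth channel
  masked <- truth
  is_str_case <- !is.na(onset_months)
  non_str_rows <- !is_str_case[idx]
  drop_grade <- non_str_rows & runif(length(idx)) < config$missingness[["grade_non_str"]]
  masked$grade[drop_grade] <- NA_integer_
  # STR cases: for a fraction, mask a run of grades right before the first
  # STR visit (never the first visit, so baseline stays observable)
  gap_cases <- which(is_str_case & runif(n) < config$missingness[["str_case"]])
  for (i in gap_cases) {
    onset_v <- onset_months[i] %/% spacing + 1L  # visit number of first STR visit
    n_pre <- onset_v - 1L
    if (n_pre < 2L) next                         # keep at least the first grade
    len <- sample.int(min(3L, n_pre - 1L), 1L)
    masked$grade[row0[i] + (onset_v - len):(onset_v - 1L)] <- NA_integer_
  }
  for (col in c("duration", "hba1c", "sbp")) {
    colname <- c(duration = "duration_years", hba1c = "hba1c_mmol_mol",
                 sbp = "sbp_mmhg")[[col]]
    masked[[colname]][runif(length(idx)) < config$missingness[[col]]] <- NA_real_
  }

  out <- as_cohort(masked)
  attr(out, "truth") <- as_cohort(truth)
  attr(out, "onset_true") <- data.frame(patient_id = pid,
                                        onset_months = onset_months,
                                        onset_latent = onset_latent,
                                        follow_up_months = fu_months,
                                        stringsAsFactors = FALSE)
  attr(out, "patients") <- data.frame(patient_id = pid, sex = sex,
                                      baseline_grade = g0, age_years = age0,
                                      stringsAsFactors = FALSE)
  attr(out, "config") <- config
  out
}

#' Complete-data truth channel of a generated cohort
#'
#' @param cohort A cohort produced by [generate_cohort()] (or read back with
#'   its `.truth.csv` sibling).
#' @return The unmasked `retscreen_cohort`; identical to the masked cohort
#'   wherever the masked value is present. Carries over the `onset_true`
#'   attribute when available.
#' @export
truth_channel <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr))
    stop("cohort has no truth channel; it was not produced by generate_cohort()",
         call. = FALSE)
  attr(tr, "onset_true") <- attr(cohort, "onset_true")
  tr
}

#' Fit the STR-onset hazard on complete data
#'
#' Estimates the generating Weibull proportional-hazards parameters from a
#' truth-channel cohort by maximum likelihood ([survival::survreg()] with a
#' Weibull AFT parameterisation, mapped back to the proportional-hazards
#' scale: shape `p = 1/scale`, `beta = -gamma/scale`). Times are the latent
#' onset times right-censored at end of follow-up. Used to check parameter
#' recovery of the generator.
#'
#' @param cohort A cohort with truth channel and `onset_true` attribute, or
#'   the truth channel itself.
#' @return A `risk_model_params` object with the fitted values; the
#'   underlying `survreg` fit is attached as attribute `fit`.
#' @export
fit_str_hazard <- function(cohort) {
  onset <- attr(cohort, "onset_true")
  if (is.null(onset))
    stop("cohort carries no onset_true attribute; generate it with generate_cohort()",
         call. = FALSE)
  tr <- if (is.null(attr(cohort, "truth"))) cohort else truth_channel(cohort)
  base <- tr[tr$t_months == ave(tr$t_months, tr$patient_id, FUN = min), ]
  base <- base[match(onset$patient_id, base$patient_id), ]
  status <- as.integer(onset$onset_latent <= onset$follow_up_months)
  time <- pmax(pmin(onset$onset_latent, onset$follow_up_months), 1e-3)
  dat <- data.frame(time = time, status = status,
                    male = as.integer(base$sex == "male"),
                    log_duration = log(base$duration_years),
                    log_hba1c = log(base$hba1c_mmol_mol),
                    log_sbp = log(base$sbp_mmhg),
                    ret = as.integer(base$grade >= 1L))
  fit <- survival::survreg(survival::Surv(time, status) ~ male + log_duration +
                             log_hba1c + log_sbp + ret,
                           data = dat, dist = "weibull")
  p <- 1 / fit$scale
  beta <- -stats::coef(fit) / fit$scale
  est <- risk_model_params(shape = p,
                           coefficients = c(intercept = unname(beta[["(Intercept)"]]),
                                            male = unname(beta[["male"]]),
                                            log_duration = unname(beta[["log_duration"]]),
                                            log_hba1c = unname(beta[["log_hba1c"]]),
                                            log_sbp = unname(beta[["log_sbp"]]),
                                            retinopathy_present = unname(beta[["ret"]])))
  attr(est, "fit") <- fit
  est
}
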