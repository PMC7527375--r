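#' @name screening_sim
#' @title Event-driven screening simulation
#' @description
#' Replays each patient's (imputed) history under a screening policy.
#' Screens start at baseline (t = 0) and are scheduled iteratively: the
#' next screen falls one policy interval after the current one and, by
#' default, is carried out at the next attended visit at or after that date
#' (`align_to_visits = TRUE`) -- retinopathy screening in this setting is
#' embedded in routine annual diabetes care, so sub-annual model intervals
#' are realised as annual screens. Set `align_to_visits = FALSE` for
#' free-running schedules between visits. A screen beyond the end of
#' follow-up (or beyond the last attended visit, under alignment) is not
#' performed. The grade observed
#' at a screen is the grade trajectory evaluated at the latest visit at or
#' before the screen (STR is observed whenever the screen falls at or after
#' the STR onset); covariates are carried forward the same way (LOCF).
#' Screening stops at referral (STR observed) or end of follow-up.
#' Detection time is the first screen at or after onset; a diagnosis is
#' delayed when detection falls strictly after onset, with delay =
#' detection - onset. An onset with no subsequent in-window screen counts
#' as delayed with the delay censored at end of follow-up (flag
#' `censor_undetected`).
NULL

# per-patient precomputation shared across policies and margins
prep_patient <- function(rows, params = NULL) {
  t <- rows$t_months
  g <- rows$grade
  # observed-grade trajectory: LOCF over non-missing grades, leading visits
  # fall back to the first observed grade
  obs <- which(!is.na(g))
  if (!length(obs)) stop("patient ", rows$patient_id[1], " has no observed grade", call. = FALSE)
  last <- cummax(ifelse(is.na(g), 0L, seq_along(g)))
  gfill <- ifelse(last > 0L, g[pmax(last, 1L)], g[obs[1]])
  ret <- gfill >= 1L & gfill < 3L
  out <- list(patient_id = rows$patient_id[1], t = t, gfill = gfill,
              fu = rows$follow_up_months[1],
              sex = rows$sex[1], dur = rows$duration_years,
              hba1c = rows$hba1c_mmol_mol, sbp = rows$sbp_mmhg, ret = ret)
  if (!is.null(params))
    out$lp <- linear_predictor(data.frame(sex = rows$sex,
                                          duration_years = rows$duration_years,
                                          hba1c_mmol_mol = rows$hba1c_mmol_mol,
                                          sbp_mmhg = rows$sbp_mmhg,
                                          retinopathy_present = ret),
                               params)
  out
}

# first visit time at or after the scheduled date, or NA when none remains
next_visit_at <- function(t_vis, scheduled) {
  pos <- findInterval(scheduled - 0.5, t_vis) + 1L
  if (pos > length(t_vis)) NA_real_ else t_vis[pos]
}

# one patient under one policy; policy is a make_policy() closure or any
# function(state) -> policy_decision
sim_core <- function(prep, policy, onset, censor_undetected = TRUE,
                     align_to_visits = TRUE) {
  if (!is.na(onset) && onset <= 0)
    stop("patient ", prep$patient_id,
         ": STR onset at or before the first screen; baseline-STR patients are excluded upstream",
         call. = FALSE)
  type <- attr(policy, "policy_name") %||% "custom"
  margin <- attr(policy, "risk_margin")
  params <- attr(policy, "params")
  t <- 0
  screens <- numeric(0)
  grades_seen <- integer(0)
  detection <- NA_real_
  repeat {
    screens <- c(screens, t)
    if (!is.na(onset) && t >= onset) { detection <- t; break }
    j <- findInterval(t, prep$t)
    g <- prep$gfill[j]
    grades_seen <- c(grades_seen, g)
    if (g >= 3L) break   # defensive: STR grade implies onset <= t
    interval <- switch(type,
      annual = 12,
      guideline = {
        n <- length(grades_seen)
        if (g >= 1L) 12
        else if (n >= 2L && grades_seen[n - 1L] == 0L) 36 else 24
      },
      personalised = interval_from_lp(prep$lp[j], margin, params),
      { # custom policy via the public state interface
        state <- list(grades = grades_seen,
                      profile = data.frame(sex = prep$sex,
                                           duration_years = prep$dur[j],
                                           hba1c_mmol_mol = prep$hba1c[j],
                                           sbp_mmhg = prep$sbp[j],
                                           retinopathy_present = prep$ret[j]))
        d <- policy(state)
        if (d$action == "refer") break
        d$interval_months
      })
    if (is.null(interval)) break
    tn <- t + interval
    if (align_to_visits) tn <- next_visit_at(prep$t, tn)
    if (is.na(tn) || tn > prep$fu) break
    t <- tn
  }
  str_case <- !is.na(onset)
  censored <- str_case && is.na(detection)
  delayed <- str_case && (censored || detection > onset)
  delay <- if (!delayed) 0
           else if (!censored) detection - onset
           else if (censor_undetected) prep$fu - onset
           else NA_real_
  list(patient_id = prep$patient_id, screen_times = screens,
       screens_count = length(screens), str_case = str_case,
       delayed = delayed, delay_months = delay, censored = censored,
       detection_time_months = detection)
}

#' Simulate one patient under a policy
#'
#' @param history One patient's visits (rows of an imputed
#'   `retscreen_cohort`).
#' @param onset_months STR onset from [assign_str_onset()], or `NA`.
#' @param policy A policy function, e.g. from [make_policy()].
#' @param censor_undetected Count an onset with no later in-window screen
#'   as delayed with delay censored at end of follow-up (default).
#' @param align_to_visits Carry out scheduled screens at the next attended
#'   visit (default; see [screening_sim]).
#' @return One-row data frame with `patient_id`, `screen_times` (list
#'   column), `screens_count`, `str_case`, `delayed`, `delay_months`,
#'   `censored`, `detection_time_months`.
#' @export
simulate_patient <- function(history, onset_months, policy,
                             censor_undetected = TRUE, align_to_visits = TRUE) {
  params <- attr(policy, "params")
  prep <- prep_patient(history, params = params)
  res <- sim_core(prep, policy, onset_months, censor_undetected, align_to_visits)
  outcome_row(res)
}

outcome_row <- function(res) {
  data.frame(patient_id = res$patient_id,
             screen_times = I(list(res$screen_times)),
             screens_count = res$screens_count,
             str_case = res$str_case,
             delayed = res$delayed,
             delay_months = res$delay_months,
             censored = res$censored,
             detection_time_months = res$detection_time_months,
             stringsAsFactors = FALSE)
}

#' Simulate a whole cohort under a policy
#'
#' @param cohort An imputed `retscreen_cohort` (complete covariates).
#' @param onsets Data frame from [assign_str_onset()] (or an
#'   `imputed_cohort`'s `$onsets`).
#' @param policy A policy function from [make_policy()], or its name
#'   (`"annual"`, `"guideline"`, `"personalised"`).
#' @param risk_margin,params Used when `policy = "personalised"`.
#' @inheritParams simulate_patient
#' @return List of class `screening_result`: `outcomes` (one row per
#'   patient, as in [simulate_patient()]) and `summary` (delayed count and
#'   percentage of STR cases, delay mean/median/IQR/max over delayed cases,
#'   total screens).
#' @export
simulate_cohort <- function(cohort, onsets, policy, risk_margin = NULL,
                            params = NULL, censor_undetected = TRUE,
                            align_to_visits = TRUE) {
  if (is.character(policy))
    policy <- make_policy(policy, risk_margin = risk_margin, params = params)
  pparams <- attr(policy, "params")
  fac <- factor(cohort$patient_id, levels = unique(cohort$patient_id))
  parts <- split(seq_len(nrow(cohort)), fac)
  onset_of <- setNames(onsets$onset_months, onsets$patient_id)
  rows <- lapply(names(parts), function(pid) {
    prep <- prep_patient(cohort[parts[[pid]], ], params = pparams)
    onset <- if (pid %in% names(onset_of)) onset_of[[pid]] else NA_real_
    outcome_row(sim_core(prep, policy, onset, censor_undetected, align_to_visits))
  })
  outcomes <- do.call(rbind, rows)
  structure(list(outcomes = outcomes, summary = summarise_outcomes(outcomes),
                 policy = attr(policy, "policy_name") %||% "custom"),
            class = "screening_result")
}

summarise_outcomes <- function(outcomes) {
  str_cases <- sum(outcomes$str_case)
  delayed <- sum(outcomes$delayed)
  d <- outcomes$delay_months[outcomes$delayed]
  list(n = nrow(outcomes),
       total_screens = sum(outcomes$screens_count),
       str_cases = str_cases,
       delayed = delayed,
       delayed_pct = if (str_cases > 0) pct(delayed, str_cases) else NA_real_,
       delay_mean = if (length(d)) mean(d) else NA_real_,
       delay_median = if (length(d)) median(d) else NA_real_,
       delay_iqr = if (length(d)) unname(quantile(d, c(0.25, 0.75))) else c(NA_real_, NA_real_),
       delay_max = if (length(d)) max(d) else NA_real_)
}

#' @export
print.screening_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Screening simulation (%s policy): %d patients, %d screens\n",
              x$policy, s$n, s$total_screens))
  if (s$str_cases > 0)
    cat(sprintf("  STR cases: %d; delayed diagnoses: %d (%.1f%%); median delay %.1f months (max %.0f)\n",
                s$str_cases, s$delayed, s$delayed_pct,
                s$delay_median %||% NA, s$delay_max %||% NA))
  else cat("  no STR cases in follow-up\n")
  invisible(x)
}

# tight inner loop for the personalised policy over a margin grid;
# returns per-margin discounted screen weight, screen count, delayed flag,
# delay months (see margin_grid_analysis)
sim_pers_margins <- function(prep, onset, margins, params, disc_rate,
                             censor_undetected = TRUE, align_to_visits = TRUE) {
  inv_p <- 1 / params$shape
  lam <- -log1p(-margins)
  lo <- params$min_interval_months
  hi <- params$max_interval_months
  elp <- exp(-prep$lp)
  m <- length(margins)
  disc <- numeric(m); scr <- integer(m); del <- logical(m); dmon <- numeric(m)
  detected <- logical(m)
  for (k in seq_len(m)) {
    t <- 0; nscr <- 0L; dsum <- 0; detection <- NA_real_
    repeat {
      nscr <- nscr + 1L
      dsum <- dsum + (1 + disc_rate)^(-t / 12)
      if (!is.na(onset) && t >= onset) { detection <- t; break }
      j <- findInterval(t, prep$t)
      iv <- if (lam[k] <= 0) lo else {
        ti <- (lam[k] * elp[j])^inv_p
        floor(min(max(ti, lo), hi))
      }
      if (params$snap_to_menu) iv <- params$menu[max(findInterval(iv, params$menu), 1L)]
      tn <- t + iv
      if (align_to_visits) tn <- next_visit_at(prep$t, tn)
      if (is.na(tn) || tn > prep$fu) break
      t <- tn
    }
    disc[k] <- dsum; scr[k] <- nscr
    str_case <- !is.na(onset)
    censored <- str_case && is.na(detection)
    del[k] <- str_case && (censored || detection > onset)
    dmon[k] <- if (!del[k]) 0
               else if (!censored) detection - onset
               else if (censor_undetected) prep$fu - onset else NA_real_
    detected[k] <- !is.na(detection)
  }
  list(disc = disc, screens = scr, delayed = del, delay = dmon, detected = detected)
}

# per-patient matrices over a margin grid (personalised policy) plus
# per-patient vectors for the annual and guideline policies; the
# workhorse behind margin_grid_analysis() and bootstrap_two_stage()
cohort_margin_stats <- function(cohort, onsets, margins, params,
                                disc_rate = 0.04, censor_undetected = TRUE,
                                align_to_visits = TRUE) {
  fac <- factor(cohort$patient_id, levels = unique(cohort$patient_id))
  parts <- split(seq_len(nrow(cohort)), fac)
  ids <- names(parts)
  onset_of <- setNames(onsets$onset_months, onsets$patient_id)
  n <- length(ids); m <- length(margins)
  D <- matrix(0, n, m); S <- matrix(0L, n, m); L <- matrix(FALSE, n, m)
  DM <- matrix(0, n, m)
  ann <- gdl <- data.frame(disc = numeric(n), screens = integer(n),
                           delayed = logical(n), delay = numeric(n))
  str_case <- logical(n); fu_years <- numeric(n)
  disc_fn <- function(times) sum((1 + disc_rate)^(-times / 12))
  for (i in seq_along(ids)) {
    prep <- prep_patient(cohort[parts[[i]], ], params = params)
    onset <- if (ids[i] %in% names(onset_of)) onset_of[[ids[i]]] else NA_real_
    res <- sim_pers_margins(prep, onset, margins, params, disc_rate,
                            censor_undetected, align_to_visits)
    D[i, ] <- res$disc; S[i, ] <- res$screens; L[i, ] <- res$delayed
    DM[i, ] <- res$delay
    a <- sim_core(prep, make_policy("annual"), onset, censor_undetected,
                  align_to_visits)
    g <- sim_core(prep, make_policy("guideline"), onset, censor_undetected,
                  align_to_visits)
    ann$disc[i] <- disc_fn(a$screen_times); ann$screens[i] <- a$screens_count
    ann$delayed[i] <- a$delayed; ann$delay[i] <- a$delay_months
    gdl$disc[i] <- disc_fn(g$screen_times); gdl$screens[i] <- g$screens_count
    gdl$delayed[i] <- g$delayed; gdl$delay[i] <- g$delay_months
    str_case[i] <- !is.na(onset)
    fu_years[i] <- prep$fu / 12
  }
  list(patient_id = ids, margins = margins, disc = D, screens = S,
       delayed = L, delay = DM, annual = ann, guideline = gdl,
       str_case = str_case, fu_years = fu_years)
}
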