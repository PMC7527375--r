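# Independent oracles, deliberately written without reusing package internals.

# bisection inversion of the cumulative incidence (oracle for the analytic
# interval inversion, before clamping/discretisation)
bisect_interval <- function(profile, risk_margin, params, tol = 1e-10) {
  if (risk_margin <= 0) return(0)
  f <- function(t) cumulative_incidence(t, profile, params) - risk_margin
  lo <- 0; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = tol)$root
}

# month-by-month event loop replaying one patient under a policy function;
# an independent re-statement of the scheduling rules (screens embedded in
# the attended visits when align_to_visits is on)
brute_force_sim <- function(history, onset, policy, align_to_visits = TRUE) {
  t_vis <- history$t_months
  g <- history$grade
  obs <- which(!is.na(g))
  fu <- history$follow_up_months[1]
  grade_at <- function(m) {
    j <- max(c(0, which(t_vis <= m)))
    if (j == 0) return(g[obs[1]])
    jj <- obs[obs <= j]
    if (!length(jj)) g[obs[1]] else g[max(jj)]
  }
  screens <- integer(0)
  grades_seen <- integer(0)
  detection <- NA_real_
  next_screen <- 0
  m <- 0
  while (m <= fu) {
    if (m == next_screen) {
      screens <- c(screens, m)
      if (!is.na(onset) && m >= onset) { detection <- m; break }
      gm <- grade_at(m)
      grades_seen <- c(grades_seen, gm)
      if (gm >= 3L) break
      j <- max(c(1, which(t_vis <= m)))
      state <- list(grades = grades_seen,
                    profile = data.frame(sex = history$sex[1],
                                         duration_years = history$duration_years[j],
                                         hba1c_mmol_mol = history$hba1c_mmol_mol[j],
                                         sbp_mmhg = history$sbp_mmhg[j],
                                         retinopathy_present = gm >= 1L && gm < 3L))
      d <- policy(state)
      if (d$action == "refer") break
      next_screen <- m + d$interval_months
      if (align_to_visits) {
        cand <- t_vis[t_vis >= next_screen]
        next_screen <- if (length(cand)) min(cand) else fu + 1
      }
    }
    m <- m + 1
  }
  str_case <- !is.na(onset)
  censored <- str_case && is.na(detection)
  delayed <- str_case && (censored || detection > onset)
  delay <- if (!delayed) 0 else if (!censored) detection - onset else fu - onset
  list(screen_times = screens, screens_count = length(screens),
       delayed = delayed, delay_months = delay,
       detection_time_months = detection)
}
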