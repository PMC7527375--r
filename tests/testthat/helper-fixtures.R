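# hand-built cohort fixtures: one row per visit
make_visits <- function(patient_id, grades, sex = "female", t = NULL,
                        hba1c = 55, sbp = 140, duration0 = 2,
                        follow_up = NULL) {
  k <- length(grades)
  t <- t %||% seq(0L, by = 12L, length.out = k)
  data.frame(patient_id = patient_id, sex = sex, t_months = as.integer(t),
             grade = as.integer(grades),
             hba1c_mmol_mol = rep_len(hba1c, k), sbp_mmhg = rep_len(sbp, k),
             duration_years = duration0 + t / 12,
             follow_up_months = as.integer(follow_up %||% max(t)),
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  df <- do.call(rbind, list(...))
  retscreen:::as_cohort(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a moderate-risk profile used across tests
test_profile <- function(sex = "female", duration_years = 2,
                         hba1c_mmol_mol = 55, sbp_mmhg = 140,
                         retinopathy_present = FALSE) {
  data.frame(sex = sex, duration_years = duration_years,
             hba1c_mmol_mol = hba1c_mmol_mol, sbp_mmhg = sbp_mmhg,
             retinopathy_present = retinopathy_present)
}

# random profiles for property-style checks
random_profiles <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sex = sample(c("male", "female"), n, TRUE),
             duration_years = exp(runif(n, log(0.2), log(30))),
             hba1c_mmol_mol = runif(n, 35, 110),
             sbp_mmhg = runif(n, 100, 200),
             retinopathy_present = runif(n) < 0.3)
}
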