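#' Screening policy decisions
#'
#' A policy maps the state observed at a screen to either the next
#' screening interval or a referral. The state is a list with `grades`
#' (grades observed at the screens so far, last element = current screen)
#' and, for the personalised policy, `profile` (the covariates carried
#' forward to this screen; see [cumulative_incidence()] for the columns).
#'
#' All policies refer exactly when the current grade is >= 3 (STR, the
#' Dutch referral threshold).
#'
#' @param action `"screen_after"` or `"refer"`.
#' @param interval_months Next interval, present iff `action ==
#'   "screen_after"`.
#' @return An object of class `policy_decision`.
#' @export
policy_decision <- function(action = c("screen_after", "refer"),
                            interval_months = NA_real_) {
  action <- match.arg(action)
  if (action == "screen_after" && (!is.finite(interval_months) || interval_months < 1))
    stop("screen_after decisions need interval_months >= 1", call. = FALSE)
  structure(list(action = action,
                 interval_months = if (action == "screen_after") interval_months else NULL),
            class = "policy_decision")
}

current_grade <- function(state) {
  g <- state$grades[length(state$grades)]
  if (is.na(g))
    stop("policy invoked without an observed grade at the current screen", call. = FALSE)
  g
}

#' Annual screening policy
#'
#' Fixed 12-month intervals; referral at STR.
#'
#' @param state Policy state, see [policy_decision()].
#' @return A `policy_decision`.
#' @export
annual_policy <- function(state) {
  if (current_grade(state) >= 3L) policy_decision("refer")
  else policy_decision("screen_after", 12)
}

#' Dutch guideline screening policy
#'
#' Stratified 1--3 year intervals: no retinopathy at the first screen leads
#' to a 2-year interval; a second consecutive retinopathy-free screen
#' stretches it to 3 years; mild retinopathy (grades 1--2) leads to annual
#' screening; STR (grades 3--5) to referral. After a grade 1--2 screen, a
#' subsequent grade-0 screen restarts at 2 years (the 3-year interval
#' requires two consecutive retinopathy-free screens).
#'
#' @inheritParams annual_policy
#' @return A `policy_decision` with interval in \{12, 24, 36\} months.
#' @export
dutch_guideline_policy <- function(state) {
  g <- current_grade(state)
  if (g >= 3L) return(policy_decision("refer"))
  if (g >= 1L) return(policy_decision("screen_after", 12))
  n <- length(state$grades)
  if (n >= 2L && !is.na(state$grades[n - 1L]) && state$grades[n - 1L] == 0L)
    policy_decision("screen_after", 36)
  else policy_decision("screen_after", 24)
}

#' Personalised screening policy
#'
#' Referral at STR; otherwise the interval obtained by inverting the risk
#' model at the given risk margin for the covariates carried forward to the
#' current screen ([personalised_interval()]).
#'
#' @inheritParams annual_policy
#' @param risk_margin Accepted STR risk over the interval (fraction).
#' @param params A [risk_model_params()] object.
#' @return A `policy_decision` with interval within the model's clamps.
#' @export
personalised_policy <- function(state, risk_margin, params) {
  if (current_grade(state) >= 3L) return(policy_decision("refer"))
  if (is.null(state$profile))
    stop("personalised policy needs covariates in state$profile", call. = FALSE)
  policy_decision("screen_after",
                  personalised_interval(state$profile, risk_margin, params))
}

#' Construct a named policy function
#'
#' Convenience wrapper used by [simulate_cohort()] and the pipeline:
#' returns a `function(state)` closure tagged with the policy name so the
#' simulator can use its fast path.
#'
#' @param name `"annual"`, `"guideline"` or `"personalised"`.
#' @param risk_margin,params Passed to [personalised_policy()].
#' @return A policy function.
#' @export
make_policy <- function(name = c("annual", "guideline", "personalised"),
                        risk_margin = NULL, params = NULL) {
  name <- match.arg(name)
  fn <- switch(name,
               annual = annual_policy,
               guideline = dutch_guideline_policy,
               personalised = {
                 if (is.null(risk_margin) || is.null(params))
                   stop("personalised policy needs risk_margin and params", call. = FALSE)
                 force(risk_margin); force(params)
                 function(state) personalised_policy(state, risk_margin, params)
               })
  structure(fn, policy_name = name, risk_margin = risk_margin, params = params)
}
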