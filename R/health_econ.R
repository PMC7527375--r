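#' Health-economic parameters
#'
#' Cost ranges per category (2015 euros), discount rates and accounting
#' perspective. Defaults follow Dutch health-economic guidance: screening
#' costs 15.25--41.07 EUR per screen, travel costs 1.58--14.19 EUR,
#' productivity losses 2.63--16.62 EUR, with costs discounted at 4.0%/year
#' and effects at 1.5%/year. The healthcare perspective counts screening
#' costs only; the societal perspective adds travel and productivity.
#'
#' @param cost_ranges Named list of `c(min, max)` per category.
#' @param discount_rate_costs,discount_rate_effects Annual rates.
#' @param perspective `"healthcare"` or `"societal"`.
#' @param price_year Price year (informational).
#' @param gamma_fit `"quantile"` fits the PSA gamma distributions so the
#'   2.5%/97.5% quantiles reproduce `(min, max)`; `"moment"` matches mean
#'   `(min+max)/2` and SD `(max-min)/4` instead.
#' @return An object of class `econ_params` with the fitted [GammaCost]
#'   distributions in `$gamma`.
#' @export
econ_params <- function(cost_ranges = list(screening = c(15.25, 41.07),
                                           travel = c(1.58, 14.19),
                                           productivity = c(2.63, 16.62)),
                        discount_rate_costs = 0.04,
                        discount_rate_effects = 0.015,
                        perspective = c("healthcare", "societal"),
                        price_year = 2015,
                        gamma_fit = c("quantile", "moment")) {
  perspective <- match.arg(perspective)
  gamma_fit <- match.arg(gamma_fit)
  for (nm in names(cost_ranges)) {
    r <- cost_ranges[[nm]]
    if (length(r) != 2L || r[1] <= 0 || r[1] >= r[2])
      stop_config(paste0("cost_ranges$", nm), "must satisfy 0 < min < max")
  }
  if (discount_rate_costs < 0 || discount_rate_effects < 0)
    stop_config("discount_rate", "rates must be non-negative")
  gam <- lapply(names(cost_ranges), function(nm)
    fit_gamma_from_range(cost_ranges[[nm]][1], cost_ranges[[nm]][2],
                         category = nm, method = gamma_fit))
  names(gam) <- names(cost_ranges)
  structure(list(cost_ranges = cost_ranges, gamma = gam,
                 discount_rate_costs = discount_rate_costs,
                 discount_rate_effects = discount_rate_effects,
                 perspective = perspective, price_year = price_year),
            class = "econ_params")
}

#' @export
print.econ_params <- function(x, ...) {
  cat(sprintf("Health-economic parameters (%s perspective, %d euros)\n",
              x$perspective, x$price_year))
  for (nm in names(x$cost_ranges))
    cat(sprintf("  %-12s %6.2f - %6.2f EUR (gamma shape %.2f, rate %.3f, mean %.2f)\n",
                nm, x$cost_ranges[[nm]][1], x$cost_ranges[[nm]][2],
                x$gamma[[nm]]$shape, x$gamma[[nm]]$rate, x$gamma[[nm]]$mean))
  cat(sprintf("  discounting: costs %.1f%%/y, effects %.1f%%/y\n",
              100 * x$discount_rate_costs, 100 * x$discount_rate_effects))
  invisible(x)
}

#' @name GammaCost
#' @title Gamma cost-uncertainty distribution
#' @description A two-parameter gamma fitted to a cost range, used for the
#'   probabilistic sensitivity analysis draws; a list with `shape`, `rate`,
#'   `mean`, `category` and the target `min`/`max`.
NULL

#' Fit a gamma distribution to a cost range
#'
#' With `method = "quantile"` (default) the gamma's 2.5% and 97.5%
#' quantiles are made to equal `(min_cost, max_cost)`: the quantile ratio
#' `qgamma(.975, k, 1) / qgamma(.025, k, 1)` depends on the shape `k`
#' alone, so `k` is found by monotone root-finding on `log k` and the rate
#' then follows from either quantile. With `method = "moment"` the mean is
#' set to `(min+max)/2` and the SD to `(max-min)/4`.
#'
#' @param min_cost,max_cost Cost range, `0 < min < max`.
#' @param category Label carried along.
#' @param method `"quantile"` or `"moment"`.
#' @return A `gamma_cost` object (see [GammaCost]).
#' @export
fit_gamma_from_range <- function(min_cost, max_cost, category = "cost",
                                 method = c("quantile", "moment")) {
  method <- match.arg(method)
  if (!(min_cost > 0 && min_cost < max_cost))
    stop("cost range must satisfy 0 < min < max", call. = FALSE)
  if (method == "moment") {
    mu <- (min_cost + max_cost) / 2
    sdv <- (max_cost - min_cost) / 4
    shape <- (mu / sdv)^2
    rate <- mu / sdv^2
  } else {
    target <- max_cost / min_cost
    ratio_gap <- function(logk) {
      k <- exp(logk)
      qgamma(0.975, k, 1) / qgamma(0.025, k, 1) - target
    }
    sol <- tryCatch(
      uniroot(ratio_gap, lower = log(1e-3), upper = log(1e12),
              tol = .Machine$double.eps^0.6, maxiter = 2000L),
      error = function(e)
        stop(sprintf("gamma fit did not converge for range (%g, %g): %s",
                     min_cost, max_cost, conditionMessage(e)), call. = FALSE))
    shape <- exp(sol$root)
    rate <- qgamma(0.025, shape, 1) / min_cost
  }
  structure(list(shape = shape, rate = rate, mean = shape / rate,
                 category = category, min = min_cost, max = max_cost,
                 method = method),
            class = "gamma_cost")
}

#' Draw unit costs from a fitted gamma
#'
#' @param g A `gamma_cost` object.
#' @param n Number of draws.
#' @return Numeric vector of cost draws.
#' @export
rgamma_cost <- function(g, n) rgamma(n, shape = g$shape, rate = g$rate)

# point unit cost (gamma mean) per screen for a perspective
unit_cost_point <- function(econ, perspective = econ$perspective) {
  cats <- if (perspective == "societal") names(econ$gamma) else "screening"
  sum(vapply(econ$gamma[cats], `[[`, numeric(1), "mean"))
}

#' Discounted screening cost of simulated outcomes
#'
#' Sums, over each patient's screens, the perspective-appropriate unit cost
#' deflated at the cost discount rate: screening cost only under the
#' healthcare perspective, plus travel and productivity under the societal
#' perspective.
#'
#' @param outcomes Outcome data frame from [simulate_cohort()] (needs the
#'   `screen_times` list column).
#' @param unit_costs Named numeric vector of per-screen unit costs (e.g.
#'   `c(screening = 20)`, plus `travel`/`productivity` for the societal
#'   perspective); defaults to the gamma means in `econ`.
#' @param econ An [econ_params()] object.
#' @param perspective Override `econ$perspective`.
#' @return Numeric vector of per-patient discounted costs (euros).
#' @export
discounted_cost <- function(outcomes, unit_costs = NULL, econ = econ_params(),
                            perspective = econ$perspective) {
  cats <- if (perspective == "societal") c("screening", "travel", "productivity")
          else "screening"
  if (is.null(unit_costs))
    unit_costs <- vapply(econ$gamma, `[[`, numeric(1), "mean")
  missing_cats <- setdiff(cats, names(unit_costs))
  if (length(missing_cats))
    stop("unit_costs lacks categories: ", paste(missing_cats, collapse = ", "),
         call. = FALSE)
  unit <- sum(unit_costs[cats])
  r <- econ$discount_rate_costs
  vapply(outcomes$screen_times,
         function(ts) unit * sum((1 + r)^(-ts / 12)), numeric(1))
}

#' Costs and delayed diagnoses over a risk-margin grid
#'
#' Runs the personalised policy over the margin grid and reports, per
#' margin, the mean discounted cost per patient (point unit costs = gamma
#' means), the cost per patient-year, the delayed-diagnosis count and the
#' total screen count. Costs fall and delayed counts rise with the margin;
#' adjacent margins whose interval matrices coincide (clamping) tie.
#'
#' @param cohort Imputed `retscreen_cohort`.
#' @param onsets Onsets from [assign_str_onset()].
#' @param margins Increasing margin grid (fractions), default 0--4% by 0.1%.
#' @param econ An [econ_params()] object.
#' @param params Risk-model parameters.
#' @param stats Optional precomputed [cohort_margin_stats] list (internal
#'   reuse by the bootstrap).
#' @return Data frame of class `margin_grid`: `margin`, `cost_per_patient`,
#'   `cost_per_patient_year`, `delayed`, `str_cases`, `screens`.
#' @export
margin_grid_analysis <- function(cohort, onsets, margins = seq(0, 0.04, by = 0.001),
                                 econ = econ_params(), params = default_risk_model(),
                                 stats = NULL) {
  if (is.null(stats))
    stats <- cohort_margin_stats(cohort, onsets, margins, params,
                                 disc_rate = econ$discount_rate_costs)
  unit <- unit_cost_point(econ)
  n <- length(stats$patient_id)
  out <- data.frame(margin = stats$margins,
                    cost_per_patient = unit * colMeans(stats$disc),
                    cost_per_patient_year = unit * colSums(stats$disc) / sum(stats$fu_years),
                    delayed = colSums(stats$delayed),
                    str_cases = sum(stats$str_case),
                    screens = colSums(stats$screens))
  rownames(out) <- NULL
  class(out) <- c("margin_grid", "data.frame")
  attr(out, "perspective") <- econ$perspective
  attr(out, "n") <- n
  out
}

#' Best risk margin by peak incremental saving per delayed diagnosis
#'
#' Walks the margin grid and, for each step with an increase in delayed
#' diagnoses, forms the ratio of the cost saving accumulated since the last
#' such step to the delayed-diagnosis increment ("incremental saving per
#' delayed STR diagnosis"); plateaus with no delayed increment carry their
#' savings forward to the next informative step. The best margin is the one
#' at the ratio's maximum; ties go to the candidate with the fewer delayed
#' diagnoses, then to the lower margin.
#'
#' @param grid A `margin_grid` data frame (needs `margin`,
#'   `cost_per_patient`, `delayed`).
#' @return List of class `best_margin`: `margin`, `ratio`, and `steps` (the
#'   per-step table). When the delayed count never increases a warning of
#'   class `retscreen_no_optimum` is raised and `margin` is `NA`.
#' @export
best_risk_margin <- function(grid) {
  stopifnot(all(c("margin", "cost_per_patient", "delayed") %in% names(grid)))
  K <- nrow(grid)
  if (K < 2L) stop("margin grid needs at least two margins", call. = FALSE)
  acc <- 0
  ratio <- rep(NA_real_, K)
  for (k in 2:K) {
    acc <- acc + (grid$cost_per_patient[k - 1L] - grid$cost_per_patient[k])
    dd <- grid$delayed[k] - grid$delayed[k - 1L]
    if (dd > 0) { ratio[k] <- acc / dd; acc <- 0 }
  }
  steps <- data.frame(margin = grid$margin, delayed = grid$delayed,
                      cost_per_patient = grid$cost_per_patient, ratio = ratio)
  if (all(is.na(ratio))) {
    warning(warningCondition("delayed-diagnosis count is flat across the margin grid; no optimum",
                             class = "retscreen_no_optimum"))
    return(structure(list(margin = NA_real_, ratio = NA_real_, steps = steps),
                     class = "best_margin"))
  }
  best <- which(ratio == max(ratio, na.rm = TRUE))
  if (length(best) > 1L) best <- best[grid$delayed[best] == min(grid$delayed[best])]
  best <- best[1L]
  structure(list(margin = grid$margin[best], ratio = ratio[best], steps = steps),
            class = "best_margin")
}

#' @export
print.best_margin <- function(x, ...) {
  if (is.na(x$margin)) cat("Best risk margin: none (flat delayed counts)\n")
  else cat(sprintf("Best risk margin: %.1f%% (peak incremental saving %.2f EUR per delayed STR diagnosis)\n",
                   100 * x$margin, x$ratio))
  invisible(x)
}
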