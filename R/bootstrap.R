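#' Two-stage bootstrap with probabilistic sensitivity analysis
#'
#' Stage 1 resamples patients with replacement (`B` iterations, original
#' sample size), determines the best risk margin in each iteration and
#' summarises it by its mean and percentile 95% CI. Because every screen
#' carries the same unit cost, the incremental-saving ratios scale by the
#' unit cost, so the per-iteration best margin needs no cost draws and is
#' identical under both perspectives. Stage 2 fixes the margin at the grid
#' point nearest the stage-1 mean and runs `B` further iterations, now
#' resampling patients *and* drawing unit costs from the fitted gamma
#' distributions: per draw it records total discounted costs per strategy
#' (annual, personalised, Dutch guideline), delayed-diagnosis counts,
#' savings per patient-year and incremental saving per delayed diagnosis
#' (ICER), under both the healthcare and the societal perspective.
#'
#' One master seed drives three independent substreams (stage-1 resampling,
#' stage-2 resampling, cost draws), so results are bit-reproducible.
#'
#' @param cohort Imputed `retscreen_cohort`.
#' @param onsets Onsets from [assign_str_onset()].
#' @param B Bootstrap iterations (>= 1) for both stages.
#' @param econ An [econ_params()] object.
#' @param seed Master seed.
#' @param margins Margin grid for stage 1.
#' @param params Risk-model parameters.
#' @param identity_resample If `TRUE`, every "resample" is the full sample
#'   (degenerate bootstrap, for testing).
#' @param stats Optional precomputed [cohort_margin_stats] list.
#' @return An object of class `retscreen_cea`; see [ceac()],
#'   [print.retscreen_cea()], [plot.retscreen_cea()].
#' @export
bootstrap_two_stage <- function(cohort, onsets, B = 1000L, econ = econ_params(),
                                seed = 1L, margins = seq(0, 0.04, by = 0.001),
                                params = default_risk_model(),
                                identity_resample = FALSE, stats = NULL) {
  if (B < 1) stop("B must be at least 1", call. = FALSE)
  if (is.null(stats))
    stats <- cohort_margin_stats(cohort, onsets, margins, params,
                                 disc_rate = econ$discount_rate_costs)
  n <- length(stats$patient_id)
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max - 1L, 3L)

  weights <- function(sub_seed) {
    if (identity_resample) return(matrix(1, n, B))
    set.seed(sub_seed)
    W <- matrix(0L, n, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      W[, b] <- tabulate(idx, n)
    }
    W
  }

  ## stage 1: best margin per resample
  W1 <- weights(substreams[1L])
  cost_mb <- crossprod(stats$disc, W1)      # margins x B, up to the unit cost
  del_mb <- crossprod(stats$delayed, W1)
  margins_b <- vapply(seq_len(B), function(b) {
    grid <- data.frame(margin = stats$margins,
                       cost_per_patient = cost_mb[, b] / n,
                       delayed = del_mb[, b])
    withCallingHandlers(best_risk_margin(grid)$margin,
                        retscreen_no_optimum = function(w) invokeRestart("muffleWarning"))
  }, numeric(1))
  margin_mean <- mean(margins_b, na.rm = TRUE)
  if (is.finite(margin_mean)) {
    margin_ci <- unname(quantile(margins_b, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
    j_star <- which.min(abs(stats$margins - margin_mean))
  } else {
    # no iteration had an informative delayed-count step (e.g. no STR cases):
    # fall back to the middle of the margin grid
    warning(warningCondition(paste("no bootstrap iteration found a best margin;",
                                   "falling back to the mid-grid margin"),
                             class = "retscreen_no_optimum"))
    margin_ci <- c(NA_real_, NA_real_)
    j_star <- ceiling(length(stats$margins) / 2)
  }
  margin_used <- stats$margins[j_star]

  ## stage 2: resample patients and draw unit costs
  W2 <- weights(substreams[2L])
  set.seed(substreams[3L])
  cs <- rgamma_cost(econ$gamma$screening, B)
  ct <- rgamma_cost(econ$gamma$travel, B)
  cp <- rgamma_cost(econ$gamma$productivity, B)
  unit <- list(healthcare = cs, societal = cs + ct + cp)

  disc_sum <- list(annual = as.vector(crossprod(stats$annual$disc, W2)),
                   personalised = as.vector(crossprod(stats$disc[, j_star], W2)),
                   guideline = as.vector(crossprod(stats$guideline$disc, W2)))
  delayed <- list(annual = as.vector(crossprod(as.numeric(stats$annual$delayed), W2)),
                  personalised = as.vector(crossprod(stats$delayed[, j_star], W2)),
                  guideline = as.vector(crossprod(as.numeric(stats$guideline$delayed), W2)))
  str_cases <- as.vector(crossprod(as.numeric(stats$str_case), W2))
  fy <- as.vector(crossprod(stats$fu_years, W2))

  totals <- lapply(unit, function(u) lapply(disc_sum, function(s) u * s))
  pairs <- list(personalised_vs_annual = c("personalised", "annual"),
                guideline_vs_annual = c("guideline", "annual"),
                personalised_vs_guideline = c("personalised", "guideline"))
  draws <- lapply(pairs, function(p) {
    data.frame(ddelayed = delayed[[p[1]]] - delayed[[p[2]]],
               dcost_healthcare = totals$healthcare[[p[1]]] - totals$healthcare[[p[2]]],
               dcost_societal = totals$societal[[p[1]]] - totals$societal[[p[2]]])
  })

  ci <- function(x) {
    x <- x[is.finite(x)]   # ICER draws with a zero delayed increment are uninformative
    if (!length(x)) return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_))
    c(mean = mean(x),
      lo = unname(quantile(x, 0.025, names = FALSE)),
      hi = unname(quantile(x, 0.975, names = FALSE)))
  }
  rows <- list()
  for (persp in c("healthcare", "societal")) {
    tt <- totals[[persp]]
    for (s in names(tt))
      rows[[paste("total_cost", s, persp, sep = ".")]] <-
        c(item = paste0("Total costs - ", s), perspective = persp, ci(tt[[s]]))
    for (s in c("personalised", "guideline")) {
      rows[[paste("saving_ppy", s, persp, sep = ".")]] <-
        c(item = paste0("Saving per patient-year - ", s, " vs annual"),
          perspective = persp, ci((tt$annual - tt[[s]]) / fy))
      icer <- (tt$annual - tt[[s]]) / (delayed[[s]] - delayed$annual)
      rows[[paste("icer", s, persp, sep = ".")]] <-
        c(item = paste0("ICER saving per delayed STR diagnosis - ", s, " vs annual"),
          perspective = persp, ci(icer))
    }
  }
  for (s in c("personalised", "guideline"))
    rows[[paste("delayed", s, sep = ".")]] <-
      c(item = paste0("Delayed STR diagnoses - ", s), perspective = "both",
        ci(delayed[[s]]))
  table <- do.call(rbind, lapply(rows, function(r)
    data.frame(item = r[["item"]], perspective = r[["perspective"]],
               mean = as.numeric(r[["mean"]]), lo = as.numeric(r[["lo"]]),
               hi = as.numeric(r[["hi"]]), stringsAsFactors = FALSE)))
  rownames(table) <- names(rows)

  # ratio-of-means ICER alongside the mean-of-ratios in the table
  icer_rom <- sapply(c("healthcare", "societal"), function(persp)
    sapply(c("personalised", "guideline"), function(s)
      mean(totals[[persp]]$annual - totals[[persp]][[s]]) /
        mean(delayed[[s]] - delayed$annual)))

  structure(list(stage1 = list(margins = margins_b, mean = margin_mean,
                               ci = margin_ci, margin_used = margin_used),
                 draws = draws, table = table, icer_ratio_of_means = icer_rom,
                 delayed_mean = vapply(delayed, mean, numeric(1)),
                 str_cases_mean = mean(str_cases),
                 B = B, seed = seed, n = n, econ = econ,
                 identity_resample = identity_resample),
            class = "retscreen_cea")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold `lambda` (euros per delayed STR
#' diagnosis avoided), the acceptance probability is the fraction of
#' bootstrap draws in which the strategy's net benefit relative to its
#' comparator, `lambda * (-ddelayed) - dcost`, is positive. At
#' `lambda = 0` this is the probability of being cheaper; as
#' `lambda` grows it tends to the probability of having fewer delayed
#' diagnoses.
#'
#' @param draws Data frame of bootstrap increments with columns `ddelayed`
#'   and `dcost` (or a `retscreen_cea` draws entry plus `perspective`).
#' @param thresholds Non-negative thresholds (euros).
#' @param perspective When `draws` carries per-perspective cost columns,
#'   which one to use.
#' @return Data frame `threshold`, `probability` of class `ceac_curve`.
#' @export
ceac <- function(draws, thresholds, perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  if (!nrow(draws)) stop("no bootstrap draws supplied", call. = FALSE)
  if (any(thresholds < 0)) stop("thresholds must be non-negative", call. = FALSE)
  dcost <- draws$dcost %||% draws[[paste0("dcost_", perspective)]]
  if (is.null(dcost)) stop("draws need a dcost column", call. = FALSE)
  prob <- vapply(thresholds,
                 function(l) mean(l * (-draws$ddelayed) - dcost > 0),
                 numeric(1))
  structure(data.frame(threshold = thresholds, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' @export
print.retscreen_cea <- function(x, digits = 1, ...) {
  cat(sprintf("Cost-effectiveness analysis (%d patients, B = %d, seed %d)\n",
              x$n, x$B, x$seed))
  cat(sprintf("Stage 1 best risk margin: mean %.1f%% (95%% CI %.1f%%, %.1f%%); stage 2 run at %.1f%%\n",
              100 * x$stage1$mean, 100 * x$stage1$ci[1], 100 * x$stage1$ci[2],
              100 * x$stage1$margin_used))
  tab <- x$table
  tab$mean <- round(tab$mean, digits); tab$lo <- round(tab$lo, digits)
  tab$hi <- round(tab$hi, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.retscreen_cea <- function(object, ...) {
  print(object, ...)
  cat("\nICER (ratio of means):\n")
  print(round(object$icer_ratio_of_means, 1))
  invisible(object)
}

#' Plot a cost-effectiveness plane or CEAC
#'
#' @param x A `retscreen_cea` object.
#' @param type `"plane"` (bootstrap increments) or `"ceac"`.
#' @param pair Strategy pair to show.
#' @param perspective Cost perspective.
#' @param thresholds Thresholds for the CEAC.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.retscreen_cea <- function(x, type = c("plane", "ceac"),
                               pair = "personalised_vs_annual",
                               perspective = c("healthcare", "societal"),
                               thresholds = seq(0, 5e4, length.out = 101), ...) {
  type <- match.arg(type)
  perspective <- match.arg(perspective)
  d <- x$draws[[pair]]
  if (is.null(d)) stop("unknown strategy pair: ", pair, call. = FALSE)
  if (type == "plane") {
    plot(d$ddelayed, d[[paste0("dcost_", perspective)]],
         xlab = "Incremental delayed STR diagnoses",
         ylab = sprintf("Incremental cost (EUR, %s)", perspective),
         main = gsub("_", " ", pair), pch = 16,
         col = grDevices::adjustcolor("steelblue", 0.4), ...)
    abline(h = 0, v = 0, lty = 3)
  } else {
    cc <- ceac(d, thresholds, perspective)
    plot(cc$threshold, cc$probability, type = "l", ylim = c(0, 1),
         xlab = "Willingness to pay (EUR per delayed STR diagnosis avoided)",
         ylab = "Probability cost-effective", main = gsub("_", " ", pair), ...)
    abline(h = c(0, 1), lty = 3)
  }
  invisible(x)
}
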