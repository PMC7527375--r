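#' @name cohort_format
#' @title Long-format cohort table
#' @description
#' A cohort is a base data frame of class `retscreen_cohort`, one row per
#' patient-visit, with columns
#' `patient_id` (character), `sex` (`"male"`/`"female"`),
#' `t_months` (integer months since patient entry, unique within patient),
#' `grade` (EURODIAB retinopathy grade 0--5 or `NA`),
#' `hba1c_mmol_mol`, `sbp_mmhg`, `duration_years` (positive or `NA`), and
#' `follow_up_months` (integer, at least the last visit time).
#' Missing values are written as empty fields in CSV. A complete-data
#' "truth" copy may ride along as `attr(cohort, "truth")` (see
#' [truth_channel()]).
NULL

cohort_columns <- c("patient_id", "sex", "t_months", "grade",
                    "hba1c_mmol_mol", "sbp_mmhg", "duration_years",
                    "follow_up_months")

as_cohort <- function(df) {
  df$patient_id <- as.character(df$patient_id)
  df$t_months <- as.integer(df$t_months)
  df$grade <- as.integer(df$grade)
  df$follow_up_months <- as.integer(df$follow_up_months)
  class(df) <- c("retscreen_cohort", "data.frame")
  df
}

# validate a cohort data frame; returns character vector of offences
cohort_offences <- function(df) {
  off <- character(0)
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols))
    return(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")))
  row_of <- function(i) paste0("row ", i, " (patient ", df$patient_id[i], ")")
  bad <- which(!is.na(df$grade) & (df$grade %% 1 != 0 | df$grade < 0 | df$grade > 5))
  for (i in bad) off <- c(off, sprintf("%s: grade %s outside 0..5", row_of(i), df$grade[i]))
  bad <- which(!is.na(df$hba1c_mmol_mol) & df$hba1c_mmol_mol <= 0)
  for (i in bad) off <- c(off, sprintf("%s: non-positive hba1c_mmol_mol", row_of(i)))
  bad <- which(!is.na(df$sbp_mmhg) & df$sbp_mmhg <= 0)
  for (i in bad) off <- c(off, sprintf("%s: non-positive sbp_mmhg", row_of(i)))
  bad <- which(is.na(df$t_months) | df$t_months < 0)
  for (i in bad) off <- c(off, sprintf("%s: t_months missing or negative", row_of(i)))
  bad <- which(!df$sex %in% c("male", "female"))
  for (i in bad) off <- c(off, sprintf("%s: sex must be 'male' or 'female'", row_of(i)))
  dup <- which(duplicated(df[c("patient_id", "t_months")]))
  for (i in dup) off <- c(off, sprintf("%s: duplicate visit time t_months=%s", row_of(i), df$t_months[i]))
  fu <- tapply(df$t_months, df$patient_id, max)
  fu_rec <- tapply(df$follow_up_months, df$patient_id, max)
  short <- names(fu)[!is.na(fu_rec) & fu_rec < fu]
  for (p in short) off <- c(off, sprintf("patient %s: follow_up_months below last visit time", p))
  off
}

validate_cohort <- function(df) {
  off <- cohort_offences(df)
  if (length(off))
    stop(paste0("invalid cohort:\n  ", paste(off, collapse = "\n  ")), call. = FALSE)
  invisible(df)
}

#' Read a cohort CSV
#'
#' Reads and validates the long-format cohort table (see [cohort_format]).
#' If a sibling file with suffix `.truth.csv` exists (written by
#' [write_cohort()] for generated cohorts) it is attached as the truth
#' channel.
#'
#' @param path CSV file path.
#' @param with_truth Attach `<path minus .csv>.truth.csv` when present.
#' @return A `retscreen_cohort` data frame, visits ordered within patient.
#' @export
read_cohort <- function(path, with_truth = TRUE) {
  if (!file.exists(path)) stop_config("path", sprintf("file '%s' does not exist", path))
  df <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character", sex = "character"))
  validate_cohort(df)
  df <- df[order(match(df$patient_id, unique(df$patient_id)), df$t_months), ]
  rownames(df) <- NULL
  df <- as_cohort(df)
  truth_path <- sub("\\.csv$", ".truth.csv", path)
  if (with_truth && truth_path != path && file.exists(truth_path)) {
    tr <- read.csv(truth_path, na.strings = "", stringsAsFactors = FALSE,
                   colClasses = c(patient_id = "character", sex = "character"))
    validate_cohort(tr)
    attr(df, "truth") <- as_cohort(tr)
  }
  df
}

#' Write a cohort CSV
#'
#' Writes the cohort in the long format of [cohort_format]; missing values
#' become empty fields, and a write-then-read round trip reproduces the
#' cohort exactly, including its missingness pattern. If the cohort carries
#' a truth channel it is written to a sibling `.truth.csv` file.
#'
#' @param cohort A `retscreen_cohort` data frame.
#' @param path Output CSV path.
#' @param write_truth Also write the truth channel when present.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, write_truth = TRUE) {
  validate_cohort(cohort)
  write.csv(cohort[cohort_columns], path, row.names = FALSE, na = "")
  tr <- attr(cohort, "truth")
  if (write_truth && !is.null(tr))
    write.csv(tr[cohort_columns], sub("\\.csv$", ".truth.csv", path),
              row.names = FALSE, na = "")
  invisible(path)
}

# earliest non-missing grade per patient; NA when no grade observed
baseline_grade <- function(cohort) {
  vapply(split(cohort$grade, factor(cohort$patient_id, levels = unique(cohort$patient_id))),
         function(g) {
           obs <- which(!is.na(g))
           if (length(obs)) g[obs[1]] else NA_integer_
         }, integer(1))
}

#' Apply the study's selection filters
#'
#' Retains patients that pass, in order: (1) at least one non-missing
#' retinopathy grade; (2) no STR (grade 3--5) at baseline, baseline being
#' the earliest visit with a non-missing grade; (3) at least
#' `min_follow_up_months` of follow-up (default 60, the model's maximum
#' screening interval). Exclusions are attributed to the first failing
#' criterion only, mirroring a sequential flow chart.
#'
#' @param cohort A validated `retscreen_cohort`.
#' @param min_follow_up_months Follow-up threshold in months.
#' @return A list of class `cohort_selection` with elements `cohort` (the
#'   retained patients; truth channel subset accordingly), `exclusions`
#'   (named counts `no_grade`, `baseline_str`, `short_follow_up`),
#'   `n_input` and `n_retained`.
#' @export
select_analysis_cohort <- function(cohort, min_follow_up_months = 60L) {
  ids <- unique(cohort$patient_id)
  base_g <- baseline_grade(cohort)
  fu <- tapply(cohort$follow_up_months, factor(cohort$patient_id, levels = ids), max)
  no_grade <- is.na(base_g)
  baseline_str <- !no_grade & base_g >= 3L
  short_fu <- !no_grade & !baseline_str & fu < min_follow_up_months
  keep_ids <- ids[!(no_grade | baseline_str | short_fu)]
  out <- cohort[cohort$patient_id %in% keep_ids, ]
  rownames(out) <- NULL
  tr <- attr(cohort, "truth")
  if (!is.null(tr)) {
    tr <- tr[tr$patient_id %in% keep_ids, ]
    rownames(tr) <- NULL
    attr(out, "truth") <- tr
  }
  ot <- attr(cohort, "onset_true")
  if (!is.null(ot)) attr(out, "onset_true") <- ot[ot$patient_id %in% keep_ids, ]
  structure(list(cohort = as_cohort(out),
                 exclusions = c(no_grade = sum(no_grade),
                                baseline_str = sum(baseline_str),
                                short_follow_up = sum(short_fu)),
                 n_input = length(ids),
                 n_retained = length(keep_ids)),
            class = "cohort_selection")
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat(sprintf("Cohort selection: %d of %d patients retained\n", x$n_retained, x$n_input))
  cat(sprintf("  excluded: %d without any retinopathy grade, %d with STR at baseline, %d with short follow-up\n",
              x$exclusions[["no_grade"]], x$exclusions[["baseline_str"]],
              x$exclusions[["short_follow_up"]]))
  invisible(x)
}

#' @export
print.retscreen_cohort <- function(x, ...) {
  ids <- unique(x$patient_id)
  bg <- baseline_grade(x)
  cat(sprintf("Longitudinal retinopathy screening cohort: %d patients, %d visits\n",
              length(ids), nrow(x)))
  cat(sprintf("  baseline grades: %s (missing baseline: %d)\n",
              paste(sprintf("%d x grade %s", tabulate(bg + 1L, 6L)[1:3], 0:2), collapse = ", "),
              sum(is.na(bg))))
  cat(sprintf("  grade records missing: %.1f%%; truth channel: %s\n",
              100 * mean(is.na(x$grade)),
              if (is.null(attr(x, "truth"))) "absent" else "present"))
  invisible(x)
}
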