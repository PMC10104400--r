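#' Night- and subject-level quality filters
#'
#' Applies the study's retention rules to a night-record table: nights with
#' missing device data are dropped, nights whose device onset disagrees with
#' the diary bedtime by more than `max_disparity` hours (e.g. a bedtime noted
#' as 8 pm but an onset recorded at 5 am) are dropped, and then subjects with
#' fewer than `min_nights` retained nights are dropped entirely. A disparity
#' of exactly `max_disparity` hours is retained (the rule reads "more than").
#' Because the night rules are per-night and the subject rule only counts
#' surviving nights, applying the two stages in sequence equals applying them
#' jointly.
#'
#' @param nights Night-record tibble as from [simulate_night_records()]
#'   (needs `subject_id`, `diary_bed`, `dev_onset`; other columns pass
#'   through).
#' @param max_disparity Maximum tolerated |device onset - diary bedtime|,
#'   hours.
#' @param min_nights Minimum retained nights for a subject to stay in.
#' @return List with `nights` (retained records) and `exclusions` (tibble
#'   `subject_id`, `night`, `reason` with reasons `missing_device`,
#'   `extreme_disparity`, `too_few_nights`).
#' @export
filter_nights <- function(nights, max_disparity = 6, min_nights = 7) {
  nights <- as_tibble(nights)
  disp <- abs(nights$dev_onset - nights$diary_bed) / 60
  reason <- dplyr::case_when(
    is.na(nights$dev_onset) ~ "missing_device",
    disp > max_disparity ~ "extreme_disparity",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  excl <- tibble(subject_id = nights$subject_id[!keep],
                 night = nights$night[!keep],
                 reason = reason[!keep])
  kept <- nights[keep, , drop = FALSE]
  cnt <- dplyr::count(kept, .data$subject_id)
  short <- cnt$subject_id[cnt$n < min_nights]
  if (length(short)) {
    drop2 <- kept$subject_id %in% short
    excl <- bind_rows(excl, tibble(subject_id = kept$subject_id[drop2],
                                   night = kept$night[drop2],
                                   reason = "too_few_nights"))
    kept <- kept[!drop2, , drop = FALSE]
  }
  list(nights = kept, exclusions = arrange(excl, .data$subject_id,
                                           .data$night))
}

#' Aggregate night records to subject-level phenotype means
#'
#' Averages each subject's retained nights on the continuous minute axis,
#' overall or separately by night type. Restorative sleep is reported as the
#' percentage of nights coded 1. Subjects with no nights of the requested
#' type are omitted (they re-enter bivariate school/nonschool models as
#' missing on that variable).
#'
#' @param nights Retained night records (see [filter_nights()]).
#' @param night_scope `"all"`, `"school"`, or `"nonschool"`.
#' @return Subject-level tibble: id/covariate columns plus `onset`, `wake`,
#'   `duration`, `midpoint` (mean minutes), `restorative` (percent of
#'   nights), `n_nights`.
#' @export
aggregate_subject <- function(nights, night_scope = c("all", "school",
                                                      "nonschool")) {
  night_scope <- match.arg(night_scope)
  nights <- as_tibble(nights)
  if (night_scope != "all") {
    nights <- filter(nights, .data$night_type == night_scope)
  }
  keys <- intersect(c("subject_id", "family_id", "zygosity", "twin_order",
                      "age", "sex"), names(nights))
  nights |>
    group_by(across(all_of(keys))) |>
    summarise(
      onset = mean(.data$dev_onset, na.rm = TRUE),
      wake = mean(.data$dev_wake, na.rm = TRUE),
      duration = mean(.data$duration, na.rm = TRUE),
      midpoint = mean(.data$midpoint, na.rm = TRUE),
      restorative = 100 * mean(.data$restorative, na.rm = TRUE),
      n_nights = dplyr::n(),
      .groups = "drop")
}

#' Standardize with winsorized outliers
#'
#' z-scores a phenotype over available subjects, removes extreme outliers
#' (|z| > `remove_z`, set missing) and winsorizes the remainder (|z| >
#' `winsorize_z`, set to the signed threshold). Removal is decided first and
#' z-scores are not recomputed afterwards, so a single pass fixes the output
#' and the operation is idempotent on its own output scale.
#'
#' @param values Numeric vector (NAs allowed, >= 3 non-missing).
#' @param winsorize_z,remove_z Thresholds; `winsorize_z < remove_z`.
#' @return Numeric vector of cleaned z-scores, same length as input.
#' @examples
#' standardize_winsorize(c(rnorm(50), 10))
#' @export
standardize_winsorize <- function(values, winsorize_z = 3.29,
                                  remove_z = 4.00) {
  if (winsorize_z >= remove_z) abort("winsorize_z must be < remove_z")
  ok <- !is.na(values)
  if (sum(ok) < 3) abort("need at least 3 non-missing values")
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0) abort("zero variance: cannot standardize",
                                     class = "twinsleep_variance_error")
  z <- (values - mean(values[ok])) / s
  z[abs(z) > remove_z] <- NA_real_
  z <- pmin(pmax(z, -winsorize_z), winsorize_z)
  z
}

#' Residualize a phenotype on age and sex
#'
#' Ordinary least-squares screen for fixed effects: regresses the phenotype
#' on age (years) and sex and returns the residuals, which downstream twin
#' models consume. Family structure is deliberately ignored at this stage —
#' it only affects standard errors of the screen, not the residuals. The
#' fitted per-year slope and male-female contrast are attached for
#' reporting.
#'
#' @param data Subject-level tibble with the phenotype column plus `age`
#'   and `sex` (`"F"`/`"M"`).
#' @param phenotype Column name (string) to residualize.
#' @return The input tibble with an added `<phenotype>_resid` column;
#'   `attr(, "coefficients")` holds a tibble of `term`, `estimate`
#'   (intercept, age slope per year, sexM contrast).
#' @export
residualize <- function(data, phenotype) {
  data <- as_tibble(data)
  if (!all(c(phenotype, "age", "sex") %in% names(data))) {
    abort("data must contain the phenotype, age and sex columns")
  }
  d <- data[, c(phenotype, "age", "sex")]
  names(d)[1] <- "y"
  d$sex <- factor(d$sex, levels = c("F", "M"))
  use <- complete.cases(d)
  if (length(unique(d$age[use])) < 2) {
    abort("age is constant: design is rank deficient",
          class = "twinsleep_rank_error")
  }
  fit <- lm(y ~ age + sex, data = d[use, ])
  if (any(is.na(coef(fit)))) {
    abort("rank-deficient covariate design", class = "twinsleep_rank_error")
  }
  res <- rep(NA_real_, nrow(data))
  res[use] <- resid(fit)
  out <- data
  out[[paste0(phenotype, "_resid")]] <- res
  cf <- coef(fit)
  attr(out, "coefficients") <- tibble(
    term = names(cf), estimate = unname(cf))
  out
}

#' Build standardized residual phenotypes for twin modeling
#'
#' Convenience pipeline for one phenotype: residualize on age and sex within
#' the supplied sample, then z-score with outlier handling. This mirrors the
#' practice of residualizing separately within each analysis sample (full,
#' younger, older), so stratified analyses should subset first.
#'
#' @inheritParams residualize
#' @inheritParams standardize_winsorize
#' @return Input tibble with an added `<phenotype>_z` column of cleaned,
#'   standardized residuals; regression coefficients attached as in
#'   [residualize()].
#' @export
prepare_phenotype <- function(data, phenotype, winsorize_z = 3.29,
                              remove_z = 4.00) {
  out <- residualize(data, phenotype)
  cf <- attr(out, "coefficients")
  out[[paste0(phenotype, "_z")]] <-
    standardize_winsorize(out[[paste0(phenotype, "_resid")]],
                          winsorize_z = winsorize_z, remove_z = remove_z)
  attr(out, "coefficients") <- cf
  out
}

#' Reshape subject-level phenotypes to pair-level records
#'
#' Turns a subject-level table into one row per family with twin 1 and twin
#' 2 columns for the requested phenotypes, the format the twin models
#' consume. Singletons get `NA` in the twin-2 slot.
#'
#' @param data Subject-level tibble with `family_id`, `zygosity`,
#'   `twin_order` and the phenotype columns.
#' @param phenotypes Character vector of phenotype column names.
#' @return Pair-level tibble: `family_id`, `zygosity`, then `<p>1`, `<p>2`
#'   per phenotype.
#' @export
pairs_from_subjects <- function(data, phenotypes) {
  data <- as_tibble(data)
  need <- c("family_id", "zygosity", "twin_order", phenotypes)
  if (!all(need %in% names(data))) {
    abort(paste("missing columns:",
                paste(setdiff(need, names(data)), collapse = ", ")))
  }
  wide_pairs(data[, need], phenotypes)
}
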