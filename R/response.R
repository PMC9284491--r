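#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles:
#' lower = `qbeta((1-level)/2; k, n-k+1)` (0 when `k = 0`),
#' upper = `qbeta(1-(1-level)/2; k+1, n-k)` (1 when `k = n`).
#' Coverage is at least the nominal level for every true proportion.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials.
#' @param level Confidence level in (0, 1); default 0.90, the convention of
#'   single-arm Phase 2 response tables.
#' @return Named numeric vector `c(lower, upper)` on the probability scale.
#' @examples
#' 100 * clopper_pearson(5, 46)   # 4.4 to 21.5 percent
#' @export
clopper_pearson <- function(k, n, level = 0.90) {
  stopifnot(length(k) == 1L, length(n) == 1L, k == round(k), n == round(n),
            n >= 1, level > 0, level < 1)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

# round-half-up, used only in the reporting layer
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

.resp_levels <- c("CR", "PR", "SD", "PD", "NE")

#' Best overall response with confirmation
#'
#' Derives the best overall response (BOR) from a series of timepoint
#' responses. A complete or partial response only counts if confirmed by a
#' second CR/PR-or-better assessment at least `confirm_window_days` later
#' (dates compared inclusively); unconfirmed responses downgrade. Stable
#' disease requires a non-PD, non-NE assessment at least `sd_min_weeks`
#' after baseline. Category ordering is CR > PR > SD > PD > NE. Clinical
#' benefit is a confirmed CR/PR or stable disease maintained for at least
#' `cb_min_weeks` (default 24) from baseline.
#'
#' Assessments after the first progression are ignored for response and
#' stable-disease determination.
#'
#' @param day Assessment days (strictly increasing, after `baseline_day`).
#' @param response Timepoint responses: `"CR"`, `"PR"`, `"SD"`, `"PD"`,
#'   `"NE"`.
#' @param baseline_day Day of the baseline assessment (default 0).
#' @param confirm_window_days Minimum spacing of the confirmatory
#'   examination in days (default 28).
#' @param sd_min_weeks Minimum duration from baseline for stable disease in
#'   weeks (default 6).
#' @param cb_min_weeks Minimum stable-disease duration for clinical benefit
#'   in weeks (default 24).
#' @return An object of class `bor`: list with `category`, `confirmed`,
#'   `sd_duration_weeks`, `clinical_benefit`.
#' @examples
#' best_overall_response(c(56, 84), c("PR", "PR"))  # confirmed PR
#' @export
best_overall_response <- function(day, response, baseline_day = 0,
                                  confirm_window_days = 28,
                                  sd_min_weeks = 6, cb_min_weeks = 24) {
  if (length(day) == 0L) {
    return(structure(list(category = "NE", confirmed = FALSE,
                          sd_duration_weeks = NA_real_,
                          clinical_benefit = FALSE, empty_series = TRUE),
                     class = "bor"))
  }
  stopifnot(length(day) == length(response))
  if (any(diff(day) <= 0)) stop("assessment days must be strictly increasing",
                                call. = FALSE)
  if (day[1] <= baseline_day) stop("baseline must precede all assessments",
                                   call. = FALSE)
  if (!all(response %in% .resp_levels)) {
    stop("responses must be one of ", paste(.resp_levels, collapse = ", "),
         call. = FALSE)
  }

  first_pd <- which(response == "PD")[1]
  keep <- if (is.na(first_pd)) seq_along(day) else seq_len(first_pd - 1L)
  d <- day[keep]; rsp <- response[keep]

  # confirmed response: any ordered pair of CR/PR assessments spaced by at
  # least the confirmation window; both CR -> CR, otherwise PR
  obj <- which(rsp %in% c("CR", "PR"))
  confirmed_cat <- NA_character_
  if (length(obj) >= 2L) {
    for (i in obj) {
      later <- obj[obj > i & d[obj] - d[i] >= confirm_window_days]
      if (length(later)) {
        both_cr <- any(rsp[i] == "CR" &
                         vapply(later, function(j) rsp[j] == "CR", logical(1)))
        if (both_cr) {
          confirmed_cat <- "CR"
          break
        }
        if (is.na(confirmed_cat)) confirmed_cat <- "PR"
      }
    }
  }

  non_pd <- which(rsp %in% c("CR", "PR", "SD"))
  sd_duration <- if (length(non_pd)) (max(d[non_pd]) - baseline_day) / 7 else NA_real_
  sd_qualifies <- length(non_pd) > 0L && sd_duration >= sd_min_weeks

  if (!is.na(confirmed_cat)) {
    category <- confirmed_cat; confirmed <- TRUE
  } else if (sd_qualifies) {
    category <- "SD"; confirmed <- FALSE
  } else if (!is.na(first_pd)) {
    category <- "PD"; confirmed <- FALSE
  } else {
    category <- "NE"; confirmed <- FALSE
  }
  cb <- confirmed || (category == "SD" && sd_duration >= cb_min_weeks)
  structure(list(category = category, confirmed = confirmed,
                 sd_duration_weeks = if (category == "SD") sd_duration else NA_real_,
                 clinical_benefit = cb, empty_series = FALSE),
            class = "bor")
}

#' @export
print.bor <- function(x, ...) {
  cat(sprintf("Best overall response: %s%s%s\n", x$category,
              if (x$confirmed) " (confirmed)" else "",
              if (x$clinical_benefit) ", clinical benefit" else ""))
  invisible(x)
}

#' Assemble a best-overall-response table from category counts
#'
#' Convenience constructor for [summarize_population()] when only the
#' published tally is available: expands counts into one row per patient.
#' Stable disease is split into prolonged (`sd_ge24`, counted as clinical
#' benefit) and shorter (`sd_lt24`) durations.
#'
#' @param cr,pr,sd_ge24,sd_lt24,pd,ne Nonnegative category counts.
#' @return A `data.frame` with columns `category` and `clinical_benefit`.
#' @export
response_counts <- function(cr = 0, pr = 0, sd_ge24 = 0, sd_lt24 = 0,
                            pd = 0, ne = 0) {
  data.frame(
    category = rep(c("CR", "PR", "SD", "SD", "PD", "NE"),
                   c(cr, pr, sd_ge24, sd_lt24, pd, ne)),
    clinical_benefit = rep(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                           c(cr, pr, sd_ge24, sd_lt24, pd, ne)),
    stringsAsFactors = FALSE
  )
}

#' Response summary with exact confidence intervals
#'
#' Tabulates best-overall-response categories and computes the objective
#' response rate (confirmed CR + PR) and clinical benefit rate with exact
#' Clopper-Pearson intervals. Percentages in the printed report are rounded
#' half-up to one decimal; full precision is retained in the returned
#' object.
#'
#' @param bor A `data.frame` with columns `category` (CR/PR/SD/PD/NE) and
#'   `clinical_benefit` (logical), one row per response-evaluable patient.
#'   Optionally produced by [response_counts()] or by applying
#'   [best_overall_response()] per patient.
#' @param population Label for the summarized population.
#' @param level Confidence level (default 0.90).
#' @return An object of class `response_summary`.
#' @examples
#' summarize_population(
#'   response_counts(cr = 1, pr = 4, sd_ge24 = 8, sd_lt24 = 11,
#'                   pd = 20, ne = 2))
#' @export
summarize_population <- function(bor, population = "all", level = 0.90) {
  stopifnot(all(c("category", "clinical_benefit") %in% names(bor)))
  n <- nrow(bor)
  counts <- table(factor(bor$category, levels = .resp_levels))
  orr_k <- sum(bor$category %in% c("CR", "PR"))
  cbr_k <- sum(bor$clinical_benefit)
  if (cbr_k < orr_k) stop("responders must be a subset of benefiters",
                          call. = FALSE)
  ci <- function(k) {
    if (n == 0) c(lower = NA_real_, upper = NA_real_)
    else clopper_pearson(k, n, level)
  }
  structure(
    list(population = population, n = n, counts = counts,
         orr = list(k = orr_k, n = n,
                    pct = if (n) 100 * orr_k / n else NA_real_,
                    ci_pct = 100 * ci(orr_k)),
         cbr = list(k = cbr_k, n = n,
                    pct = if (n) 100 * cbr_k / n else NA_real_,
                    ci_pct = 100 * ci(cbr_k)),
         level = level),
    class = "response_summary"
  )
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("Response summary: %s (n = %d)\n", x$population, x$n))
  for (lv in names(x$counts)) {
    if (x$n > 0) {
      cat(sprintf("  %-2s %3d (%.1f%%)\n", lv, x$counts[[lv]],
                  round_half_up(100 * x$counts[[lv]] / x$n)))
    }
  }
  fmt <- function(z, nm) {
    if (x$n == 0) {
      cat(sprintf("  %s: undefined (n = 0)\n", nm))
    } else {
      cat(sprintf("  %s: %d/%d = %.1f%% [%.1f-%.1f], %.0f%% CI\n", nm, z$k,
                  z$n, round_half_up(z$pct), round_half_up(z$ci_pct[[1]]),
                  round_half_up(z$ci_pct[[2]]), 100 * x$level))
    }
  }
  fmt(x$orr, "ORR")
  fmt(x$cbr, "CBR")
  invisible(x)
}

#' Relative dose intensity
#'
#' Relative dose intensity in percent: actual dose intensity (total
#' cumulative dose in mg divided by `duration_weeks * 7 - 1` dosing days,
#' reflecting the single planned omission day at treatment start) over the
#' planned dose intensity in mg per day, times 100.
#'
#' @param cumulative_mg Total cumulative dose received, mg.
#' @param duration_weeks Treatment duration, weeks (`> 1/7`).
#' @param planned_mg_per_day Planned dose intensity at treatment start,
#'   mg/day.
#' @return Relative dose intensity in percent.
#' @examples
#' relative_dose_intensity(27600, 10, 400)  # 100
#' @export
relative_dose_intensity <- function(cumulative_mg, duration_weeks,
                                    planned_mg_per_day) {
  if (any(duration_weeks * 7 <= 1)) {
    stop("treatment duration must exceed one day", call. = FALSE)
  }
  stopifnot(all(planned_mg_per_day > 0), all(cumulative_mg >= 0))
  100 * (cumulative_mg / (duration_weeks * 7 - 1)) / planned_mg_per_day
}

#' Waterfall metrics: best relative change in target-lesion burden
#'
#' @param baseline Baseline sum of target-lesion diameters (mm, `> 0`); `NA`
#'   marks a patient excluded for missing baseline.
#' @param followups Numeric vector of post-baseline sums (mm).
#' @return A list with `best_change_pct` (minimum percent change from
#'   baseline over follow-ups), `shrinkage` (best change `< 0`) and
#'   `excluded` (missing baseline or no follow-up data).
#' @export
waterfall_metrics <- function(baseline, followups) {
  followups <- followups[!is.na(followups)]
  if (is.na(baseline) || length(followups) == 0L) {
    return(list(best_change_pct = NA_real_, shrinkage = NA, excluded = TRUE))
  }
  stopifnot(baseline > 0, all(followups >= 0))
  best <- min(100 * (followups - baseline) / baseline)
  list(best_change_pct = best, shrinkage = best < 0, excluded = FALSE)
}
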