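#' Immunohistochemistry H-score
#'
#' The standard H-score: `1 * p1 + 2 * p2 + 3 * p3` where `p1`, `p2`, `p3`
#' are the percentages of tumor cells staining at weak, moderate and strong
#' intensity. Range 0 (all negative) to 300 (all strongly positive).
#'
#' @param p1,p2,p3 Percentages of cells at intensities 1-3 (each `>= 0`,
#'   sum `<= 100`). Vectorized.
#' @return H-score(s) in `[0, 300]`.
#' @examples
#' h_score(10, 20, 30)  # 140
#' @export
h_score <- function(p1, p2, p3) {
  stopifnot(all(p1 >= 0), all(p2 >= 0), all(p3 >= 0))
  if (any(p1 + p2 + p3 > 100 + 1e-9)) {
    stop("intensity percentages must sum to at most 100", call. = FALSE)
  }
  p1 + 2 * p2 + 3 * p3
}

#' Relative change from screening
#'
#' `100 * (followup - screen) / screen`, the pharmacodynamic change metric
#' for screening/on-treatment biomarker pairs. Records with a zero screening
#' value are undefined on the relative scale and are returned as `NA` (with
#' a warning); such patients belong on a separate absolute-change track.
#'
#' @param screen,followup Paired measurements (vectorized).
#' @return Percent change(s); `NA` where `screen == 0`.
#' @examples
#' relative_change(100, 42)  # -58
#' @export
relative_change <- function(screen, followup) {
  stopifnot(length(screen) == length(followup))
  out <- ifelse(screen == 0, NA_real_, 100 * (followup - screen) / screen)
  if (any(screen == 0)) {
    warning(sum(screen == 0),
            " record(s) with zero screening value excluded (NA)")
  }
  out
}

#' Longitudinal mutation clearance in circulating free DNA
#'
#' Pairs per-mutation allele-frequency calls across two timepoints. A
#' mutation is *detected* when its allele frequency is at or above the assay
#' detection threshold, and *cleared* when it was detected at baseline but
#' no longer detected on treatment. Mutations detected at baseline with no
#' on-treatment record are excluded (and reported); mutations first emerging
#' on treatment are reported separately and never enter the clearance
#' fraction, whose denominator is the baseline-detected set.
#'
#' @param calls A `data.frame` with columns `patient_id`, `variant`,
#'   `timepoint` and `af` (allele frequency as a fraction in `[0, 1]`).
#'   Missing (patient, variant, timepoint) rows are treated as not assayed.
#' @param baseline,followup The two timepoint labels (defaults `"C1D1"`,
#'   `"C2D28"`).
#' @param threshold Detection threshold as an allele-frequency fraction
#'   (default `5e-4`, i.e. 0.05 percent).
#' @return Object of class `mutation_clearance`: `per_mutation` table with
#'   frequency changes and cleared flags, `cleared_k`, `cleared_n`,
#'   `cleared_fraction`, an `emergent` table, a per-patient `patients` table
#'   with an any-mutation-decreased flag, and the identifiers of excluded
#'   (unpaired) baseline mutations.
#' @export
mutation_clearance <- function(calls, baseline = "C1D1", followup = "C2D28",
                               threshold = 5e-4) {
  stopifnot(all(c("patient_id", "variant", "timepoint", "af") %in% names(calls)))
  if (any(calls$af < 0 | calls$af > 1)) {
    stop("allele frequencies must be fractions in [0, 1]", call. = FALSE)
  }
  b <- calls[calls$timepoint == baseline, c("patient_id", "variant", "af")]
  f <- calls[calls$timepoint == followup, c("patient_id", "variant", "af")]
  names(b)[3] <- "af_baseline"; names(f)[3] <- "af_followup"
  m <- merge(b, f, by = c("patient_id", "variant"), all = TRUE)
  m$det_baseline <- !is.na(m$af_baseline) & m$af_baseline >= threshold
  m$det_followup <- !is.na(m$af_followup) & m$af_followup >= threshold

  emergent <- m[!m$det_baseline & m$det_followup, , drop = FALSE]
  unpaired <- m$det_baseline & is.na(m$af_followup)
  if (any(unpaired)) {
    message(sum(unpaired), " baseline-detected mutation(s) lack a paired ",
            followup, " record and are excluded from the clearance fraction")
  }
  per <- m[m$det_baseline & !is.na(m$af_followup), , drop = FALSE]
  per$delta_af <- per$af_followup - per$af_baseline
  per$cleared <- !per$det_followup
  per$decreased <- per$af_followup < per$af_baseline

  patients <- do.call(rbind, lapply(split(per, per$patient_id), function(d) {
    data.frame(patient_id = d$patient_id[1], n_mutations = nrow(d),
               any_decreased = any(d$decreased), all_cleared = all(d$cleared),
               stringsAsFactors = FALSE)
  }))
  rownames(patients) <- NULL
  structure(
    list(per_mutation = per[, c("patient_id", "variant", "af_baseline",
                                "af_followup", "delta_af", "cleared",
                                "decreased")],
         cleared_k = sum(per$cleared), cleared_n = nrow(per),
         cleared_fraction = if (nrow(per)) sum(per$cleared) / nrow(per) else NA_real_,
         emergent = emergent[, c("patient_id", "variant", "af_followup")],
         patients = patients,
         excluded_unpaired = m[unpaired, c("patient_id", "variant")],
         threshold = threshold),
    class = "mutation_clearance"
  )
}

#' @export
print.mutation_clearance <- function(x, ...) {
  cat(sprintf(
    "Mutation clearance: %d/%d (%.1f%%) baseline-detected mutations cleared (threshold %.3g)\n",
    x$cleared_k, x$cleared_n, round_half_up(100 * x$cleared_fraction),
    x$threshold))
  if (nrow(x$emergent)) {
    cat(sprintf("  %d mutation(s) newly detected on treatment (reported separately)\n",
                nrow(x$emergent)))
  }
  invisible(x)
}

#' Baseline variant table stratified by clinical benefit
#'
#' Cross-tabulates baseline-detected variants by whether the patient
#' subsequently achieved clinical benefit. Percentages use the number of
#' mutated patients within each stratum as denominator; a patient may carry
#' several variants, so variant counts need not sum to patient counts.
#'
#' @param baseline_calls A `data.frame` with columns `patient_id` and
#'   `variant`, one row per baseline-detected variant call. Patients absent
#'   from this table but present in `benefit` are counted as wild-type.
#' @param benefit A `data.frame` with columns `patient_id` and
#'   `clinical_benefit` (logical), covering every analyzed patient.
#' @return Object of class `cb_variant_table`: per-stratum patient counts
#'   (`n_mutated`, `n_wildtype`) and a `variants` table with counts and
#'   percentages in each stratum.
#' @export
cb_variant_table <- function(baseline_calls, benefit) {
  stopifnot(all(c("patient_id", "variant") %in% names(baseline_calls)),
            all(c("patient_id", "clinical_benefit") %in% names(benefit)))
  if (anyDuplicated(benefit$patient_id)) {
    stop("one clinical-benefit label per patient is required", call. = FALSE)
  }
  if (!all(baseline_calls$patient_id %in% benefit$patient_id)) {
    stop("every patient with variant calls must have a clinical-benefit label",
         call. = FALSE)
  }
  mutated <- unique(baseline_calls$patient_id)
  benefit$mutated <- benefit$patient_id %in% mutated
  n_mut <- table(factor(benefit$clinical_benefit[benefit$mutated],
                        levels = c(TRUE, FALSE)))
  n_wt <- table(factor(benefit$clinical_benefit[!benefit$mutated],
                       levels = c(TRUE, FALSE)))
  calls <- merge(unique(baseline_calls[, c("patient_id", "variant")]),
                 benefit[, c("patient_id", "clinical_benefit")],
                 by = "patient_id")
  variants <- sort(unique(calls$variant))
  rows <- lapply(variants, function(v) {
    k_cb <- length(unique(calls$patient_id[calls$variant == v &
                                             calls$clinical_benefit]))
    k_no <- length(unique(calls$patient_id[calls$variant == v &
                                             !calls$clinical_benefit]))
    data.frame(
      variant = v, cb_k = k_cb, cb_n = as.integer(n_mut[["TRUE"]]),
      cb_pct = if (n_mut[["TRUE"]] > 0) 100 * k_cb / n_mut[["TRUE"]] else NA_real_,
      nocb_k = k_no, nocb_n = as.integer(n_mut[["FALSE"]]),
      nocb_pct = if (n_mut[["FALSE"]] > 0) 100 * k_no / n_mut[["FALSE"]] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(n_mutated = c(cb = as.integer(n_mut[["TRUE"]]),
                       no_cb = as.integer(n_mut[["FALSE"]])),
         n_wildtype = c(cb = as.integer(n_wt[["TRUE"]]),
                        no_cb = as.integer(n_wt[["FALSE"]])),
         variants = if (length(rows)) do.call(rbind, rows) else
           data.frame(variant = character(0))),
    class = "cb_variant_table"
  )
}

#' @export
print.cb_variant_table <- function(x, ...) {
  cat("Baseline variant status by clinical benefit\n")
  cat(sprintf("  wild-type: CB %d, no CB %d; mutated: CB %d, no CB %d\n",
              x$n_wildtype[["cb"]], x$n_wildtype[["no_cb"]],
              x$n_mutated[["cb"]], x$n_mutated[["no_cb"]]))
  if (nrow(x$variants)) {
    for (i in seq_len(nrow(x$variants))) {
      v <- x$variants[i, ]
      cat(sprintf("  %-6s %d/%d (%.1f%%)  %d/%d (%.1f%%)\n", v$variant,
                  v$cb_k, v$cb_n, round_half_up(v$cb_pct),
                  v$nocb_k, v$nocb_n, round_half_up(v$nocb_pct)))
    }
  }
  invisible(x)
}
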