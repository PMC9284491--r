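#' Dose ladder for 3+3 escalation
#'
#' A dose ladder is an ordered table of dose levels. "Main" levels form the
#' backbone of the escalation path; intermediate "bis" levels are conditional
#' insertions that are only tested when a PET-occupancy trigger fires (see
#' [bis_trigger()]). Each bis level records the main level it follows.
#'
#' @param label Character vector of unique level labels.
#' @param dose_mg Dose per administration in mg.
#' @param schedule `"QD"` (once daily) or `"BID"` (twice daily).
#' @param bis Logical: is this an intermediate (bis) level?
#' @param follows For bis levels, the label of the main level each follows;
#'   `NA` for main levels.
#' @return A `data.frame` of class `dose_ladder` with a derived
#'   `daily_mg` column (dose intensity per day).
#' @examples
#' default_dose_ladder()
#' @export
dose_ladder <- function(label, dose_mg, schedule, bis = FALSE, follows = NA) {
  schedule <- match.arg(schedule, c("QD", "BID"), several.ok = TRUE)
  ld <- data.frame(
    label = as.character(label),
    dose_mg = as.numeric(dose_mg),
    schedule = as.character(schedule),
    bis = rep_len(as.logical(bis), length(label)),
    follows = rep_len(as.character(follows), length(label)),
    stringsAsFactors = FALSE
  )
  ld$daily_mg <- ld$dose_mg * ifelse(ld$schedule == "BID", 2, 1)
  if (anyDuplicated(ld$label)) stop("dose level labels must be unique", call. = FALSE)
  for (sch in unique(ld$schedule)) {
    d <- ld$daily_mg[ld$schedule == sch]
    if (any(diff(d) <= 0)) {
      stop("daily dose intensity must be strictly increasing within a schedule",
           call. = FALSE)
    }
  }
  bad <- ld$bis & !(ld$follows %in% ld$label[!ld$bis])
  if (any(bad)) stop("each bis level must follow an existing main level", call. = FALSE)
  class(ld) <- c("dose_ladder", "data.frame")
  ld
}

#' Default pre-specified dose-escalation schedule
#'
#' The ten-level ladder used as the package default: main once-daily levels
#' DL(-1) 10 mg through DL5 600 mg, with conditional intermediate levels
#' (DL1bis 50 mg QD, DL2bis 150 mg QD) and twice-daily levels of matched
#' daily intensity (DL4bis 200 mg BID, DL5bis 300 mg BID).
#'
#' @return A [dose_ladder()] object.
#' @export
default_dose_ladder <- function() {
  dose_ladder(
    label = c("DL-1", "DL1", "DL1bis", "DL2", "DL2bis",
              "DL3", "DL4", "DL4bis", "DL5", "DL5bis"),
    dose_mg = c(10, 20, 50, 100, 150, 200, 400, 200, 600, 300),
    schedule = c("QD", "QD", "QD", "QD", "QD", "QD", "QD", "BID", "QD", "BID"),
    bis = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    follows = c(NA, NA, "DL1", NA, "DL2", NA, NA, "DL4", NA, "DL5")
  )
}

#' 3+3 cohort decision
#'
#' Standard 3+3 rule: with no DLT among three evaluable patients the next
#' cohort starts one level higher; with one DLT among three, up to three more
#' patients are treated at the same level; with two or more DLTs at any point
#' the maximum administered dose is reached. After expansion to six, at most
#' one DLT among six allows escalation.
#'
#' @param dlt Logical vector of DLT flags, one per DLT-evaluable patient in
#'   the cohort.
#' @return One of `"escalate"`, `"expand_cohort"`,
#'   `"max_administered_dose_reached"`.
#' @export
cohort_decision <- function(dlt) {
  stopifnot(is.logical(dlt))
  n <- length(dlt)
  k <- sum(dlt)
  if (k >= 2L) return("max_administered_dose_reached")
  if (n < 3L) stop("at least 3 DLT-evaluable patients are required", call. = FALSE)
  if (k == 0L && n >= 3L) return("escalate")
  # exactly one DLT
  if (n >= 6L) "escalate" else "expand_cohort"
}

#' Intermediate (bis) dose-level trigger
#'
#' A bis level is investigated when either (a) at least one patient at the
#' lower reference level shows low target inhibition (`<= low` percent), or
#' (b) the upper reference level has been tested and *all* of its patients
#' show high inhibition (`> high` percent). Patients without an evaluable
#' scan contribute to neither clause; an empty upper cohort cannot satisfy
#' the all-patients clause.
#'
#' @param occ_lower Occupancy percentages at the lower reference level
#'   (may be empty or contain `NA` for unscanned patients).
#' @param occ_upper Occupancy percentages at the upper reference level.
#' @param low Low-inhibition threshold in percent (default 30).
#' @param high High-inhibition threshold in percent (default 85).
#' @return `TRUE` if the bis level should be tested.
#' @export
bis_trigger <- function(occ_lower, occ_upper, low = 30, high = 85) {
  stopifnot(low > 0, high > low, high <= 100)
  a <- occ_lower[!is.na(occ_lower)]
  b <- occ_upper[!is.na(occ_upper)]
  any(a <= low) || (length(b) > 0L && all(b > high))
}

#' Maximum tolerated dose from completed escalation cohorts
#'
#' The MTD is the highest dose level at which at most 1 of 6 evaluable
#' patients experienced a DLT. If no level hit the 3+3 stopping boundary
#' (two or more DLTs), the MTD is declared not reached.
#'
#' @param cohorts A `data.frame` with columns `label`, `n_evaluable`,
#'   `n_dlt`, one row per tested level in escalation order.
#' @return The MTD level label, or `"not_reached"`.
#' @export
determine_mtd <- function(cohorts) {
  stopifnot(all(c("label", "n_evaluable", "n_dlt") %in% names(cohorts)))
  stopifnot(all(cohorts$n_dlt <= cohorts$n_evaluable))
  boundary <- cohorts$n_dlt >= 2
  cleared <- cohorts$n_dlt <= 1 &
    (cohorts$n_dlt == 0 | cohorts$n_evaluable >= 6)
  if (!any(boundary)) return("not_reached")
  first_bad <- which(boundary)[1]
  ok <- which(cleared[seq_len(first_bad - 1)])
  if (length(ok) == 0L) return("not_reached")
  cohorts$label[max(ok)]
}

#' Recommended Phase 2 dose from occupancy saturation and safety
#'
#' The nominal RP2D is the level a configurable number of *main-ladder*
#' steps above the lowest tested level at which every evaluable patient
#' showed occupancy above the saturation threshold (default >90 percent
#' reduction in corrected SUVmax), capped at the highest cleared level.
#' If DLTs occurred at the nominal level, the RP2D falls back to the highest
#' DLT-free level whose patients all reached saturation (`fallback =
#' "any_saturating"`), or, more restrictively, to such a level between the
#' saturating anchor and the nominal level (`fallback = "between"`).
#'
#' Bis levels are excluded when counting "levels above": they are conditional
#' insertions, not backbone steps. The saturating anchor itself may be a bis
#' level.
#'
#' @param cohorts A `data.frame` with columns `label`, `n_evaluable`, `n_dlt`
#'   in escalation order (tested levels only).
#' @param occupancy A named list: for each tested level label, the vector of
#'   evaluable occupancy percentages (may be empty).
#' @param ladder A [dose_ladder()]; defaults to [default_dose_ladder()].
#' @param saturation Saturation threshold in percent (default 90, strict).
#' @param levels_above Number of main-ladder steps above the anchor
#'   (default 2).
#' @param fallback DLT fallback behaviour, see Details.
#' @return A list with elements `rp2d` (level label or `NA`), `anchor`
#'   (saturating level label or `NA`) and `mtd` (from [determine_mtd()]).
#' @export
select_rp2d <- function(cohorts, occupancy, ladder = default_dose_ladder(),
                        saturation = 90, levels_above = 2,
                        fallback = c("any_saturating", "between")) {
  fallback <- match.arg(fallback)
  stopifnot(all(cohorts$label %in% ladder$label))
  mtd <- determine_mtd(cohorts)

  saturating <- vapply(cohorts$label, function(lb) {
    occ <- occupancy[[lb]]
    occ <- occ[!is.na(occ)]
    length(occ) > 0L && all(occ > saturation)
  }, logical(1))
  if (!any(saturating)) {
    return(list(rp2d = NA_character_, anchor = NA_character_, mtd = mtd))
  }
  # lowest saturating level by daily dose intensity
  daily <- ladder$daily_mg[match(cohorts$label, ladder$label)]
  sat_idx <- which(saturating)
  anchor <- cohorts$label[sat_idx[which.min(daily[sat_idx])]]
  anchor_daily <- ladder$daily_mg[ladder$label == anchor]

  # main-ladder levels strictly above the anchor's daily intensity
  mains <- ladder[!ladder$bis & ladder$daily_mg > anchor_daily, , drop = FALSE]
  # highest cleared (tested, <2 DLT) level caps the choice
  cleared <- cohorts$label[cohorts$n_dlt <= 1]
  if (length(cleared) == 0L) {
    return(list(rp2d = NA_character_, anchor = anchor, mtd = mtd))
  }
  cap_daily <- max(ladder$daily_mg[match(cleared, ladder$label)])

  if (nrow(mains) == 0L) {
    nominal <- anchor
  } else {
    k <- min(levels_above, nrow(mains))
    nominal <- mains$label[k]
  }
  # cap at highest cleared level
  if (ladder$daily_mg[ladder$label == nominal] > cap_daily) {
    hi <- cleared[which.max(ladder$daily_mg[match(cleared, ladder$label)])]
    nominal <- hi
  }

  # DLT override
  n_dlt_at <- function(lb) {
    i <- match(lb, cohorts$label)
    if (is.na(i)) 0L else cohorts$n_dlt[i]
  }
  if (n_dlt_at(nominal) > 0L) {
    pool <- cohorts$label[saturating & cohorts$n_dlt == 0]
    if (fallback == "between") {
      pd <- ladder$daily_mg[match(pool, ladder$label)]
      pool <- pool[pd >= anchor_daily &
                     pd <= ladder$daily_mg[ladder$label == nominal]]
    }
    if (length(pool) == 0L) {
      return(list(rp2d = NA_character_, anchor = anchor, mtd = mtd))
    }
    nominal <- pool[which.max(ladder$daily_mg[match(pool, ladder$label)])]
  }
  list(rp2d = nominal, anchor = anchor, mtd = mtd)
}

#' Replay a completed escalation on observed cohort data
#'
#' Applies the MTD and RP2D rules to an observed escalation path (tested
#' levels, DLT counts and occupancy readings), returning the conclusions the
#' rule engine draws from that path.
#'
#' @inheritParams select_rp2d
#' @return A list with `mtd`, `rp2d`, `anchor`, and the per-level decision
#'   from [cohort_decision()].
#' @export
replay_escalation <- function(cohorts, occupancy,
                              ladder = default_dose_ladder(),
                              saturation = 90, levels_above = 2,
                              fallback = c("any_saturating", "between")) {
  decisions <- vapply(seq_len(nrow(cohorts)), function(i) {
    cohort_decision(rep(c(TRUE, FALSE),
                        c(cohorts$n_dlt[i],
                          cohorts$n_evaluable[i] - cohorts$n_dlt[i])))
  }, character(1))
  sel <- select_rp2d(cohorts, occupancy, ladder, saturation, levels_above,
                     fallback)
  c(sel, list(decisions = setNames(decisions, cohorts$label)))
}

#' Monte Carlo simulation of PET-gated 3+3 dose escalation
#'
#' Simulates the escalation walk along a dose ladder: cohorts of three (with
#' 3+3 expansion) are enrolled at successive main levels; after each
#' completed main-level cohort the bis triggers decide whether an
#' intermediate level is tested next. Low inhibition at a main level
#' (clause (a) of [bis_trigger()]) jumps the walk directly to the bis level
#' following the *next* main level, skipping the intermediate main level;
#' uniformly high inhibition (clause (b)) inserts the bis level attached to
#' the current main level before continuing. Escalation stops at the ladder
#' top or when the 3+3 boundary is hit, after which the MTD and RP2D rules
#' are applied.
#'
#' @param tox_fun Function of daily dose in mg returning the DLT probability.
#' @param occ_fun Function `(daily_mg, n)` returning `n` occupancy
#'   percentages.
#' @param ladder A [dose_ladder()].
#' @param start Label of the first level enrolled (default `"DL1"`).
#' @param n_replicates Number of simulated trials.
#' @param seed Integer seed.
#' @param cohort_size Patients per initial cohort (default 3).
#' @param saturation,levels_above,fallback Passed to [select_rp2d()].
#' @param low,high Passed to [bis_trigger()].
#' @return A `data.frame` with one row per replicate: `mtd`, `rp2d`,
#'   `n_enrolled`, `bis_tested` (comma-separated labels) and `path`.
#' @export
simulate_escalation <- function(tox_fun, occ_fun,
                                ladder = default_dose_ladder(),
                                start = "DL1", n_replicates = 100,
                                seed = 1, cohort_size = 3,
                                saturation = 90, levels_above = 2,
                                fallback = "any_saturating",
                                low = 30, high = 85) {
  stopifnot(start %in% ladder$label[!ladder$bis])
  set.seed(seed)
  mains <- ladder$label[!ladder$bis]
  bis_after <- function(main_lb) {
    b <- ladder$label[ladder$bis & ladder$follows == main_lb &
                        ladder$schedule == "QD"]
    if (length(b)) b[1] else NA_character_
  }
  out <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    path <- character(0)
    cohorts <- data.frame(label = character(0), n_evaluable = integer(0),
                          n_dlt = integer(0), stringsAsFactors = FALSE)
    occupancy <- list()
    queue <- start
    stopped <- FALSE
    while (length(queue) > 0L && !stopped) {
      lb <- queue[1]; queue <- queue[-1]
      daily <- ladder$daily_mg[ladder$label == lb]
      dlt <- runif(cohort_size) < tox_fun(daily)
      dec <- cohort_decision(dlt)
      if (dec == "expand_cohort") {
        dlt <- c(dlt, runif(cohort_size) < tox_fun(daily))
        dec <- cohort_decision(dlt)
      }
      occ <- occ_fun(daily, length(dlt))
      path <- c(path, lb)
      cohorts <- rbind(cohorts, data.frame(
        label = lb, n_evaluable = length(dlt), n_dlt = sum(dlt),
        stringsAsFactors = FALSE))
      occupancy[[lb]] <- occ
      if (dec == "max_administered_dose_reached") {
        stopped <- TRUE
        break
      }
      if (length(queue) > 0L) next  # a queued (bis) level is tested first
      if (!(lb %in% mains)) {
        # completed a bis level: resume after the main level it follows
        lb <- ladder$follows[ladder$label == lb]
      }
      i <- match(lb, mains)
      if (is.na(i) || i >= length(mains)) break  # ladder top
      nxt <- mains[i + 1]
      # clause (a): low inhibition at lb -> jump to bis after the next main
      jump_bis <- bis_after(nxt)
      if (!is.na(jump_bis) && !(jump_bis %in% path) &&
          bis_trigger(occupancy[[lb]], numeric(0), low, high)) {
        queue <- jump_bis
        next
      }
      # clause (b): uniformly high inhibition at lb -> insert bis after lb
      ins_bis <- bis_after(lb)
      if (!is.na(ins_bis) && !(ins_bis %in% path) &&
          bis_trigger(numeric(0), occupancy[[lb]], low, high)) {
        queue <- c(ins_bis, nxt)
      } else {
        queue <- nxt
      }
    }
    sel <- select_rp2d(cohorts, occupancy, ladder, saturation, levels_above,
                       fallback)
    bis_tested <- path[path %in% ladder$label[ladder$bis]]
    out[[rep_i]] <- data.frame(
      replicate = rep_i, mtd = sel$mtd,
      rp2d = ifelse(is.na(sel$rp2d), "none", sel$rp2d),
      n_enrolled = sum(cohorts$n_evaluable),
      bis_tested = paste(bis_tested, collapse = ","),
      path = paste(path, collapse = ">"),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
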