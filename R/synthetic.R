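.sdlog <- function(cv) sqrt(log(1 + cv^2))

# steady-state concentration at time t (h) after the last of an infinite
# train of doses tau hours apart; one-compartment, first-order absorption
.ss_conc <- function(t, dose_mg, ka, ke, v_f, tau = 24) {
  d_ng <- dose_mg * 1e6
  v_ml <- v_f * 1000
  (d_ng * ka / (v_ml * (ka - ke))) *
    (exp(-ke * t) / (1 - exp(-ke * tau)) - exp(-ka * t) / (1 - exp(-ka * tau)))
}

.esr1_panel <- c("D538G", "Y537S", "Y537N", "Y537C", "Y537D", "E380Q",
                 "S463P", "L536H", "L536P", "L536R", "V534E", "P535H")
.esr1_weights <- c(0.28, 0.14, 0.10, 0.08, 0.02, 0.10,
                   0.08, 0.05, 0.05, 0.04, 0.03, 0.03)

.default_response_probs <- function() {
  # outcome frequencies of a heavily pretreated ER+/HER2- expansion cohort,
  # by baseline ESR1 status; categories cr/pr/sd_ge24/sd_lt24/pd/ne
  wt <- c(cr = 1, pr = 3, sd_ge24 = 5, sd_lt24 = 5, pd = 11, ne = 1) / 26
  mut <- c(cr = 0, pr = 1, sd_ge24 = 3, sd_lt24 = 6, pd = 8, ne = 1) / 19
  # the published tables do not cross ESR1 status with prior CDK4/6
  # inhibitor exposure, so outcome probabilities default to the ESR1
  # margins in both prior-therapy strata
  list(wildtype_cdk = wt, wildtype_nocdk = wt,
       mutated_cdk = mut, mutated_nocdk = mut)
}

#' Configuration for the synthetic trial generator
#'
#' Assembles and validates the parameters of [simulate_trial()]. Defaults
#' are calibrated to the study conditions the package emulates: a 400 mg
#' once-daily oral SERD with geometric-mean steady-state trough
#' concentration 466 ng/mL, a typical absorption peak near 3 h, receptor
#' occupancy of 90 percent at 100 ng/mL, no dose-limiting toxicity observed
#' up to 600 mg/day, and response-category frequencies by baseline ESR1
#' status taken from the expansion-cohort response table.
#'
#' @param seed Integer seed; every draw in [simulate_trial()] flows from it.
#' @param n_patients Number of patients.
#' @param ladder A [dose_ladder()].
#' @param assigned_level Label of the dose level all patients receive
#'   (default `"DL4"`, 400 mg QD).
#' @param pk One-compartment oral PK parameters: `ka` (1/h), `cl_f` (L/h),
#'   `v_f` (L), lognormal coefficients of variation `cv_ka`, `cv_cl`,
#'   `cv_v`, residual assay CV `resid_cv`, and `lloq` (ng/mL).
#' @param emax Occupancy model: `emax` (percent) and `ec50` (ng/mL).
#' @param dlt_logistic `c(intercept, slope)` of a logistic model for DLT
#'   probability on log daily dose.
#' @param response_probs Named list of outcome probability vectors
#'   (`cr`, `pr`, `sd_ge24`, `sd_lt24`, `pd`, `ne`), one per stratum
#'   `{wildtype, mutated} x {cdk, nocdk}`.
#' @param esr1_mut_prob Probability of baseline ESR1-mutated status.
#' @param prior_cdk_prob Probability of prior CDK4/6-inhibitor exposure.
#' @param af_decline Allele-frequency dynamics: lognormal baseline
#'   (`baseline_meanlog`, `baseline_sdlog`), multiplicative on-treatment
#'   factor (`factor_meanlog`, `factor_sdlog`), detection `threshold`
#'   (fraction), and `max_variants` per patient.
#' @param pk_times Sampling times (h) for the steady-state profile.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 49L,
                       ladder = default_dose_ladder(),
                       assigned_level = "DL4",
                       pk = list(),
                       emax = list(),
                       dlt_logistic = c(intercept = -6, slope = 0.5),
                       response_probs = .default_response_probs(),
                       esr1_mut_prob = 0.45,
                       prior_cdk_prob = 0.61,
                       af_decline = list(),
                       pk_times = c(0, 0.5, 1, 2, 3, 4, 6, 8, 12, 24)) {
  pk_def <- list(ka = 0.811, cl_f = 10.6, v_f = 120.2,
                 cv_ka = 0.30, cv_cl = 0.25, cv_v = 0.25,
                 resid_cv = 0.10, lloq = 5)
  pk <- utils::modifyList(pk_def, pk)
  emax_def <- list(emax = 100, ec50 = 100 / 9)
  emax <- utils::modifyList(emax_def, emax)
  af_def <- list(baseline_meanlog = log(0.005), baseline_sdlog = 1.5,
                 factor_meanlog = log(0.25), factor_sdlog = 1.0,
                 threshold = 5e-4, max_variants = 3L)
  af_decline <- utils::modifyList(af_def, af_decline)

  stopifnot(inherits(ladder, "dose_ladder"),
            assigned_level %in% ladder$label,
            n_patients >= 1, length(seed) == 1L)
  if (emax$ec50 <= 0) stop("EC50 must be positive", call. = FALSE)
  if (emax$emax < 0 || emax$emax > 100) {
    stop("Emax must lie in [0, 100] percent", call. = FALSE)
  }
  with(pk, stopifnot(ka > 0, cl_f > 0, v_f > 0, cv_ka >= 0, cv_cl >= 0,
                     cv_v >= 0, resid_cv >= 0, lloq >= 0))
  needed <- c("cr", "pr", "sd_ge24", "sd_lt24", "pd", "ne")
  for (nm in names(response_probs)) {
    p <- response_probs[[nm]]
    if (!all(needed %in% names(p)) || any(p < 0 | p > 1) ||
        abs(sum(p) - 1) > 1e-8) {
      stop("response probabilities for stratum '", nm,
           "' must be named ", paste(needed, collapse = "/"),
           ", lie in [0, 1] and sum to 1", call. = FALSE)
    }
  }
  if (!all(c("wildtype_cdk", "wildtype_nocdk", "mutated_cdk",
             "mutated_nocdk") %in% names(response_probs))) {
    stop("response_probs must cover all four ESR1 x prior-CDK4/6i strata",
         call. = FALSE)
  }
  stopifnot(esr1_mut_prob >= 0, esr1_mut_prob <= 1,
            prior_cdk_prob >= 0, prior_cdk_prob <= 1,
            af_decline$threshold > 0, af_decline$threshold < 1)
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         ladder = ladder, assigned_level = assigned_level, pk = pk,
         emax = emax, dlt_logistic = dlt_logistic,
         response_probs = response_probs, esr1_mut_prob = esr1_mut_prob,
         prior_cdk_prob = prior_cdk_prob, af_decline = af_decline,
         pk_times = pk_times),
    class = "sim_config"
  )
}

#' Closed-form one-compartment oral concentration profile
#'
#' `C(t) = (D ka) / (V (ka - ke)) * (exp(-ke t) - exp(-ka t))` summed over
#' `n_doses` administrations spaced `tau` hours apart (superposition), where
#' `ke = CL/F / V/F`. Apparent (oral) parameters absorb bioavailability.
#'
#' @param dose_mg Dose per administration, mg.
#' @param times Times in hours since the first dose (`>= 0`).
#' @param ka Absorption rate constant, 1/h.
#' @param cl_f Apparent clearance, L/h.
#' @param v_f Apparent volume, L.
#' @param n_doses Number of doses given `tau` apart (default 1).
#' @param tau Dosing interval, h (default 24).
#' @return Concentrations in ng/mL.
#' @examples
#' pk_profile(400, c(0, 1, 3, 24), ka = 0.811, cl_f = 10.6, v_f = 120.2)
#' @export
pk_profile <- function(dose_mg, times, ka, cl_f, v_f, n_doses = 1, tau = 24) {
  stopifnot(all(times >= 0), dose_mg > 0, ka > 0, cl_f > 0, v_f > 0,
            n_doses >= 1, tau > 0)
  ke <- cl_f / v_f
  if (abs(ka - ke) < 1e-10) {
    stop("ka equals ke: the two-exponential oral model is degenerate; ",
         "perturb one rate constant", call. = FALSE)
  }
  d_ng <- dose_mg * 1e6
  v_ml <- v_f * 1000
  scale <- d_ng * ka / (v_ml * (ka - ke))
  out <- numeric(length(times))
  for (d in seq_len(n_doses) - 1L) {
    td <- times - d * tau
    pos <- td > 0
    out[pos] <- out[pos] + scale * (exp(-ke * td[pos]) - exp(-ka * td[pos]))
  }
  out
}

#' Generate a synthetic patient-level trial dataset
#'
#' Draws a complete seeded dataset with the statistical structure the
#' analysis pipeline assumes: steady-state PK from a one-compartment oral
#' model with lognormal between-patient variability, receptor occupancy tied
#' to the individual trough concentration through the Emax model (exactly,
#' by construction), paired PET scans whose corrected uptake reproduces that
#' occupancy, timepoint RECIST responses drawn per stratum and expanded into
#' assessment series, dose-limiting-toxicity flags from a logistic
#' dose-toxicity model, ESR1 allele frequencies declining multiplicatively
#' with censoring below the detection threshold, and paired IHC measures.
#'
#' @param config A [sim_config()].
#' @param families Which record families to generate; a subset of
#'   `c("patients", "dosing", "pk", "pet", "recist", "esr1", "ihc")`. The
#'   patient-level table is always produced. Identical `config` and
#'   `families` give identical output.
#' @return Object of class `sim_trial`: a list of data frames (one per
#'   family) plus the config.
#' @examples
#' trial <- simulate_trial(sim_config(seed = 7, n_patients = 12))
#' head(trial$patients)
#' @export
simulate_trial <- function(config,
                           families = c("patients", "dosing", "pk", "pet",
                                        "recist", "esr1", "ihc")) {
  stopifnot(inherits(config, "sim_config"))
  families <- match.arg(families, several.ok = TRUE)
  set.seed(config$seed)
  n <- config$n_patients
  pk <- config$pk
  lad <- config$ladder
  lvl <- lad[lad$label == config$assigned_level, ]

  id <- sprintf("P%04d", seq_len(n))
  esr1 <- ifelse(runif(n) < config$esr1_mut_prob, "mutated", "wildtype")
  cdk <- runif(n) < config$prior_cdk_prob
  stratum <- paste0(esr1, ifelse(cdk, "_cdk", "_nocdk"))

  ka_i <- pk$ka * rlnorm(n, 0, .sdlog(pk$cv_ka))
  cl_i <- pk$cl_f * rlnorm(n, 0, .sdlog(pk$cv_cl))
  v_i <- pk$v_f * rlnorm(n, 0, .sdlog(pk$cv_v))
  ke_i <- cl_i / v_i
  clash <- abs(ka_i - ke_i) < 1e-8
  ka_i[clash] <- ka_i[clash] * (1 + 1e-6)

  ctrough <- .ss_conc(24, lvl$dose_mg, ka_i, ke_i, v_i)
  occ <- config$emax$emax * ctrough / (config$emax$ec50 + ctrough)

  p_dlt <- plogis(config$dlt_logistic[[1]] +
                    config$dlt_logistic[[2]] * log(lvl$daily_mg))
  dlt <- runif(n) < p_dlt
  dlt_day <- ifelse(dlt, sample.int(28, n, replace = TRUE), NA_integer_)

  cats <- c("cr", "pr", "sd_ge24", "sd_lt24", "pd", "ne")
  category <- character(n)
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    category[idx] <- sample(cats, length(idx), replace = TRUE,
                            prob = config$response_probs[[s]])
  }
  base_weeks <- c(cr = 48, pr = 40, sd_ge24 = 36, sd_lt24 = 26,
                  pd = 9, ne = 4)
  duration_weeks <- round(base_weeks[category] *
                            rlnorm(n, 0, 0.15), 1)
  duration_weeks <- pmax(duration_weeks, 4)

  patients <- data.frame(
    patient_id = id, esr1_status = esr1, prior_cdk = cdk,
    level = lvl$label, dose_mg = lvl$dose_mg, schedule = lvl$schedule,
    daily_mg = lvl$daily_mg, ka = ka_i, cl_f = cl_i, v_f = v_i,
    ctrough_ngml = ctrough, occupancy_pct = occ,
    dlt = dlt, dlt_day = dlt_day, category = category,
    duration_weeks = unname(duration_weeks),
    stringsAsFactors = FALSE
  )
  out <- list(patients = patients)

  if ("dosing" %in% families) {
    n_days <- pmax(round(patients$duration_weeks * 7), 3)
    # dose omitted on day 2 (the fed-state single-dose day follows on day 3)
    day_list <- lapply(n_days, function(nd) c(1L, 3:nd))
    lens <- lengths(day_list)
    out$dosing <- data.frame(
      patient_id = rep(id, lens), day = unlist(day_list),
      dose_mg = rep(lvl$dose_mg, sum(lens)),
      schedule = rep(lvl$schedule, sum(lens)),
      stringsAsFactors = FALSE
    )
  }

  if ("pk" %in% families) {
    tms <- config$pk_times
    m <- length(tms)
    conc <- .ss_conc(rep(tms, n), rep(lvl$dose_mg, n * m),
                     rep(ka_i, each = m), rep(ke_i, each = m),
                     rep(v_i, each = m))
    conc <- conc * rlnorm(n * m, 0, .sdlog(pk$resid_cv))
    blq <- conc < pk$lloq
    out$pk <- data.frame(
      patient_id = rep(id, each = m), day = 22L, time_h = rep(tms, n),
      conc_ngml = ifelse(blq, 0, conc), blq = blq,
      stringsAsFactors = FALSE
    )
  }

  if ("pet" %in% families) {
    n_les <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    tot <- sum(n_les)
    pid <- rep(id, n_les)
    occ_l <- rep(occ, n_les)
    lesion <- unlist(lapply(n_les, seq_len))
    background <- rlnorm(tot, log(1.0), 0.2)
    specific <- rlnorm(tot, log(3.0), 0.4)
    out$pet <- rbind(
      data.frame(patient_id = pid, lesion = lesion, timepoint = "screening",
                 suvmax = background + specific, background = background,
                 stringsAsFactors = FALSE),
      data.frame(patient_id = pid, lesion = lesion, timepoint = "on_treatment",
                 suvmax = background + specific * (1 - occ_l / 100),
                 background = background, stringsAsFactors = FALSE)
    )
  }

  if ("recist" %in% families) {
    traj <- list(
      cr = list(day = c(56, 112, 168), response = c("PR", "CR", "CR")),
      pr = list(day = c(56, 112, 168, 224),
                response = c("PR", "PR", "PR", "PD")),
      sd_ge24 = list(day = c(56, 112, 168, 224),
                     response = c("SD", "SD", "SD", "PD")),
      sd_lt24 = list(day = c(56, 112, 168), response = c("SD", "SD", "PD")),
      pd = list(day = 56, response = "PD"),
      ne = list(day = 56, response = "NE")
    )
    lens <- vapply(category, function(ct) length(traj[[ct]]$day), integer(1))
    out$recist <- data.frame(
      patient_id = rep(id, lens),
      day = unlist(lapply(category, function(ct) traj[[ct]]$day)),
      response = unlist(lapply(category, function(ct) traj[[ct]]$response)),
      stringsAsFactors = FALSE
    )
  }

  if ("esr1" %in% families) {
    af <- config$af_decline
    mut_idx <- which(esr1 == "mutated")
    rows <- lapply(mut_idx, function(i) {
      k <- sample.int(af$max_variants, 1, prob = c(0.6, 0.3, 0.1)[seq_len(af$max_variants)])
      vars <- sample(.esr1_panel, k, prob = .esr1_weights)
      af1 <- rlnorm(k, af$baseline_meanlog, af$baseline_sdlog)
      af1 <- pmin(af1, 0.5)
      af2 <- pmin(af1 * rlnorm(k, af$factor_meanlog, af$factor_sdlog), 1)
      data.frame(
        patient_id = id[i],
        variant = rep(vars, 2),
        timepoint = rep(c("C1D1", "C2D28"), each = k),
        af = c(ifelse(af1 >= af$threshold, af1, 0),
               ifelse(af2 >= af$threshold, af2, 0)),
        detected = c(af1 >= af$threshold, af2 >= af$threshold),
        stringsAsFactors = FALSE
      )
    })
    out$esr1 <- if (length(rows)) do.call(rbind, rows) else
      data.frame(patient_id = character(0), variant = character(0),
                 timepoint = character(0), af = numeric(0),
                 detected = logical(0), stringsAsFactors = FALSE)
  }

  if ("ihc" %in% families) {
    er0 <- ifelse(runif(n) < 0.2, 0, round(rbeta(n, 2, 1) * 300))
    pgr0 <- ifelse(runif(n) < 0.35, 0, round(rbeta(n, 1.5, 1.5) * 300))
    ki0 <- round(rbeta(n, 2, 3) * 60, 1)
    er_fac <- pmin(rlnorm(n, log(0.42), 0.35), 1)
    pgr_fac <- pmin(rlnorm(n, log(0.12), 0.60), 1)
    ki_delta <- rnorm(n, -8, 12)
    er1 <- round(er0 * er_fac)
    pgr1 <- round(pgr0 * pgr_fac)
    ki1 <- pmin(pmax(ki0 + ki_delta, 0), 100)
    out$ihc <- data.frame(
      patient_id = rep(id, times = 6),
      timepoint = rep(rep(c("screening", "C2D28"), each = n), times = 3),
      marker = rep(c("ER", "PgR", "Ki67"), each = 2 * n),
      value = c(er0, er1, pgr0, pgr1, ki0, round(ki1, 1)),
      stringsAsFactors = FALSE
    )
  }

  structure(c(out, list(config = config)), class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  fams <- setdiff(names(x), "config")
  cat(sprintf("Synthetic trial: %d patients at %s (seed %d)\n",
              x$config$n_patients, x$config$assigned_level, x$config$seed))
  for (f in fams) cat(sprintf("  $%-8s %6d rows\n", f, nrow(x[[f]])))
  invisible(x)
}

#' Extract one patient's course from a synthetic trial
#'
#' @param trial A [simulate_trial()] result.
#' @param patient_id One patient identifier.
#' @return Named list of this patient's rows from each record family.
#' @export
patient_course <- function(trial, patient_id) {
  stopifnot(inherits(trial, "sim_trial"))
  fams <- setdiff(names(trial), "config")
  if (!patient_id %in% trial$patients$patient_id) {
    stop("unknown patient_id", call. = FALSE)
  }
  lapply(setNames(fams, fams), function(f) {
    d <- trial[[f]]
    d[d$patient_id == patient_id, , drop = FALSE]
  })
}

#' Write a synthetic trial as delimited text tables
#'
#' One CSV per record family plus a JSON manifest recording the seed,
#' patient count and file list.
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_trial_tables <- function(trial, dir) {
  stopifnot(inherits(trial, "sim_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fams <- setdiff(names(trial), "config")
  files <- character(0)
  for (f in fams) {
    path <- file.path(dir, paste0(f, ".csv"))
    write.csv(trial[[f]], path, row.names = FALSE)
    files[f] <- basename(path)
  }
  manifest <- list(
    seed = trial$config$seed,
    n_patients = trial$config$n_patients,
    assigned_level = trial$config$assigned_level,
    families = as.list(files)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
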