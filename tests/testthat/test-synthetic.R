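test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99, n_patients = 30)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  for (f in setdiff(names(t1), "config")) expect_identical(t1[[f]], t2[[f]])
  t3 <- simulate_trial(sim_config(seed = 100, n_patients = 30))
  expect_false(identical(t1$patients$ctrough_ngml,
                         t3$patients$ctrough_ngml))
})

test_that("configuration validation rejects malformed inputs", {
  rp <- list(
    wildtype_cdk = c(cr = 0.5, pr = 0.5, sd_ge24 = 0.2, sd_lt24 = 0,
                     pd = 0, ne = 0),  # sums to 1.2
    wildtype_nocdk = c(cr = 1, pr = 0, sd_ge24 = 0, sd_lt24 = 0, pd = 0,
                       ne = 0),
    mutated_cdk = c(cr = 1, pr = 0, sd_ge24 = 0, sd_lt24 = 0, pd = 0,
                    ne = 0),
    mutated_nocdk = c(cr = 1, pr = 0, sd_ge24 = 0, sd_lt24 = 0, pd = 0,
                      ne = 0)
  )
  expect_error(sim_config(response_probs = rp), "sum to 1")
  expect_error(sim_config(emax = list(ec50 = -1)), "EC50")
  expect_error(sim_config(assigned_level = "DL99"), "assigned_level")
})

test_that("a toxicity-free configuration produces no DLT flags", {
  cfg <- sim_config(seed = 5, n_patients = 200,
                    dlt_logistic = c(intercept = -1e6, slope = 0))
  trial <- simulate_trial(cfg, families = "patients")
  expect_equal(sum(trial$patients$dlt), 0L)
})

test_that("single-dose profiles start at zero and peak at the analytic tmax", {
  expect_equal(pk_profile(400, 0, 0.811, 10.6, 120.2), 0)
  # ka >> ke: tmax -> log(ka/ke) / (ka - ke)
  ka <- 5; cl <- 10.6; v <- 120.2; ke <- cl / v
  tmax_analytic <- log(ka / ke) / (ka - ke)
  tg <- seq(0.01, 6, by = 0.001)
  conc <- pk_profile(100, tg, ka, cl, v)
  expect_lt(abs(tg[which.max(conc)] - tmax_analytic), 0.002)
  expect_true(all(conc >= 0))
  expect_error(pk_profile(100, 1, ka = 0.1, cl_f = 12, v_f = 120),
               "degenerate")
})

test_that("superposition troughs approach steady state monotonically", {
  troughs <- vapply(1:12, function(nd) {
    pk_profile(400, nd * 24, 0.811, 10.6, 120.2, n_doses = nd)
  }, numeric(1))
  expect_true(all(diff(troughs) > 0))
  ss <- earlyphase:::.ss_conc(24, 400, 0.811, 10.6 / 120.2, 120.2)
  expect_true(all(troughs < ss + 1e-9))
  expect_lt(abs(troughs[12] - ss) / ss, 0.01)
})

test_that("the calibrated generator hits the target trough geometric mean", {
  trial <- simulate_trial(sim_config(seed = 314, n_patients = 10000),
                          families = "patients")
  gs <- geometric_summary(trial$patients$ctrough_ngml)
  expect_lt(abs(gs$gm - 466) / 466, 0.05)
})

test_that("stratum outcome frequencies obey the law of large numbers", {
  cfg <- sim_config(seed = 271, n_patients = 10000)
  trial <- simulate_trial(cfg, families = "patients")
  p <- trial$patients
  stratum <- paste0(p$esr1_status, ifelse(p$prior_cdk, "_cdk", "_nocdk"))
  for (s in unique(stratum)) {
    idx <- stratum == s
    probs <- cfg$response_probs[[s]]
    obs <- table(factor(p$category[idx], levels = names(probs)))
    # zero-probability categories must never occur
    expect_true(all(obs[probs == 0] == 0))
    # goodness of fit of the whole outcome distribution per stratum;
    # individual category deviations stay within ~3 standard errors
    gof <- suppressWarnings(
      stats::chisq.test(obs[probs > 0], p = probs[probs > 0]))
    expect_gt(gof$p.value, 1e-3, label = sprintf("stratum %s", s))
    phat <- as.numeric(obs) / sum(obs)
    se <- sqrt(probs * (1 - probs) / sum(obs))
    expect_lt(max(abs(phat - probs) / pmax(se, 1e-12)), 4,
              label = sprintf("stratum %s max z", s))
  }
})

test_that("generated occupancy is exactly Emax of the generated trough", {
  cfg <- sim_config(seed = 17, n_patients = 500)
  trial <- simulate_trial(cfg, families = "patients")
  p <- trial$patients
  expect_equal(p$occupancy_pct,
               cfg$emax$emax * p$ctrough_ngml /
                 (cfg$emax$ec50 + p$ctrough_ngml),
               tolerance = 1e-12)
})

test_that("paired PET scans reproduce the patient's occupancy", {
  trial <- simulate_trial(sim_config(seed = 23, n_patients = 40),
                          families = c("patients", "pet"))
  pet <- trial$pet
  for (pid in trial$patients$patient_id[1:10]) {
    s <- pet[pet$patient_id == pid & pet$timepoint == "screening", ]
    o <- pet[pet$patient_id == pid & pet$timepoint == "on_treatment", ]
    occ <- fes_occupancy(s$suvmax, s$background, o$suvmax, o$background)
    expect_equal(
      occ,
      trial$patients$occupancy_pct[trial$patients$patient_id == pid],
      tolerance = 1e-8)
  }
})

test_that("derived best overall responses recover the drawn categories", {
  trial <- simulate_trial(sim_config(seed = 37, n_patients = 150),
                          families = c("patients", "recist"))
  rec <- trial$recist
  for (i in seq_len(nrow(trial$patients))) {
    pid <- trial$patients$patient_id[i]
    d <- rec[rec$patient_id == pid, ]
    b <- best_overall_response(d$day, d$response)
    expected <- switch(trial$patients$category[i],
                       cr = "CR", pr = "PR", sd_ge24 = "SD", sd_lt24 = "SD",
                       pd = "PD", ne = "NE")
    expect_equal(b$category, expected, label = pid)
    expect_equal(b$clinical_benefit,
                 trial$patients$category[i] %in% c("cr", "pr", "sd_ge24"),
                 label = pid)
  }
})

test_that("generated tables respect their domain invariants", {
  trial <- simulate_trial(sim_config(seed = 61, n_patients = 80))
  expect_true(all(trial$pk$conc_ngml >= 0))
  expect_true(all(trial$pk$conc_ngml[trial$pk$blq] == 0))
  expect_true(all(trial$pk$conc_ngml[!trial$pk$blq] >= 5))
  expect_true(all(trial$esr1$af >= 0 & trial$esr1$af <= 1))
  expect_true(all(trial$esr1$detected == (trial$esr1$af >= 5e-4)))
  ihc <- trial$ihc
  hs <- ihc$value[ihc$marker %in% c("ER", "PgR")]
  expect_true(all(hs >= 0 & hs <= 300))
  ki <- ihc$value[ihc$marker == "Ki67"]
  expect_true(all(ki >= 0 & ki <= 100))
  # assessment days strictly increasing within patient
  by_pt <- split(trial$recist$day, trial$recist$patient_id)
  expect_true(all(vapply(by_pt, function(d) all(diff(d) > 0), logical(1))))
  # dosing skips day 2 only
  by_dose <- split(trial$dosing$day, trial$dosing$patient_id)
  expect_true(all(vapply(by_dose, function(d) {
    identical(d[1:2], c(1L, 3L)) && all(diff(d[-1]) == 1)
  }, logical(1))))
})

test_that("trial tables round-trip through delimited text with a manifest", {
  trial <- simulate_trial(sim_config(seed = 8, n_patients = 10))
  dir <- file.path(tempdir(), "eph-trial")
  mpath <- write_trial_tables(trial, dir)
  expect_true(file.exists(file.path(dir, "patients.csv")))
  man <- jsonlite::read_json(mpath)
  expect_equal(man$seed, 8L)
  expect_equal(man$n_patients, 10L)
  back <- utils::read.csv(file.path(dir, "recist.csv"),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(trial$recist))
  pc <- patient_course(trial, trial$patients$patient_id[3])
  expect_equal(nrow(pc$patients), 1L)
  expect_true(all(pc$pk$patient_id == trial$patients$patient_id[3]))
})
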