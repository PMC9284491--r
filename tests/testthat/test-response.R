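test_that("Clopper-Pearson intervals reproduce published response tables", {
  # (k, n) -> published 90% CI in percent at one decimal
  cases <- list(
    list(5, 46, c(4.4, 21.5)),    # expansion ORR
    list(13, 46, c(17.6, 41.1)),  # expansion CBR
    list(1, 16, c(0.3, 26.4)),    # escalation ORR
    list(8, 16, c(27.9, 72.1)),   # escalation CBR
    list(4, 26, c(5.4, 31.8)),    # ESR1 wild-type ORR
    list(9, 26, c(19.4, 52.6)),   # ESR1 wild-type CBR
    list(1, 19, c(0.3, 22.6)),    # ESR1 mutated ORR
    list(4, 19, c(7.5, 41.9)),    # ESR1 mutated CBR
    list(5, 27, c(7.6, 35.1)),    # <=3 prior lines ORR
    list(12, 27, c(28.0, 61.8)),  # <=3 prior lines CBR
    list(4, 11, c(13.5, 65.0)),   # no prior CDK4/6i/mTORi/fulv ORR
    list(6, 11, c(27.1, 80.0)),   # no prior CDK4/6i/mTORi/fulv CBR
    list(5, 19, c(11.0, 47.6)),   # no prior CDK4/6i ORR
    list(10, 19, c(32.0, 72.6)),  # no prior CDK4/6i CBR
    list(5, 45, c(4.5, 22.0)),    # interim ORR
    list(13, 45, c(18.0, 42.0))   # interim CBR
  )
  for (cs in cases) {
    ci <- 100 * clopper_pearson(cs[[1]], cs[[2]], 0.90)
    expect_equal(unname(round(ci, 1)), cs[[3]],
                 info = sprintf("k=%d n=%d", cs[[1]], cs[[2]]))
  }
})

test_that("Clopper-Pearson boundary cases use closed forms", {
  expect_equal(clopper_pearson(0, 12, 0.90)[["lower"]], 0)
  expect_equal(clopper_pearson(12, 12, 0.90)[["upper"]], 1)
  # k = 1 lower bound closed form: 1 - (0.95)^(1/n)
  expect_equal(clopper_pearson(1, 16, 0.90)[["lower"]],
               1 - 0.95^(1 / 16), tolerance = 1e-10)
  expect_error(clopper_pearson(5, 4), "k must lie")
})

test_that("exact coverage is at least nominal for all k, n <= 30", {
  level <- 0.90
  for (n in c(5, 12, 19, 30)) {
    bounds <- vapply(0:n, function(k) clopper_pearson(k, n, level),
                     numeric(2))
    for (p in seq(0.02, 0.98, by = 0.08)) {
      covered <- bounds[1, ] <= p & p <= bounds[2, ]
      expect_gte(sum(dbinom(0:n, n, p) * covered), level)
    }
  }
  # interval contains k/n; width shrinks with n at fixed k/n
  ci1 <- clopper_pearson(4, 16); ci2 <- clopper_pearson(16, 64)
  expect_true(ci1[["lower"]] <= 0.25 && 0.25 <= ci1[["upper"]])
  expect_lt(diff(ci2), diff(ci1))
})

test_that("confirmed responses require a second assessment 28+ days later", {
  b <- best_overall_response(c(56, 84), c("PR", "PR"))
  expect_equal(b$category, "PR")
  expect_true(b$confirmed)
  expect_true(b$clinical_benefit)
  # 27-day spacing is not confirmation
  b <- best_overall_response(c(56, 83, 120), c("PR", "PR", "PD"))
  expect_equal(b$category, "SD")
  expect_false(b$confirmed)
  # CR needs a confirming CR; CR then PR confirms only PR
  b <- best_overall_response(c(56, 112), c("CR", "PR"))
  expect_equal(b$category, "PR")
  b <- best_overall_response(c(56, 112, 168), c("PR", "CR", "CR"))
  expect_equal(b$category, "CR")
})

test_that("unconfirmed responses downgrade per the stable-disease rule", {
  b <- best_overall_response(c(56, 70), c("PR", "PD"))
  expect_equal(b$category, "SD")  # day 56 >= 6 weeks from baseline
  expect_false(b$clinical_benefit)
  b <- best_overall_response(c(28, 40), c("PR", "PD"))
  expect_equal(b$category, "PD")  # 4 weeks: below the SD minimum
})

test_that("prolonged stable disease constitutes clinical benefit", {
  b <- best_overall_response(c(56, 112, 170), c("SD", "SD", "SD"))
  expect_equal(b$category, "SD")
  expect_gte(b$sd_duration_weeks, 24)
  expect_true(b$clinical_benefit)
  b <- best_overall_response(c(56, 112, 160), c("SD", "SD", "PD"))
  expect_false(b$clinical_benefit)
})

test_that("BOR agrees with rule-set enumeration over short series", {
  # independent oracle: direct restatement of the category rules, evaluated
  # by explicit case analysis over every length-3 series on the q8w grid
  oracle <- function(days, rsp, sd_min_days = 42, confirm = 28) {
    pd_i <- which(rsp == "PD")[1]
    pre <- if (is.na(pd_i)) seq_along(days) else seq_len(pd_i - 1)
    d <- days[pre]; r <- rsp[pre]
    conf <- NA
    for (i in seq_along(r)) for (j in seq_along(r)) {
      if (j > i && r[i] %in% c("CR", "PR") && r[j] %in% c("CR", "PR") &&
          d[j] - d[i] >= confirm) {
        cat_ij <- if (r[i] == "CR" && r[j] == "CR") "CR" else "PR"
        if (is.na(conf) || (conf == "PR" && cat_ij == "CR")) conf <- cat_ij
      }
    }
    if (!is.na(conf)) return(conf)
    ok <- r %in% c("CR", "PR", "SD")
    if (any(ok & d >= sd_min_days)) return("SD")
    if (!is.na(pd_i)) return("PD")
    "NE"
  }
  days <- c(56, 112, 168)
  lv <- c("CR", "PR", "SD", "PD", "NE")
  for (a in lv) for (b in lv) for (cc in lv) {
    rsp <- c(a, b, cc)
    got <- best_overall_response(days, rsp)$category
    expect_equal(got, oracle(days, rsp),
                 info = paste(rsp, collapse = ","))
  }
})

test_that("BOR is invariant to NE assessments appended after confirmation", {
  b1 <- best_overall_response(c(56, 112), c("PR", "PR"))
  b2 <- best_overall_response(c(56, 112, 168, 224), c("PR", "PR", "NE", "NE"))
  expect_equal(b1$category, b2$category)
  expect_equal(b1$confirmed, b2$confirmed)
  expect_equal(b1$clinical_benefit, b2$clinical_benefit)
})

test_that("empty series yield a flagged non-evaluable result", {
  b <- best_overall_response(numeric(0), character(0))
  expect_equal(b$category, "NE")
  expect_true(b$empty_series)
})

test_that("population summaries reproduce the published expansion table", {
  tbl <- summarize_population(
    response_counts(cr = 1, pr = 4, sd_ge24 = 8, sd_lt24 = 11, pd = 20,
                    ne = 2))
  expect_equal(tbl$n, 46L)
  expect_equal(tbl$orr$k, 5L)
  expect_equal(round(tbl$orr$pct, 1), 10.9)
  expect_equal(unname(round(tbl$orr$ci_pct, 1)), c(4.4, 21.5))
  expect_equal(tbl$cbr$k, 13L)
  expect_equal(round(tbl$cbr$pct, 1), 28.3)
  expect_equal(unname(round(tbl$cbr$ci_pct, 1)), c(17.6, 41.1))
})

test_that("subgroup summaries match the ESR1-status columns", {
  wt <- summarize_population(
    response_counts(cr = 1, pr = 3, sd_ge24 = 5, sd_lt24 = 5, pd = 11,
                    ne = 1), population = "ESR1 wild-type")
  expect_equal(round(wt$orr$pct, 1), 15.4)
  expect_equal(round(wt$cbr$pct, 1), 34.6)
  mut <- summarize_population(
    response_counts(cr = 0, pr = 1, sd_ge24 = 3, sd_lt24 = 6, pd = 8,
                    ne = 1), population = "ESR1 mutated")
  expect_equal(round(mut$orr$pct, 1), 5.3)
  expect_equal(round(mut$cbr$pct, 1), 21.1)
})

test_that("ORR never exceeds CBR and empty populations are well-defined", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(0:5, 6, replace = TRUE)
    s <- summarize_population(response_counts(k[1], k[2], k[3], k[4], k[5],
                                              k[6]))
    if (s$n > 0) expect_lte(s$orr$k, s$cbr$k)
  }
  s0 <- summarize_population(response_counts())
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$orr$pct))
})

test_that("relative dose intensity follows the dosing-day convention", {
  # 10 weeks = 69 dosing days (day-2 omission); 69 x 400 mg given
  expect_equal(relative_dose_intensity(27600, 10, 400), 100)
  expect_equal(relative_dose_intensity(0, 10, 400), 0)
  expect_equal(relative_dose_intensity(13800, 10, 400), 50)  # half doses
  expect_error(relative_dose_intensity(100, 1 / 7, 400), "duration")
})

test_that("waterfall metrics capture best change and shrinkage", {
  w <- waterfall_metrics(50, c(45, 35, 40))
  expect_equal(w$best_change_pct, -30)
  expect_true(w$shrinkage)
  w <- waterfall_metrics(50, c(50, 55))
  expect_equal(w$best_change_pct, 0)
  expect_false(w$shrinkage)
  expect_true(waterfall_metrics(NA, c(40))$excluded)
  # cohort with 10 of 16 shrinking
  best <- c(rep(-10, 10), rep(5, 6))
  shr <- vapply(best, function(b) {
    waterfall_metrics(100, 100 * (1 + b / 100))$shrinkage
  }, logical(1))
  expect_equal(mean(shr), 0.625)
})
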