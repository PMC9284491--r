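#' Trapezoidal AUC with linear-up/log-down interpolation
#'
#' Area under the concentration-time curve by the trapezoidal rule. With
#' `method = "linuplogdown"` (the industry default for oral profiles),
#' segments where the concentration declines between two positive values use
#' the logarithmic trapezoid `dt * (c1 - c2) / log(c1 / c2)`; all other
#' segments (rising, flat, or touching zero) use the linear trapezoid.
#'
#' @param time Sample times in hours, strictly increasing.
#' @param conc Concentrations in ng/mL, nonnegative.
#' @param method `"linuplogdown"` or `"linear"`.
#' @return AUC in ng*h/mL.
#' @export
auc_trapezoid <- function(time, conc, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  stopifnot(length(time) == length(conc), length(time) >= 2,
            all(diff(time) > 0), all(conc >= 0))
  c1 <- conc[-length(conc)]; c2 <- conc[-1]; dt <- diff(time)
  seg <- ifelse(
    method == "linuplogdown" & c2 < c1 & c2 > 0,
    dt * (c1 - c2) / log(c1 / c2),
    dt * (c1 + c2) / 2
  )
  sum(seg)
}

#' Noncompartmental pharmacokinetic analysis of one profile
#'
#' Derives Cmax, tmax (earliest time on ties), AUC over `[0, tau]`,
#' the trough concentration at `tau`, and the apparent steady-state oral
#' clearance `CLss/F = dose / AUC` (with mg and ng*h/mL converted to L/h).
#'
#' Below-LLOQ handling: values flagged below the lower limit of
#' quantification before the first quantifiable sample are set to 0;
#' embedded or trailing below-LLOQ values are excluded from the profile.
#'
#' @param time Sample times in hours, strictly increasing, starting at or
#'   after 0.
#' @param conc Concentrations in ng/mL; below-LLOQ samples may be recorded
#'   as 0 or any value `< lloq`.
#' @param dose_mg Administered dose in mg.
#' @param tau Dosing interval in hours (default 24).
#' @param lloq Lower limit of quantification in ng/mL (default 5).
#' @param method AUC method, see [auc_trapezoid()].
#' @param steady_state Whether the profile is at steady state, in which case
#'   `dose / AUC` is reported as `clss_f` (default `TRUE`).
#' @return An object of class `pk_params`, or one with `evaluable = FALSE`
#'   if fewer than three quantifiable samples are available.
#' @examples
#' t <- c(0, 1, 2, 3, 4, 6, 8, 12, 24)
#' c <- c(0, 800, 1500, 1700, 1600, 1300, 1000, 700, 450)
#' nca(t, c, dose_mg = 400)
#' @export
nca <- function(time, conc, dose_mg, tau = 24, lloq = 5,
                method = c("linuplogdown", "linear"), steady_state = TRUE) {
  method <- match.arg(method)
  stopifnot(length(time) == length(conc), all(time >= 0),
            all(diff(time) > 0), all(conc >= 0), dose_mg > 0)
  quant <- conc >= lloq
  if (sum(quant) < 3) {
    return(structure(list(evaluable = FALSE, n_quantifiable = sum(quant)),
                     class = "pk_params"))
  }
  first_q <- which(quant)[1]
  # pre-first-quantifiable BLQ -> 0; embedded/trailing BLQ -> excluded
  pre <- seq_along(conc) < first_q
  conc[pre & !quant] <- 0
  keep <- quant | pre
  tt <- time[keep]; cc <- conc[keep]

  in_tau <- tt <= tau
  if (sum(in_tau) < 2) {
    return(structure(list(evaluable = FALSE, n_quantifiable = sum(quant)),
                     class = "pk_params"))
  }
  t_auc <- tt[in_tau]; c_auc <- cc[in_tau]
  auc <- auc_trapezoid(t_auc, c_auc, method)
  cmax <- max(c_auc)
  tmax <- t_auc[which.max(c_auc)]  # which.max returns the first maximum
  ctrough <- c_auc[length(c_auc)]
  clss_f <- if (steady_state && auc > 0) (dose_mg * 1e6 / auc) / 1000 else NA_real_
  structure(
    list(evaluable = TRUE, cmax = cmax, tmax = tmax, auc_0_tau = auc,
         ctrough = ctrough, clss_f = clss_f, dose_mg = dose_mg, tau = tau,
         method = method, n_quantifiable = sum(quant)),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("PK profile not evaluable (%d quantifiable samples)\n",
                x$n_quantifiable))
    return(invisible(x))
  }
  cat(sprintf("NCA (%s trapezoid), dose %g mg, tau %g h\n", x$method,
              x$dose_mg, x$tau))
  cat(sprintf("  Cmax %.4g ng/mL at tmax %.3g h\n", x$cmax, x$tmax))
  cat(sprintf("  AUC0-%gh %.6g ng*h/mL, Ctrough %.4g ng/mL\n", x$tau,
              x$auc_0_tau, x$ctrough))
  if (!is.na(x$clss_f)) cat(sprintf("  CLss/F %.3g L/h\n", x$clss_f))
  invisible(x)
}

#' Geometric mean and geometric coefficient of variation
#'
#' @param x Strictly positive values.
#' @return List with `gm = exp(mean(log x))` and
#'   `cv_pct = 100 * sqrt(exp(var(log x)) - 1)`.
#' @export
geometric_summary <- function(x) {
  if (any(!is.finite(x) | x <= 0)) {
    stop("geometric summaries require strictly positive values", call. = FALSE)
  }
  lx <- log(x)
  list(gm = exp(mean(lx)),
       cv_pct = if (length(x) > 1) 100 * sqrt(exp(sd(lx)^2) - 1) else 0)
}

#' Paired geometric mean ratio with confidence interval
#'
#' Geometric mean ratio `test / reference` from paired observations, with a
#' t-based confidence interval on the log scale (the standard
#' accumulation-ratio and bioequivalence analysis).
#'
#' @param test,reference Strictly positive paired measurements.
#' @param level Confidence level (default 0.90).
#' @return List of class `gmr_ci`: `gmr`, `lower`, `upper`, `n`. With fewer
#'   than two pairs, the interval is `NA`.
#' @export
paired_gmr_ci <- function(test, reference, level = 0.90) {
  stopifnot(length(test) == length(reference))
  if (any(test <= 0 | reference <= 0)) {
    stop("paired ratio requires strictly positive values", call. = FALSE)
  }
  d <- log(test) - log(reference)
  n <- length(d)
  gmr <- exp(mean(d))
  if (n < 2) {
    return(structure(list(gmr = gmr, lower = NA_real_, upper = NA_real_,
                          n = n, level = level), class = "gmr_ci"))
  }
  se <- sd(d) / sqrt(n)
  tq <- qt(1 - (1 - level) / 2, df = n - 1)
  structure(list(gmr = gmr, lower = exp(mean(d) - tq * se),
                 upper = exp(mean(d) + tq * se), n = n, level = level),
            class = "gmr_ci")
}

#' @export
print.gmr_ci <- function(x, ...) {
  cat(sprintf("Geometric mean ratio %.3g (%.0f%% CI %.3g-%.3g), n = %d\n",
              x$gmr, 100 * x$level, x$lower, x$upper, x$n))
  invisible(x)
}

#' Dose proportionality by the power model
#'
#' Fits `log(exposure) = a + b * log(dose)`; exposure is dose-proportional
#' when the slope confidence interval contains 1.
#'
#' @param dose Doses in mg (at least 3 distinct levels).
#' @param exposure Exposure metric (e.g. AUC in ng*h/mL), positive.
#' @param level Confidence level for the slope interval (default 0.95).
#' @return List: `slope`, `ci` (length 2), `proportional` (CI contains 1),
#'   and the fitted `lm` object.
#' @export
dose_proportionality <- function(dose, exposure, level = 0.95) {
  stopifnot(length(dose) == length(exposure), all(dose > 0), all(exposure > 0))
  if (length(unique(dose)) < 3) {
    stop("at least 3 distinct dose levels are required", call. = FALSE)
  }
  fit <- lm(log(exposure) ~ log(dose))
  slope <- unname(coef(fit)[2])
  ci <- unname(confint(fit, level = level)[2, ])
  list(slope = slope, ci = ci,
       proportional = ci[1] <= 1 && 1 <= ci[2], fit = fit)
}

#' Fraction of dose excreted in urine
#'
#' @param amount_mg Amount excreted over the collection interval, mg.
#' @param dose_mg Administered dose, mg (`> 0`).
#' @return Excreted fraction of the dose (0.001 = 0.1 percent).
#' @export
urine_fraction <- function(amount_mg, dose_mg) {
  stopifnot(all(dose_mg > 0), all(amount_mg >= 0))
  amount_mg / dose_mg
}
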