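#' Background-corrected SUVmax averaged over index lesions
#'
#' The scan-level uptake statistic: the mean over index lesions of the
#' body-weight-standardized maximum tracer uptake minus the background
#' uptake. Background correction is by subtraction; a lesion whose
#' background exceeds its SUVmax is clipped to zero specific uptake with a
#' warning, since negative specific binding is non-physical.
#'
#' @param suvmax Per-lesion maximum standardized uptake values (`>= 0`).
#' @param background Per-lesion background uptake values, same length.
#' @return Scalar corrected SUVmax.
#' @examples
#' suvmax_cor(c(4, 2), c(1, 1))  # 2.0
#' @export
suvmax_cor <- function(suvmax, background) {
  if (length(suvmax) == 0L) stop("at least one index lesion is required",
                                 call. = FALSE)
  stopifnot(length(suvmax) == length(background),
            all(suvmax >= 0), all(background >= 0))
  cor <- suvmax - background
  if (any(cor < 0)) {
    warning("background exceeds SUVmax for ", sum(cor < 0),
            " lesion(s); clipped to 0")
    cor <- pmax(cor, 0)
  }
  mean(cor)
}

#' Estrogen receptor occupancy from paired PET scans
#'
#' Occupancy is the percentage reduction in background-corrected SUVmax
#' between the on-treatment and screening scans:
#' `100 * (1 - cor_on / cor_screen)`. Values above 100 cannot occur (uptake
#' is nonnegative); negative values (increased on-treatment uptake) are
#' retained, not floored.
#'
#' @param screen_suvmax,screen_background Per-lesion values at screening.
#' @param on_suvmax,on_background Per-lesion values on treatment; the lesion
#'   set must match the screening scan.
#' @return Occupancy in percent, or `NA` (with a warning) when the
#'   screening corrected uptake is zero.
#' @examples
#' fes_occupancy(4, 0, 0.4, 0)  # 90
#' @export
fes_occupancy <- function(screen_suvmax, screen_background,
                          on_suvmax, on_background) {
  if (length(screen_suvmax) != length(on_suvmax)) {
    stop("paired scans must have matching lesion sets", call. = FALSE)
  }
  cs <- suvmax_cor(screen_suvmax, screen_background)
  co <- suvmax_cor(on_suvmax, on_background)
  if (cs == 0) {
    warning("screening corrected SUVmax is zero; occupancy undefined")
    return(NA_real_)
  }
  100 * (1 - co / cs)
}

#' Fit an Emax concentration-occupancy model
#'
#' Least-squares fit of `E = Emax * C / (EC50 + C)` to paired plasma
#' concentration / occupancy observations, via Levenberg-Marquardt
#' nonlinear least squares. At least four pairs spanning more than one
#' decade of concentration are required for identifiability; a fit whose
#' EC50 standard error exceeds the estimate is flagged `wide_ci`.
#'
#' @param conc Plasma concentrations in ng/mL (`>= 0`).
#' @param occupancy Occupancy percentages.
#' @param emax_start,ec50_start Optional starting values.
#' @return Object of class `emax_fit`: `emax`, `ec50`, standard errors,
#'   `wide_ci` flag and the underlying `nls` fit. Use [predict_emax()] for
#'   predicted occupancy.
#' @export
fit_emax <- function(conc, occupancy, emax_start = NULL, ec50_start = NULL) {
  stopifnot(length(conc) == length(occupancy), all(conc >= 0))
  pos <- conc[conc > 0]
  if (length(conc) < 4) stop("at least 4 pairs are required", call. = FALSE)
  if (length(pos) && max(pos) / min(pos) <= 10) {
    warning("concentrations span one decade or less; EC50 may be poorly identified")
  }
  if (is.null(emax_start)) emax_start <- max(occupancy)
  if (is.null(ec50_start)) ec50_start <- max(median(conc) / 10, 1e-3)
  dat <- data.frame(conc = conc, occ = occupancy)
  fit <- minpack.lm::nlsLM(
    occ ~ emax * conc / (ec50 + conc), data = dat,
    start = list(emax = emax_start, ec50 = ec50_start),
    lower = c(emax = 0, ec50 = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(
    list(emax = unname(est["emax"]), ec50 = unname(est["ec50"]),
         emax_se = unname(se["emax"]), ec50_se = unname(se["ec50"]),
         wide_ci = unname(se["ec50"] > abs(est["ec50"])), fit = fit),
    class = "emax_fit"
  )
}

#' Predicted occupancy from an Emax fit
#'
#' @param object An [fit_emax()] result.
#' @param conc Concentrations at which to predict, ng/mL.
#' @return Predicted occupancy percentages.
#' @export
predict_emax <- function(object, conc) {
  stopifnot(inherits(object, "emax_fit"), all(conc >= 0))
  object$emax * conc / (object$ec50 + conc)
}

#' @export
print.emax_fit <- function(x, ...) {
  cat(sprintf("Emax model fit: Emax %.3g%% (SE %.2g), EC50 %.3g ng/mL (SE %.2g)%s\n",
              x$emax, x$emax_se, x$ec50, x$ec50_se,
              if (x$wide_ci) " [poorly identified]" else ""))
  invisible(x)
}

#' Occupancy summary by dose level
#'
#' Median, minimum and maximum occupancy per dose level, honoring an
#' explicit exclusion list (e.g. scans outside the protocol window).
#'
#' @param occupancy Numeric occupancy percentages.
#' @param level Dose-level label per observation.
#' @param patient_id Optional patient identifier per observation, used by
#'   `exclude`.
#' @param exclude Patient identifiers to drop before summarizing.
#' @return A `data.frame`: `level`, `n`, `median`, `min`, `max`.
#' @export
occupancy_summary <- function(occupancy, level, patient_id = NULL,
                              exclude = NULL) {
  stopifnot(length(occupancy) == length(level))
  keep <- !is.na(occupancy)
  if (!is.null(exclude)) {
    stopifnot(!is.null(patient_id), length(patient_id) == length(occupancy))
    keep <- keep & !(patient_id %in% exclude)
  }
  occupancy <- occupancy[keep]; level <- level[keep]
  if (length(occupancy) == 0L) stop("no occupancy results to summarize",
                                    call. = FALSE)
  out <- do.call(rbind, lapply(split(occupancy, level), function(x) {
    data.frame(n = length(x), median = median(x), min = min(x), max = max(x))
  }))
  out$level <- rownames(out)
  rownames(out) <- NULL
  out[, c("level", "n", "median", "min", "max")]
}
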