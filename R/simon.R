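#' Simon two-stage design
#'
#' Construct a Simon two-stage design object. The boundary convention follows
#' Simon's original parameterization: accrual stops for futility after stage 1
#' if the number of responders among the first `n1` patients is `<= r1`
#' (a *binding* futility rule), and the null hypothesis is rejected at the end
#' of the trial if the total number of responders among all `n` patients is
#' `>= r + 1`. A trial protocol stated as "reject if at least 13 of 78
#' respond" therefore corresponds to `r = 12`.
#'
#' @param n1 Stage-1 sample size.
#' @param r1 Stage-1 futility boundary: stop if responders `<= r1`.
#' @param n Total sample size (`n >= n1`).
#' @param r Final fail boundary: reject the null if responders `>= r + 1`.
#' @param p0 Null (uninteresting) response probability.
#' @param p1 Alternative (target) response probability, `p1 > p0`.
#' @param alpha Nominal one-sided type I error bound.
#' @param beta Nominal type II error bound (power bound is `1 - beta`).
#' @return An object of class `simon_design`.
#' @examples
#' d <- simon_design(n1 = 45, r1 = 4, n = 78, r = 12, p0 = 0.10, p1 = 0.20)
#' simon_oc(d)
#' @export
simon_design <- function(n1, r1, n, r, p0 = 0.10, p1 = 0.20,
                         alpha = 0.05, beta = 0.20) {
  stopifnot(
    length(n1) == 1L, length(r1) == 1L, length(n) == 1L, length(r) == 1L,
    n1 == round(n1), n == round(n), r1 == round(r1), r == round(r)
  )
  if (!(p0 > 0 && p1 > p0 && p1 < 1)) {
    stop("hypotheses must satisfy 0 < p0 < p1 < 1", call. = FALSE)
  }
  if (!(r1 >= 0 && r1 <= n1 && n1 <= n && r1 <= r && r <= n)) {
    stop("boundaries must satisfy 0 <= r1 <= n1 <= n and r1 <= r <= n",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha <= 1 && beta > 0 && beta <= 1)) {
    stop("alpha and beta must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(n1 = as.integer(n1), r1 = as.integer(r1),
         n = as.integer(n), r = as.integer(r),
         p0 = p0, p1 = p1, alpha = alpha, beta = beta),
    class = "simon_design"
  )
}

#' @export
print.simon_design <- function(x, ...) {
  cat("Simon two-stage design\n")
  cat(sprintf("  H0: p <= %.3g vs H1: p >= %.3g (alpha = %.3g, power >= %.3g)\n",
              x$p0, x$p1, x$alpha, 1 - x$beta))
  cat(sprintf("  Stage 1: stop for futility if <= %d responders of %d\n",
              x$r1, x$n1))
  cat(sprintf("  Final:   reject H0 if >= %d responders of %d\n",
              x$r + 1L, x$n))
  invisible(x)
}

#' Exact probability of rejecting the null under a Simon design
#'
#' Computed by full enumeration of the joint binomial distribution of stage-1
#' and stage-2 responders; no normal approximation is used. The trial rejects
#' when stage 1 passes the binding futility boundary (`X1 > r1`) and the
#' final responder total exceeds the fail boundary (`X1 + X2 >= r + 1`).
#'
#' @param design A [simon_design()] object.
#' @param p True response probability (vectorized).
#' @return Rejection probability, same length as `p`.
#' @export
simon_reject_prob <- function(design, p) {
  stopifnot(inherits(design, "simon_design"), all(p >= 0 & p <= 1))
  n1 <- design$n1; r1 <- design$r1; n2 <- design$n - design$n1; r <- design$r
  vapply(p, function(pp) {
    if (r1 >= n1) return(0)  # stage 1 can never pass
    x1 <- (r1 + 1L):n1
    # P(X2 >= r + 1 - x1); automatically 1 when x1 > r
    sum(dbinom(x1, n1, pp) * pbinom(r - x1, n2, pp, lower.tail = FALSE))
  }, numeric(1))
}

#' Probability of early termination (stage-1 futility stop)
#'
#' @inheritParams simon_reject_prob
#' @return `P(X1 <= r1)` with `X1 ~ Binomial(n1, p)`, vectorized over `p`.
#' @export
simon_pet <- function(design, p) {
  stopifnot(inherits(design, "simon_design"), all(p >= 0 & p <= 1))
  pbinom(design$r1, design$n1, p)
}

#' Expected sample size of a Simon design
#'
#' @inheritParams simon_reject_prob
#' @return `n1 + (1 - PET(p)) * (n - n1)`, vectorized over `p`.
#' @export
simon_expected_n <- function(design, p) {
  design$n1 + (1 - simon_pet(design, p)) * (design$n - design$n1)
}

#' Operating characteristics of a Simon design
#'
#' @param design A [simon_design()] object.
#' @return An object of class `simon_oc`: exact one-sided type I error at
#'   `p0`, power at `p1`, probability of early termination under `p0`, and
#'   expected sample size under `p0`.
#' @export
simon_oc <- function(design) {
  structure(
    list(type1_error = simon_reject_prob(design, design$p0),
         power = simon_reject_prob(design, design$p1),
         pet_p0 = simon_pet(design, design$p0),
         expected_n_p0 = simon_expected_n(design, design$p0),
         design = design),
    class = "simon_oc"
  )
}

#' @export
print.simon_oc <- function(x, ...) {
  print(x$design)
  cat(sprintf("  Type I error at p0: %.4f\n", x$type1_error))
  cat(sprintf("  Power at p1:        %.4f\n", x$power))
  cat(sprintf("  PET(p0):            %.4f\n", x$pet_p0))
  cat(sprintf("  E[N | p0]:          %.2f\n", x$expected_n_p0))
  invisible(x)
}

#' Stage-1 futility decision
#'
#' @param responders Observed number of stage-1 responders.
#' @param design A [simon_design()] object.
#' @return `"stop_futility"` if `responders <= r1`, else `"continue"`.
#' @export
simon_stage1_decision <- function(responders, design) {
  stopifnot(inherits(design, "simon_design"),
            length(responders) == 1L, responders == round(responders))
  if (responders < 0 || responders > design$n1) {
    stop("responders must lie in [0, n1]", call. = FALSE)
  }
  if (responders <= design$r1) "stop_futility" else "continue"
}

# Rejection probabilities for all r1 in 0:(n1 - 1) and all r in 0:(n - 1),
# for one (n1, n, p): matrix M[r1 + 1, r + 1]. Used by the design search.
# (r1 = n1 means stage 1 can never pass and is excluded.)
.simon_reject_grid <- function(n1, n, p) {
  n2 <- n - n1
  x1 <- 0:n1
  r <- 0:(n - 1)
  # A[x1 + 1, r + 1] = P(X1 = x1) * P(X2 >= r + 1 - x1)
  A <- outer(x1, r, function(a, b) {
    dbinom(a, n1, p) * pbinom(b - a, n2, p, lower.tail = FALSE)
  })
  # reject(r1, r) = sum over x1 >= r1 + 1 of A[x1, r]
  revcs <- apply(A, 2, function(col) rev(cumsum(rev(col))))
  revcs[2:(n1 + 1), , drop = FALSE]
}

#' Exhaustive search for Simon two-stage designs
#'
#' Searches all boundary configurations `(n1, r1, n, r)` with `n <= n_max`
#' whose exact type I error is at most `alpha` and exact power at least
#' `1 - beta`. The `"minimax"` criterion returns the feasible design with the
#' smallest total `n` (ties broken by smallest expected sample size under
#' `p0`); `"optimal"` minimizes the expected sample size under `p0`.
#' `n1` and/or `n` may be fixed to reproduce an operationally constrained
#' design.
#'
#' @param p0,p1 Null and alternative response probabilities.
#' @param alpha One-sided type I error bound.
#' @param beta Type II error bound.
#' @param n_max Largest total sample size considered.
#' @param criterion `"minimax"` or `"optimal"`.
#' @param n1_fixed,n_fixed Optional fixed stage-1 / total sample sizes.
#' @return The selected [simon_design()] (with an `oc` attribute), or an
#'   object of class `simon_infeasible` if no design satisfies the
#'   constraints within `n_max`.
#' @export
simon_search <- function(p0, p1, alpha = 0.05, beta = 0.20, n_max = 100,
                         criterion = c("minimax", "optimal"),
                         n1_fixed = NULL, n_fixed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(p0 > 0, p1 > p0, p1 < 1, n_max >= 2)
  ns <- if (is.null(n_fixed)) 2:n_max else n_fixed
  best <- NULL
  for (n in ns) {
    n1s <- if (is.null(n1_fixed)) 1:(n - 1) else n1_fixed
    n1s <- n1s[n1s >= 1 & n1s < n]
    for (n1 in n1s) {
      M0 <- .simon_reject_grid(n1, n, p0)
      M1 <- .simon_reject_grid(n1, n, p1)
      ok <- which(M0 <= alpha & M1 >= 1 - beta, arr.ind = TRUE)
      if (nrow(ok) == 0L) next
      r1s <- ok[, 1] - 1L
      rs <- ok[, 2] - 1L
      valid <- rs >= r1s
      if (!any(valid)) next
      r1s <- r1s[valid]; rs <- rs[valid]
      en <- n1 + (1 - pbinom(r1s, n1, p0)) * (n - n1)
      i <- which.min(en)
      cand <- list(n1 = n1, r1 = r1s[i], n = n, r = rs[i], en = en[i])
      if (is.null(best) || cand$en < best$en) best <- cand
    }
    if (criterion == "minimax" && !is.null(best)) break
  }
  if (is.null(best)) {
    return(structure(
      list(feasible = FALSE, p0 = p0, p1 = p1, alpha = alpha, beta = beta,
           n_max = n_max),
      class = "simon_infeasible"
    ))
  }
  d <- simon_design(best$n1, best$r1, best$n, best$r,
                    p0 = p0, p1 = p1, alpha = alpha, beta = beta)
  attr(d, "oc") <- simon_oc(d)
  d
}

#' @export
print.simon_infeasible <- function(x, ...) {
  cat(sprintf(
    "No feasible Simon two-stage design with n <= %d for p0 = %.3g, p1 = %.3g, alpha = %.3g, beta = %.3g\n",
    x$n_max, x$p0, x$p1, x$alpha, x$beta))
  invisible(x)
}

#' Monte Carlo simulation of a Simon two-stage trial
#'
#' Simulates complete trials under the design's decision rule; useful as an
#' independent cross-check of the exact enumeration.
#'
#' @param design A [simon_design()] object.
#' @param p True response probability.
#' @param n_sim Number of simulated trials.
#' @return A list with the simulated rejection probability (`reject`),
#'   early-termination probability (`pet`) and Monte Carlo standard errors.
#' @export
simon_simulate <- function(design, p, n_sim = 1e6) {
  x1 <- rbinom(n_sim, design$n1, p)
  go <- x1 > design$r1
  x2 <- integer(n_sim)
  x2[go] <- rbinom(sum(go), design$n - design$n1, p)
  rej <- go & (x1 + x2 >= design$r + 1L)
  list(
    reject = mean(rej),
    reject_se = sd(rej) / sqrt(n_sim),
    pet = mean(!go),
    pet_se = sd(!go) / sqrt(n_sim)
  )
}
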