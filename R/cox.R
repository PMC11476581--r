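#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the Efron-tie-corrected partial
#' likelihood, written from the likelihood up. Convergence is declared when
#' the score gradient magnitude falls below 1e-9 or the Newton step below
#' 1e-10, within 50 iterations. A diverging coefficient (monotone
#' likelihood / perfect separation) is reported through the `converged`
#' flag and a diagnostic message, never as a silent number.
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators (>= 1 event required).
#' @param x Numeric covariate with positive variance.
#' @return An object of class `cox_fit` with elements `beta`, `se`, `z`,
#'   `p_value`, `loglik` (log partial likelihood at `beta`), `gradient`,
#'   `n`, `n_events`, `converged`, `iterations`, `diagnostic`.
#' @examples
#' set.seed(1)
#' x <- rnorm(80)
#' tm <- rexp(80, rate = 0.2 * exp(0.5 * x))
#' fit <- fit_cox_univariate(pmin(tm, 8), as.numeric(tm <= 8), x)
#' coef(fit)
#' @export
fit_cox_univariate <- function(time, event, x) {
  prep <- cox_prep(time, event)
  fit <- cox_newton(prep, x)
  class(fit) <- "cox_fit"
  fit
}

#' Precompute risk-set structure for repeated univariate Cox fits
#'
#' Sorting and tie grouping depend only on `(time, event)`; when many genes
#' are fitted against the same follow-up (as in prognostic scoring) this
#' structure is built once and reused via [cox_newton()].
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @return A list of class `cox_prep`.
#' @export
cox_prep <- function(time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(event)) stop("time and event must align")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1) stop("need >= 1 event")
  ord <- order(time, decreasing = TRUE)   # risk set at t = all with time >= t
  ts <- time[ord]; es <- event[ord]
  death_times <- unique(ts[es == 1])      # decreasing
  groups <- lapply(death_times, function(dt) {
    list(risk_end = max(which(ts >= dt)),       # cumsum index of the risk set
         tied = which(ts == dt & es == 1))      # indices (sorted scale) of tied deaths
  })
  structure(list(ord = ord, time_sorted = ts, event_sorted = es,
                 groups = groups, n = length(time), n_events = sum(event)),
            class = "cox_prep")
}

# Efron log partial likelihood, gradient and information at beta for a
# covariate already permuted to the sorted (decreasing-time) order.
.cox_efron_quants <- function(prep, xs, beta) {
  eta <- beta * xs
  eta <- eta - max(eta)                 # guard overflow; cancels in ratios
  w <- exp(eta)
  cw <- cumsum(w); cxw <- cumsum(xs * w); cx2w <- cumsum(xs^2 * w)
  ll <- 0; grad <- 0; info <- 0
  for (g in prep$groups) {
    i <- g$risk_end; tied <- g$tied; d <- length(tied)
    R0 <- cw[i]; R1 <- cxw[i]; R2 <- cx2w[i]
    T0 <- sum(w[tied]); T1 <- sum(xs[tied] * w[tied]); T2 <- sum(xs[tied]^2 * w[tied])
    frac <- (seq_len(d) - 1) / d
    D0 <- R0 - frac * T0; D1 <- R1 - frac * T1; D2 <- R2 - frac * T2
    # shifted eta cancels: sum(eta[tied]) - sum(log D0) is shift-invariant
    ll <- ll + sum(eta[tied]) - sum(log(D0))
    grad <- grad + sum(xs[tied]) - sum(D1 / D0)
    info <- info + sum(D2 / D0 - (D1 / D0)^2)
  }
  list(loglik = ll, gradient = grad, information = info)
}

#' Newton-Raphson Cox fit against a prepared risk-set structure
#'
#' @param prep A [cox_prep()] object.
#' @param x Covariate vector in the original sample order.
#' @return A list with the same elements as [fit_cox_univariate()].
#' @export
cox_newton <- function(prep, x) {
  x <- as.numeric(x)
  if (length(x) != prep$n) stop("covariate length mismatch")
  if (any(!is.finite(x))) stop("covariate must be finite")
  if (stats::sd(x) == 0) stop("zero-variance covariate")
  xs <- x[prep$ord]
  beta <- 0; converged <- FALSE; diag_msg <- NA_character_
  q <- .cox_efron_quants(prep, xs, beta)
  iter <- 0L
  for (iter in seq_len(50L)) {
    if (abs(q$gradient) < 1e-9) { converged <- TRUE; break }
    if (q$information <= 0) { diag_msg <- "non-positive information"; break }
    step <- q$gradient / q$information
    # step-halving if the likelihood does not improve
    for (h in 0:5) {
      cand <- beta + step / 2^h
      qc <- .cox_efron_quants(prep, xs, cand)
      if (is.finite(qc$loglik) && qc$loglik >= q$loglik - 1e-12) break
    }
    if (abs(cand - beta) < 1e-10) { beta <- cand; q <- qc; converged <- TRUE; break }
    beta <- cand; q <- qc
    if (abs(beta) > 20) {
      diag_msg <- "monotone partial likelihood (coefficient diverging): possible perfect separation"
      break
    }
  }
  if (!converged && abs(q$gradient) < 1e-9) converged <- TRUE
  if (!converged && is.na(diag_msg)) diag_msg <- "maximum iterations reached"
  se <- if (q$information > 0) 1 / sqrt(q$information) else NA_real_
  z <- if (is.finite(se) && se > 0) beta / se else NA_real_
  p <- if (is.finite(z)) max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin) else NA_real_
  list(beta = beta, se = se, z = z, p_value = p, loglik = q$loglik,
       gradient = q$gradient, n = prep$n, n_events = prep$n_events,
       converged = converged, iterations = iter, diagnostic = diag_msg)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Univariate Cox proportional-hazards fit (Efron ties)\n")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  beta = %.4f (se %.4f), HR = %.3f, z = %.3f, p = %.3g\n",
              x$beta, x$se, exp(x$beta), x$z, x$p_value))
  if (!x$converged) cat("  NOT converged: ", x$diagnostic, "\n")
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) c(beta = object$beta)

#' @export
summary.cox_fit <- function(object, ...) {
  out <- data.frame(beta = object$beta, se = object$se, z = object$z,
                    p_value = object$p_value, n = object$n,
                    n_events = object$n_events, converged = object$converged)
  class(out) <- c("summary.cox_fit", "data.frame")
  out
}
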