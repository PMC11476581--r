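#' Kaplan-Meier product-limit estimator
#'
#' Ties at a time are handled jointly; subjects censored at an event time
#' are counted at risk for that time's factor (the usual right-continuous
#' convention).
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @return An object of class `km_fit` with `time` (distinct times),
#'   `n_risk`, `n_event`, `n_censor` and `surv` (the step-function values
#'   after each time). `S(0) = 1` and `surv` is non-increasing in [0, 1].
#' @export
kaplan_meier <- function(time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) < 1) stop("need >= 1 subject")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 n_censor = n_censor, surv = surv, n = length(time)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d, %d distinct times\n",
              x$n, sum(x$n_event), length(x$time)))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ..., xlab = "Time (years)", ylab = "Survival probability") {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv[-length(x$surv)], each = 2), x$surv[length(x$surv)])
  graphics::plot(tt, ss[seq_along(tt)], type = "l", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Survival probability at given times
#' @param object A `km_fit`.
#' @param times Numeric times at which to evaluate the step function.
#' @param ... Unused.
#' @return Numeric survival probabilities.
#' @export
predict.km_fit <- function(object, times, ...) {
  vapply(times, function(t) {
    i <- findInterval(t, object$time)
    if (i == 0) 1 else object$surv[i]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over distinct event times; p-value from the chi-square
#' distribution with 1 df. Invariant to swapping group labels.
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators (>= 1 event overall).
#' @param group Two-level group labels.
#' @return List with `chi2`, `p_value`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time); event <- as.numeric(event)
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 1)) stop("both groups need >= 1 subject")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1) stop("need >= 1 event overall")
  g1 <- g == levels(g)[1]
  dt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p_value = p,
       observed = c(O, sum(event) - O), expected = c(E, sum(event) - E))
}

#' Administrative censoring at a follow-up horizon
#'
#' Subjects with follow-up beyond `horizon` are censored at the horizon;
#' events at exactly the horizon remain events. Used to refit survival
#' models over a grid of cutoff times instead of relying on a single one.
#'
#' @param time Follow-up times (years).
#' @param event 0/1 event indicators.
#' @param horizon Positive horizon in years; `Inf` is the identity.
#' @return List with truncated `time` and `event`.
#' @export
truncate_followup <- function(time, event, horizon) {
  if (length(horizon) != 1 || horizon <= 0) stop("horizon must be a positive scalar")
  over <- time > horizon
  list(time = pmin(time, horizon), event = ifelse(over, 0, event))
}
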