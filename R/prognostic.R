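#' Multi-endpoint, multi-horizon prognostic score for one gene
#'
#' For every combination of survival endpoint and administrative-censoring
#' horizon, follow-up is truncated at the horizon and a univariate Cox model
#' is fitted on the z-scored continuous expression (or a median-dichotomized
#' covariate in sensitivity mode). Each fit contributes -1 when beta > 0
#' with p < alpha (risky), +1 when beta < 0 with p < alpha (protective) and
#' 0 otherwise; the prognostic score is the sum, so its magnitude is bounded
#' by endpoints x horizons and strongly negative scores mark consistently
#' risky genes. An endpoint with fewer than 20 usable samples or fewer than
#' 5 events (before or after truncation) is skipped and contributes 0,
#' flagged in the audit records. A gene is "risky in the cohort" when
#' score <= `risky_threshold`.
#'
#' @param expr_g Named numeric vector of one gene's expression (names =
#'   sample ids).
#' @param clinical A [clinical_table()] (a single cohort).
#' @param endpoints Endpoints to use (default all endpoints of `clinical`).
#' @param horizons Horizons in years (`Inf` = no truncation).
#' @param alpha Per-fit significance gate.
#' @param risky_threshold Score at or below which the gene is flagged risky.
#' @param dichotomize Use expression > median as the covariate instead of
#'   the z-scored continuous value.
#' @return List with `score` (NA when every fit was skipped), `available`,
#'   `risky`, `n_fits` and `records` (per-fit audit data.frame with
#'   endpoint, horizon, n, n_events, beta, se, p_value, contribution,
#'   status).
#' @export
prognostic_score_gene <- function(expr_g, clinical,
                                  endpoints = NULL,
                                  horizons = c(1, 3, 5, 10, Inf),
                                  alpha = 0.05, risky_threshold = -12,
                                  dichotomize = FALSE) {
  if (is.null(endpoints)) endpoints <- attr(clinical, "endpoints")
  if (is.null(names(expr_g))) stop("expr_g must be named by sample id")
  recs <- list()
  for (ep in endpoints) {
    fu <- endpoint_followup(clinical, ep)
    shared <- intersect(names(expr_g), fu$sample_id)
    idx <- match(shared, fu$sample_id)
    tm <- fu$time[idx]; ev <- fu$event[idx]; xg <- expr_g[shared]
    for (h in horizons) {
      rec <- .prognostic_fit_one(tm, ev, xg, h, alpha, dichotomize)
      rec$endpoint <- ep; rec$horizon <- h
      recs[[length(recs) + 1L]] <- rec
    }
  }
  records <- do.call(rbind, lapply(recs, as.data.frame))
  records <- records[, c("endpoint", "horizon", "n", "n_events", "beta",
                         "se", "p_value", "contribution", "status")]
  available <- any(records$status == "fit")
  score <- if (available) sum(records$contribution) else NA_integer_
  list(score = score, available = available,
       risky = available && score <= risky_threshold,
       n_fits = sum(records$status == "fit"), records = records)
}

.prognostic_fit_one <- function(tm, ev, xg, h, alpha, dichotomize,
                                prep = NULL) {
  blank <- list(n = length(tm), n_events = NA_real_, beta = NA_real_,
                se = NA_real_, p_value = NA_real_, contribution = 0L,
                status = "skipped")
  if (length(tm) < 20) return(blank)
  if (is.null(prep)) {
    tr <- truncate_followup(tm, ev, h)
    if (sum(tr$event) < 5) { blank$n_events <- sum(tr$event); return(blank) }
    prep <- cox_prep(tr$time, tr$event)
  }
  x <- if (dichotomize) as.numeric(xg > stats::median(xg)) else xg
  if (stats::sd(x) == 0) { blank$n_events <- prep$n_events; return(blank) }
  x <- (x - mean(x)) / stats::sd(x)
  fit <- tryCatch(cox_newton(prep, x), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    blank$n_events <- prep$n_events
    blank$status <- if (is.null(fit)) "skipped" else "not_converged"
    return(blank)
  }
  contrib <- 0L
  if (fit$p_value < alpha) contrib <- if (fit$beta > 0) -1L else 1L
  list(n = fit$n, n_events = fit$n_events, beta = fit$beta, se = fit$se,
       p_value = fit$p_value, contribution = contrib, status = "fit")
}

#' Prognostic scores for many genes across cohorts
#'
#' Runs [prognostic_score_gene()] for every gene in every cohort, reusing
#' the sorted risk-set structure per (cohort, endpoint, horizon) so the cost
#' per additional gene is a single Newton solve. Produces the table driving
#' the "risky in more than k tumor types" pan-cohort criterion (strict >).
#'
#' @param expr An [expression_matrix()] covering all cohorts' samples.
#' @param clinical A [clinical_table()] with a `cohort` column.
#' @param genes Genes to score (default all rows of `expr`).
#' @param cohorts Cohorts to score (default all in `clinical`).
#' @inheritParams prognostic_score_gene
#' @param audit Keep the full per-fit audit trail (may be large).
#' @return An object of class `prognostic_table`: list with `scores` (gene x
#'   cohort integer matrix, NA = unavailable), `risky` (logical matrix),
#'   `n_cohorts_risky` (named vector), `table` (long data.frame), `audit`
#'   (per-fit records or NULL) and `params`.
#' @export
batch_prognostic_scores <- function(expr, clinical, genes = rownames(expr),
                                    cohorts = unique(clinical$cohort),
                                    endpoints = NULL,
                                    horizons = c(1, 3, 5, 10, Inf),
                                    alpha = 0.05, risky_threshold = -12,
                                    dichotomize = FALSE, audit = TRUE) {
  if (is.null(endpoints)) endpoints <- attr(clinical, "endpoints")
  genes <- intersect(genes, rownames(expr))
  scores <- matrix(NA_integer_, length(genes), length(cohorts),
                   dimnames = list(genes, cohorts))
  audit_rows <- list()
  for (co in cohorts) {
    co_samples <- clinical$sample_id[clinical$cohort == co]
    co_samples <- intersect(co_samples, colnames(expr))
    sub <- clinical[match(co_samples, clinical$sample_id), , drop = FALSE]
    attr(sub, "endpoints") <- attr(clinical, "endpoints")
    class(sub) <- class(clinical)
    contrib <- matrix(0L, length(genes), 0)
    any_fit <- rep(FALSE, length(genes))
    total <- integer(length(genes))
    for (ep in endpoints) {
      fu <- endpoint_followup(sub, ep)
      shared <- fu$sample_id
      ok_ep <- length(shared) >= 20 && sum(fu$event) >= 5
      X <- unclass(expr)[genes, shared, drop = FALSE]
      for (h in horizons) {
        prep <- NULL
        if (ok_ep) {
          tr <- truncate_followup(fu$time, fu$event, h)
          if (sum(tr$event) >= 5) prep <- cox_prep(tr$time, tr$event)
        }
        for (gi in seq_along(genes)) {
          rec <- .prognostic_fit_one(fu$time, fu$event, X[gi, ], h, alpha,
                                     dichotomize, prep = prep)
          total[gi] <- total[gi] + rec$contribution
          if (rec$status == "fit") any_fit[gi] <- TRUE
          if (audit)
            audit_rows[[length(audit_rows) + 1L]] <-
              data.frame(gene = genes[gi], cohort = co, endpoint = ep,
                         horizon = h, n = rec$n, n_events = rec$n_events,
                         beta = rec$beta, p_value = rec$p_value,
                         contribution = rec$contribution, status = rec$status,
                         stringsAsFactors = FALSE)
        }
      }
    }
    scores[, co] <- ifelse(any_fit, total, NA_integer_)
  }
  risky <- !is.na(scores) & scores <= risky_threshold
  n_risky <- rowSums(risky)
  tab <- data.frame(gene = rep(genes, times = length(cohorts)),
                    cohort = rep(cohorts, each = length(genes)),
                    score = as.vector(scores), risky = as.vector(risky),
                    stringsAsFactors = FALSE)
  structure(list(scores = scores, risky = risky, n_cohorts_risky = n_risky,
                 table = tab,
                 audit = if (audit) do.call(rbind, audit_rows) else NULL,
                 params = list(endpoints = endpoints, horizons = horizons,
                               alpha = alpha, risky_threshold = risky_threshold,
                               dichotomize = dichotomize)),
            class = "prognostic_table")
}

#' @export
print.prognostic_table <- function(x, ...) {
  cat(sprintf("<prognostic_table> %d genes x %d cohorts (grid: %d endpoints x %d horizons)\n",
              nrow(x$scores), ncol(x$scores),
              length(x$params$endpoints), length(x$params$horizons)))
  cat(sprintf("  risky threshold %s; %d gene(s) risky in >= 1 cohort\n",
              x$params$risky_threshold, sum(x$n_cohorts_risky > 0)))
  invisible(x)
}

#' @export
summary.prognostic_table <- function(object, ...) {
  data.frame(gene = rownames(object$scores),
             min_score = apply(object$scores, 1, min, na.rm = TRUE),
             n_cohorts_risky = object$n_cohorts_risky,
             row.names = NULL, stringsAsFactors = FALSE)
}
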