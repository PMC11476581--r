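test_that("Cox fit maximizes the Efron partial likelihood (brute-force and coxph checks)", {
  for (seed in c(2, 5, 9)) {
    d <- random_survival_data(45, seed)
    fit <- fit_cox_univariate(d$time, d$event, d$x)
    expect_true(fit$converged)
    expect_lt(abs(fit$gradient), 1e-6)
    b_brute <- cox_beta_bruteforce(d$time, d$event, d$x)
    expect_equal(fit$beta, b_brute, tolerance = 1e-3)
    cph <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x, ties = "efron")
    expect_equal(fit$beta, unname(coef(cph)), tolerance = 1e-7)
    expect_equal(fit$se, unname(sqrt(vcov(cph))[1]), tolerance = 1e-6)
  }
})

test_that("Cox fit handles heavy ties, matching coxph's Efron correction", {
  set.seed(21)
  x <- rnorm(120)
  tm <- ceiling(rexp(120, 0.3 * exp(0.6 * x)) * 2) / 2   # forced ties
  ev <- rbinom(120, 1, 0.8)
  fit <- fit_cox_univariate(tm, ev, x)
  cph <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "efron")
  expect_equal(fit$beta, unname(coef(cph)), tolerance = 1e-7)
  expect_equal(fit$p_value, summary(cph)$coefficients[1, "Pr(>|z|)"],
               tolerance = 1e-6)
})

test_that("perfect separation is flagged, never returned silently", {
  # covariate perfectly ordered with event times -> monotone likelihood
  tm <- 1:12
  ev <- rep(1, 12)
  x <- 12:1
  fit <- fit_cox_univariate(tm, ev, x)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "monotone|separation")
  expect_error(fit_cox_univariate(tm, ev, rep(1, 12)), "zero-variance")
})

test_that("Kaplan-Meier reproduces closed-form and hand-computed toys", {
  k <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
  k0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(k0$surv, rep(1, 3))
  # 6 subjects, censor at t=2 alongside an event and at t=4:
  # S = 5/6, 5/6*4/5, * 2/3, (censor), * 0
  k6 <- kaplan_meier(c(1, 2, 2, 3, 4, 5), c(1, 1, 0, 1, 0, 1))
  expect_equal(k6$surv, c(5 / 6, 2 / 3, 4 / 9, 4 / 9, 0), tolerance = 1e-12)
  expect_equal(predict(k6, c(0.5, 2.5, 10)), c(1, 2 / 3, 0))
  # S(0)=1, non-increasing, in [0,1]; agrees with survfit
  set.seed(30)
  tm <- round(rexp(60, 0.4), 1); ev <- rbinom(60, 1, 0.7)
  km <- kaplan_meier(tm, ev)
  expect_true(all(diff(km$surv) <= 1e-12))
  sf <- summary(survival::survfit(survival::Surv(tm, ev) ~ 1), times = km$time)
  expect_equal(predict(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("log-rank matches the hand-computed O/E/V toy and is label-symmetric", {
  tm <- c(1, 2, 3, 4, 2, 3, 5, 6); ev <- c(1, 1, 0, 1, 1, 1, 1, 0)
  gr <- c(0, 0, 0, 0, 1, 1, 1, 1)
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$chi2, 0.738347264668, tolerance = 1e-10)
  expect_equal(lr$observed[1], 3)
  expect_equal(lr$expected[1], 2.090476190476, tolerance = 1e-10)
  lr2 <- logrank_test(tm, ev, 1 - gr)
  expect_equal(lr2$chi2, lr$chi2, tolerance = 1e-12)
  sd_ref <- survival::survdiff(survival::Surv(tm, ev) ~ gr)
  expect_equal(lr$chi2, sd_ref$chisq, tolerance = 1e-10)
  # identical groups: no signal
  lr0 <- logrank_test(rep(tm, 2), rep(ev, 2), rep(0:1, each = 8))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank_test(tm, ev, rep(1, 8)), "two groups")
})

test_that("follow-up truncation censors beyond the horizon, keeps boundary events", {
  tr <- truncate_followup(c(8, 5, 3), c(1, 1, 0), 5)
  expect_equal(tr$time, c(5, 5, 3))
  expect_equal(tr$event, c(0, 1, 0))      # event at exactly the horizon kept
  tr2 <- truncate_followup(c(1, 2), c(1, 0), 10)
  expect_equal(tr2, list(time = c(1, 2), event = c(1, 0)))
  # never increases time, never converts censoring into an event
  set.seed(31)
  tm <- rexp(50); ev <- rbinom(50, 1, 0.5)
  tr3 <- truncate_followup(tm, ev, 0.7)
  expect_true(all(tr3$time <= tm))
  expect_true(all(tr3$event <= ev))
})

test_that("prognostic score sums its own audit records and respects the grid bound", {
  co <- simulate_bulk_cohort(sim_config(n_samples = 250, n_genes = 60,
                                        n_planted_negative = 5,
                                        n_planted_dual = 2, n_cohorts = 1,
                                        seed = 12))
  g <- co$ground_truth$planted_negative[1]
  ps <- prognostic_score_gene(unclass(co$expression)[g, ], co$clinical)
  expect_equal(ps$score, sum(ps$records$contribution))
  expect_lte(abs(ps$score), 4 * 5)
  expect_true(ps$available)
  # antisymmetry under negating the covariate: risky <-> protective
  ps_neg <- prognostic_score_gene(-unclass(co$expression)[g, ], co$clinical)
  expect_equal(ps_neg$score, -ps$score)
})

test_that("strong planted genes attain the -20 bound; unavailable endpoints skip", {
  # strong-signal configuration: per-gene hazard coefficient 1
  co <- simulate_bulk_cohort(sim_config(n_samples = 500, n_genes = 60,
                                        n_planted_negative = 5,
                                        n_planted_dual = 2, n_cohorts = 1,
                                        beta = 1, seed = 13))
  g <- co$ground_truth$planted_negative[2]
  ps <- prognostic_score_gene(unclass(co$expression)[g, ], co$clinical)
  expect_equal(ps$score, -20)
  expect_true(ps$risky)
  # too few samples: every fit skipped, score unavailable (not 0)
  tiny <- co$clinical[1:10, ]
  attr(tiny, "endpoints") <- endpoints(co$clinical)
  class(tiny) <- class(co$clinical)
  ps2 <- prognostic_score_gene(unclass(co$expression)[g, 1:10], tiny)
  expect_false(ps2$available)
  expect_true(is.na(ps2$score))
  expect_true(all(ps2$records$status == "skipped"))
})

test_that("null genes rarely reach large prognostic scores at the default grid", {
  co <- simulate_bulk_cohort(sim_config(n_samples = 300, n_genes = 40,
                                        n_planted_negative = 2,
                                        n_planted_dual = 1, n_cohorts = 1,
                                        seed = 14))
  set.seed(14)
  n <- nrow(co$clinical)
  X <- matrix(rnorm(120 * n), 120, n,
              dimnames = list(sprintf("N%03d", 1:120), co$clinical$sample_id))
  prog <- batch_prognostic_scores(expression_matrix(X, "log2_tpm"),
                                  co$clinical, audit = FALSE)
  sc <- prog$scores[, 1]
  # calibrated null behaviour: nested horizons correlate fits, so a tail
  # beyond |2| remains; the bulk stays small
  expect_gte(mean(abs(sc) <= 2), 0.85)
  expect_lt(mean(abs(sc)), 1.5)
})

test_that("batch scoring matches per-gene scoring and the strict pan-cohort rule", {
  co <- simulate_bulk_cohort(sim_config(n_samples = 150, n_genes = 50,
                                        n_planted_negative = 4,
                                        n_planted_dual = 2, n_cohorts = 2,
                                        seed = 15))
  genes <- c(co$ground_truth$planted_negative[1:2], "DCY_0001")
  prog <- batch_prognostic_scores(co$expression, co$clinical, genes = genes)
  for (g in genes) {
    c1 <- co$clinical[co$clinical$cohort == "C1", ]
    attr(c1, "endpoints") <- endpoints(co$clinical)
    class(c1) <- class(co$clinical)
    single <- prognostic_score_gene(
      unclass(co$expression)[g, c1$sample_id], c1)
    expect_equal(unname(prog$scores[g, "C1"]), single$score)
  }
  # audit consistency: every score equals the sum of its audit rows
  aud <- prog$audit
  for (g in genes) for (co_ in c("C1", "C2")) {
    expect_equal(unname(prog$scores[g, co_]),
                 sum(aud$contribution[aud$gene == g & aud$cohort == co_]))
  }
  # strict "> k cohorts" rule
  expect_identical(sum(prog$n_cohorts_risky > 2), 0L)   # only 2 cohorts exist
})
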