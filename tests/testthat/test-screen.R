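test_that("correlation filter applies the inclusive rho and strict p bounds", {
  set.seed(61)
  n <- 50
  s <- rnorm(n)
  X <- rbind(anti = -s,                       # rho = -1
             pos = s + rnorm(n, 0, 0.1),
             flat = rnorm(n))
  colnames(X) <- paste0("smp", 1:n)
  em <- toy_expr(X, genes = rownames(X), samples = colnames(X))
  scores <- setNames(s, colnames(X))
  cf <- correlation_filter(em, scores)
  expect_true("anti" %in% cf$pass)
  expect_false("pos" %in% cf$pass)
  expect_equal(cf$table$rho[cf$table$gene == "anti"], -1)
  # boundary: rho exactly at the threshold passes (inclusive)
  th <- screen_thresholds(rho_signature_max = cf$table$rho[cf$table$gene == "flat"],
                          p_max = 1)
  cf2 <- correlation_filter(em, scores, th)
  expect_true("flat" %in% cf2$pass)
  # agreement with the scalar implementation
  r_ref <- spearman_cor(X["flat", ], s)
  expect_equal(cf$table$rho[cf$table$gene == "flat"], r_ref$rho, tolerance = 1e-12)
  expect_equal(cf$table$p_value[cf$table$gene == "flat"], r_ref$p_value,
               tolerance = 1e-10)
})

test_that("expression filter boundary is inclusive and scale-checked", {
  X <- rbind(at = rep(1, 4), below = rep(0.99, 4), above = rep(3, 4))
  em <- toy_expr(X, genes = rownames(X), samples = paste0("s", 1:4))
  keep <- expression_filter(em)
  expect_setequal(keep, c("at", "above"))
  emc <- toy_expr(matrix(1:8, 2, 4), scale = "counts")
  expect_error(expression_filter(emc), "log2_tpm")
})

test_that("prognostic filter uses strict bounds on score and cohort count", {
  pt <- list(scores = matrix(c(-12L, -13L, -13L, -15L),
                             dimnames = list(c("gA", "gB", "gC", "gD"), "C1")),
             n_cohorts_risky = c(gA = 6, gB = 6, gC = 3, gD = 4))
  expect_setequal(prognostic_filter(pt, "C1"), c("gB", "gD"))
  # gA: score -12 exactly fails (strict <); gC: risky in exactly 3 fails (> 3)
})

test_that("candidate intersection is exact, sorted and order-independent", {
  s1 <- c("a", "b", "c"); s2 <- c("b", "c"); s3 <- c("c", "b", "d")
  expect_identical(intersect_candidates(list(s1, s2, s3)), c("b", "c"))
  expect_identical(intersect_candidates(list(s3, s1, s2)), c("b", "c"))
  expect_identical(intersect_candidates(list(s1, character(0))), character(0))
  expect_error(intersect_candidates(list(s1)), ">= 2")
})

test_that("TIL filter requires both cell types strictly below the cutoff", {
  rho <- rbind(both = c(-0.2, -0.3), one = c(-0.2, -0.05),
               boundary = c(-0.1, -0.4))
  colnames(rho) <- c("CD8_T", "NK_activated")
  keep <- til_filter(rownames(rho), rho)
  expect_identical(keep, "both")       # -0.1 exactly fails (strict)
  expect_error(til_filter("both", rho[, 1, drop = FALSE]), "lacks cell type")
})

test_that("dual-effector filter needs negative correlation and essential dependency", {
  cfg <- sim_config(n_samples = 100, n_genes = 120, n_planted_negative = 8,
                    n_planted_dual = 3, n_cohorts = 1, seed = 8)
  pan <- simulate_cellline_panel(cfg)
  scores <- zscore_normalize(ucell_score(pan$expression, mhc1_signature(),
                                         max_rank = 100))
  gt <- pan$ground_truth$planted_dual
  cand <- c(gt, "DCY_0001", "NOT_IN_PANEL")
  res <- suppressMessages(
    cellline_dual_effector_filter(cand, pan, scores))
  expect_setequal(res$pass, gt)
  expect_false("DCY_0001" %in% res$pass)
  # strict boundary on the dependency median
  pan2 <- pan
  pan2$dependency[gt[1], ] <- -0.5
  res2 <- suppressMessages(cellline_dual_effector_filter(gt, pan2, scores))
  expect_false(gt[1] %in% res2$pass)
})

test_that("single-cell validation excludes extreme tumor fractions", {
  sc <- simulate_single_cell(sim_config(seed = 9))
  props <- vapply(sc$samples, function(s)
    mean(s$cell_types == "Cancer_epithelial"), numeric(1))
  v <- single_cell_validation(sc, sc$ground_truth$planted_negative[1:3])
  expect_true(all(props[v$samples_used] >= 0.10 & props[v$samples_used] <= 0.90))
  excluded <- setdiff(names(sc$samples), v$samples_used)
  expect_true(all(props[excluded] < 0.10 | props[excluded] > 0.90))
})

test_that("a fully permissive cascade keeps every gene; an impossible one keeps none", {
  co <- simulate_bulk_cohort(sim_config(n_samples = 60, n_genes = 60,
                                        n_planted_negative = 4,
                                        n_planted_dual = 2, n_cohorts = 1,
                                        seed = 10))
  th_open <- screen_thresholds(rho_signature_max = 1, p_max = 1,
                               expr_min = -Inf, prognostic_max = Inf,
                               min_risky_cohorts = -1, rho_til_max = 1,
                               dependency_max = Inf, cellline_rho_max = 1)
  cfg <- run_config(thresholds = th_open, fraction_source = "supplied", seed = 10)
  res <- suppressMessages(run_full_screen(co, config = cfg))
  expect_setequal(res$candidates, rownames(co$expression))
  th_closed <- screen_thresholds(rho_signature_max = -1.1)
  cfg2 <- run_config(thresholds = th_closed, fraction_source = "supplied", seed = 10)
  res2 <- suppressMessages(run_full_screen(co, config = cfg2))
  expect_length(res2$stages$correlation, 0)
  expect_length(res2$candidates, 0)
  expect_s3_class(res2, "screen_result")
})

test_that("relaxing a threshold never shrinks a stage (monotonicity)", {
  co <- simulate_bulk_cohort(sim_config(n_samples = 150, n_genes = 100,
                                        n_planted_negative = 6,
                                        n_planted_dual = 2, n_cohorts = 2,
                                        seed = 11))
  base <- screen_thresholds()
  relaxed <- screen_thresholds(rho_signature_max = 0, p_max = 0.5,
                               expr_min = 0, prognostic_max = 0,
                               min_risky_cohorts = 0)
  cfg_b <- run_config(thresholds = base, fraction_source = "supplied", seed = 11)
  cfg_r <- run_config(thresholds = relaxed, fraction_source = "supplied", seed = 11)
  rb <- suppressMessages(run_full_screen(co, config = cfg_b))
  rr <- suppressMessages(run_full_screen(co, config = cfg_r))
  expect_true(all(rb$stages$correlation %in% rr$stages$correlation))
  expect_true(all(rb$candidates %in% rr$candidates))
  # subset chain within one run
  expect_true(all(rb$candidates %in% rb$stages$correlation))
  expect_true(all(rb$stages$til %in% rb$candidates))
  expect_true(all(rb$stages$dual_effectors %in% rb$stages$til))
})

test_that("the default synthetic screen recovers planted genes end to end", {
  co <- simulate_bulk_cohort(sim_config(n_samples = 300, n_genes = 400,
                                        n_planted_negative = 10,
                                        n_planted_dual = 3, seed = 12))
  pan <- simulate_cellline_panel(sim_config(n_samples = 300, n_genes = 400,
                                            n_planted_negative = 10,
                                            n_planted_dual = 3, seed = 12))
  res <- suppressMessages(run_full_screen(co, pan, run_config(seed = 12)))
  gt <- co$ground_truth
  recall <- mean(gt$planted_negative %in% res$candidates)
  decoy_rate <- mean(gt$decoys %in% res$candidates)
  expect_gte(recall, 0.8)
  expect_lt(decoy_rate, recall)
  expect_setequal(res$dual_effectors, gt$planted_dual)
})
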