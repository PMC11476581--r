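test_that("size factors reproduce hand-computed medians of ratios", {
  cts <- rbind(c(10, 20, 30), c(5, 10, 15), c(100, 210, 290),
               c(0, 5, 8), c(8, 16, 20))
  em <- toy_expr(cts, scale = "counts")
  sf <- median_of_ratios_size_factors(em)
  # row 4 has a zero and is excluded from the reference set
  expect_equal(unname(sf), c(0.550321208149, 1.125297849314, 1.619497173832),
               tolerance = 1e-10)
  # identical samples -> all factors 1; exact doubling -> ratio 1:2
  em1 <- toy_expr(matrix(rep(c(4, 9, 2), 3), 3, 3), scale = "counts")
  expect_equal(unname(median_of_ratios_size_factors(em1)), rep(1, 3))
  em2 <- toy_expr(cbind(c(4, 9, 2), c(8, 18, 4)), scale = "counts")
  f <- median_of_ratios_size_factors(em2)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
  em0 <- toy_expr(rbind(c(1, 0), c(0, 1)), scale = "counts")
  expect_error(median_of_ratios_size_factors(em0), "pseudo-reference")
})

test_that("differential expression flags low counts and finds planted changes", {
  set.seed(51)
  n_per <- 10
  mu <- runif(150, 20, 200)
  planted <- 1:20
  cts <- t(vapply(seq_along(mu), function(i) {
    m <- rep(mu[i], 2 * n_per)
    if (i %in% planted) m[(n_per + 1):(2 * n_per)] <- mu[i] * 4
    rpois(2 * n_per, m)
  }, numeric(2 * n_per)))
  cts <- rbind(cts, low = c(rep(0, 2 * n_per - 3), 3, 3, 3))  # total 9 < 10
  em <- toy_expr(cts, scale = "counts",
                 genes = c(sprintf("G%03d", seq_along(mu)), "LOWG"))
  de <- differential_expression(em, rep(0:1, each = n_per), min_count = 10)
  expect_true(de$filtered[de$gene == "LOWG"])
  expect_true(is.na(de$p_value[de$gene == "LOWG"]))
  hit <- de$gene %in% sprintf("G%03d", planted)
  expect_true(all(abs(de$log2fc[hit] - 2) <= 0.5))
  expect_gte(mean(de$q_value[hit] < 0.05), 0.9)
  # q >= p wherever tested
  ok <- !de$filtered
  expect_true(all(de$q_value[ok] >= de$p_value[ok] - 1e-12))
})

test_that("null differential expression makes almost no q < 0.05 calls", {
  set.seed(52)
  cts <- matrix(rpois(200 * 12, 50), 200, 12)
  em <- toy_expr(cts, scale = "counts")
  de <- differential_expression(em, rep(0:1, each = 6))
  expect_lte(sum(de$q_value < 0.05, na.rm = TRUE), 2)
})

test_that("BH matches the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(53)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("hypergeometric ORA matches full enumeration on small universes", {
  uni <- paste0("u", 1:20)
  path <- paste0("u", 1:5)
  hits <- paste0("u", c(1:4, 8:13))    # overlap 4
  r <- overrepresentation_test(hits, path, uni)
  expect_equal(r$overlap, 4)
  expect_equal(r$p_value, hyper_tail_enum(4, 5, 20, 10), tolerance = 1e-12)
  expect_equal(r$fold_enrichment, (4 / 10) / (5 / 20))
  # overlap at its minimum -> p = 1; hits = universe -> certainty
  r0 <- overrepresentation_test(paste0("u", 6:10), paste0("u", 1:3), uni)
  expect_equal(r0$p_value, 1)
  r1 <- overrepresentation_test(uni, path, uni)
  expect_equal(r1$overlap, 5)
  expect_equal(r1$p_value, 1)
  set.seed(54)
  for (i in 1:20) {
    N <- sample(8:25, 1)
    u <- paste0("g", 1:N)
    K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    pa <- sample(u, K); hi <- sample(u, n)
    k <- length(intersect(pa, hi))
    expect_equal(overrepresentation_test(hi, pa, u)$p_value,
                 hyper_tail_enum(k, K, N, n), tolerance = 1e-10)
  }
  expect_error(overrepresentation_test("a", "a", character(0)), "empty universe")
})

test_that("preranked GSEA reproduces the hand-computed 5-gene walk", {
  rk <- c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1)
  gs <- gene_set_collection(list(s = c("g1", "g3")))
  res <- preranked_gsea(rk, gs, n_perm = 50, seed = 1)
  # hand walk: 0.625, 0.29167, 0.66667, 0.33333, 0 -> extreme = 2/3 at g3
  expect_equal(res$es, 2 / 3, tolerance = 1e-12)
  expect_identical(res$leading_edge, "g1,g3")
  expect_gte(res$p_value, 1 / 51)
})

test_that("GSEA: top-k concentration, antisymmetry, reproducibility, fgsea cross-check", {
  set.seed(55)
  rk <- setNames(sort(rnorm(1000), decreasing = TRUE), paste0("g", 1:1000))
  gs <- gene_set_collection(list(top = names(rk)[1:10]))
  res0 <- preranked_gsea(rk, gs, n_perm = 50, weight = 0, seed = 2)
  expect_gt(res0$es, 0.9)
  # antisymmetry under negation of the statistic (no ties here)
  rk2 <- setNames(rnorm(200), paste0("h", 1:200))
  gsr <- gene_set_collection(list(s = sample(names(rk2), 15)))
  e_pos <- preranked_gsea(rk2, gsr, n_perm = 10, seed = 3)$es
  e_neg <- preranked_gsea(-rk2, gsr, n_perm = 10, seed = 3)$es
  expect_equal(e_pos, -e_neg, tolerance = 1e-12)
  # fixed seed -> bit-identical results
  a <- preranked_gsea(rk2, gsr, n_perm = 100, seed = 9)
  b <- preranked_gsea(rk2, gsr, n_perm = 100, seed = 9)
  expect_identical(a, b)
  # ES agrees with fgsea's score for the same weighting
  skip_if_not_installed("fgsea")
  fg <- suppressWarnings(fgsea::fgseaSimple(list(s = gsr$s), rk2, nperm = 100,
                                            gseaParam = 1))
  expect_equal(a$es, fg$ES, tolerance = 1e-6)
})

test_that("GSEA rejects degenerate sets and missing stats", {
  rk <- c(a = 3, b = 2, c = 1)
  expect_error(preranked_gsea(rk, gene_set_collection(list(s = c("a", "b", "c")))),
               "whole gene universe|whole universe")
  expect_error(preranked_gsea(c(a = 1, b = NA),
                              gene_set_collection(list(s = "a"))),
               "missing")
})
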