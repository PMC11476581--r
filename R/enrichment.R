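#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each gene positive in every
#' sample, the ratio of its count to its cross-sample geometric mean is
#' formed, and the sample's factor is the median of those ratios.
#'
#' @param counts An [expression_matrix()] on the counts scale.
#' @return Named positive numeric vector of per-sample factors.
#' @export
median_of_ratios_size_factors <- function(counts) {
  if (expr_scale(counts) != "counts") stop("size factors require the counts scale")
  X <- unclass(counts)
  all_pos <- rowSums(X > 0) == ncol(X)
  if (!any(all_pos))
    stop("no gene is positive in all samples; consider a pseudo-reference fallback")
  logX <- log(X[all_pos, , drop = FALSE])
  log_geo <- rowMeans(logX)
  factors <- apply(exp(logX - log_geo), 2, stats::median)
  stats::setNames(factors, colnames(X))
}

#' Two-group differential expression (Welch t on log normalized counts)
#'
#' A lightweight differential-expression test used to drive downstream
#' ranking: genes with total count below `min_count` are flagged filtered
#' and not tested; the rest are normalized by median-of-ratios size
#' factors, transformed to log2(normalized + 1), compared by Welch's
#' t-test, and corrected by Benjamini-Hochberg across tested genes. The
#' log2 fold change is the difference of group means on the transformed
#' scale (group 1 minus group 0).
#'
#' @param counts An [expression_matrix()] on the counts scale.
#' @param group Binary group labels (0/1, logical, or two-level factor);
#'   both groups need >= 2 samples.
#' @param min_count Minimum total count for a gene to be tested.
#' @return A data.frame with per-gene `log2fc`, `p_value`, `q_value`,
#'   `mean_0`, `mean_1`, `filtered`.
#' @export
differential_expression <- function(counts, group, min_count = 10) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("group must be binary")
  if (any(table(g) < 2)) stop("both groups need >= 2 samples")
  X <- unclass(counts)
  sf <- median_of_ratios_size_factors(counts)
  N <- log2(sweep(X, 2, sf, "/") + 1)
  filtered <- rowSums(X) < min_count
  i0 <- g == levels(g)[1]; i1 <- !i0
  m0 <- rowMeans(N[, i0, drop = FALSE]); m1 <- rowMeans(N[, i1, drop = FALSE])
  v0 <- apply(N[, i0, drop = FALSE], 1, stats::var)
  v1 <- apply(N[, i1, drop = FALSE], 1, stats::var)
  n0 <- sum(i0); n1 <- sum(i1)
  sedm <- sqrt(v0 / n0 + v1 / n1)
  tstat <- (m1 - m0) / sedm
  df <- (v0 / n0 + v1 / n1)^2 /
    ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[sedm == 0 & m1 == m0] <- 1          # identical constant groups: no evidence
  p <- pmax(p, .Machine$double.xmin)    # keep p in (0, 1] for BH
  p[filtered] <- NA
  q <- rep(NA_real_, length(p))
  tested <- !filtered & !is.na(p)
  if (any(tested)) q[tested] <- bh_fdr(p[tested])
  data.frame(gene = rownames(X), log2fc = m1 - m0, p_value = p, q_value = q,
             mean_0 = m0, mean_1 = m1, filtered = filtered,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_i = min over j >= i of p_(j) * m / j` on the sorted p-values, mapped
#' back to the input order. Guarantees `q >= p` elementwise and
#' monotonicity in the sorted order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values aligned with `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the realized overlap
#' between a hit list and a pathway within a finite gene universe. BH
#' correction across pathways is the caller's responsibility (see
#' [ora_collection()]).
#'
#' @param hits Character vector of hit genes (restricted to the universe;
#'   hits outside it are dropped with a warning).
#' @param pathway Character vector of pathway genes.
#' @param universe Character vector: the gene universe (non-empty).
#' @return List with `p_value`, `overlap`, `fold_enrichment`, `n_hits`,
#'   `n_pathway`, `n_universe`.
#' @export
overrepresentation_test <- function(hits, pathway, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits)
  outside <- setdiff(hits, universe)
  if (length(outside) > 0) {
    warning("dropping ", length(outside), " hit(s) outside the universe")
    hits <- intersect(hits, universe)
  }
  pathway <- intersect(unique(pathway), universe)
  if (length(pathway) == 0) stop("pathway has no genes in the universe")
  N <- length(universe); K <- length(pathway); n <- length(hits)
  k <- length(intersect(hits, pathway))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  list(p_value = p, overlap = k, fold_enrichment = fold,
       n_hits = n, n_pathway = K, n_universe = N)
}

#' Over-representation analysis across a gene-set collection
#'
#' Applies [overrepresentation_test()] to every set and adjusts p-values by
#' [bh_fdr()].
#'
#' @param hits Character vector of hit genes.
#' @param sets A [gene_set_collection()].
#' @param universe Character vector: the gene universe.
#' @return Data.frame with one row per pathway: overlap, fold enrichment,
#'   p and BH q, sorted by p.
#' @export
ora_collection <- function(hits, sets, universe) {
  res <- lapply(names(sets), function(nm) {
    r <- overrepresentation_test(hits, sets[[nm]], universe)
    data.frame(pathway = nm, overlap = r$overlap,
               fold_enrichment = r$fold_enrichment, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out[order(out$p_value), ]
}
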