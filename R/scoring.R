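#' GSVA-style single-sample gene-set scores
#'
#' Per-sample enrichment scores computed in four steps: (1) a per-gene
#' cross-sample statistic — under `kcdf = "gaussian"` the average Gaussian
#' kernel CDF with bandwidth sd/4 (genes with zero variance fall back to
#' ranks with a warning), under `kcdf = "rank"` plain cross-sample ranks;
#' (2) within each sample genes are ordered by decreasing statistic;
#' (3) a weighted Kolmogorov-Smirnov random walk over that ordering, hit
#' increments proportional to |statistic|^tau, miss increments uniform;
#' (4) the enrichment score is v+ - v-, the difference of the maximum
#' positive and maximum negative walk deviations (each floored at 0),
#' hence in (-1, 1).
#'
#' Sets with no genes in the matrix are skipped with a warning.
#'
#' @param expr An [expression_matrix()] with >= 2 samples.
#' @param sets A [gene_set_collection()] (or a character vector, treated as
#'   one set named "set").
#' @param kcdf `"gaussian"` for continuous (log2-TPM-like) values, `"rank"`
#'   for counts.
#' @param tau Weighting exponent of the random walk.
#' @return A `signature_scores` object for a single set, or a named list of
#'   them for a collection: numeric per-sample scores with attributes
#'   `method`, `gene_set`, `normalized`.
#' @export
gsva_score <- function(expr, sets, kcdf = c("gaussian", "rank"), tau = 1) {
  kcdf <- match.arg(kcdf)
  if (ncol(expr) < 2) stop("GSVA scoring needs >= 2 samples")
  single <- FALSE
  if (is.character(sets)) {
    sets <- gene_set_collection(list(set = sets))
    single <- TRUE
  }
  genes <- rownames(expr)
  keep <- vapply(sets, function(s) any(s %in% genes), logical(1))
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " set(s) with no genes in the matrix: ",
            paste(names(sets)[!keep], collapse = ", "))
    sets <- sets[keep]
  }
  if (length(sets) == 0) stop("no scorable gene sets")
  Z <- .kcdf_statistic(unclass(expr), kcdf)
  # one decreasing ordering per sample, shared across sets
  ord <- apply(Z, 2, order, decreasing = TRUE)
  out <- lapply(names(sets), function(nm) {
    hit <- genes %in% sets[[nm]]
    es <- vapply(seq_len(ncol(Z)), function(j) {
      .ks_walk_es(Z[ord[, j], j], hit[ord[, j]], tau)
    }, numeric(1))
    signature_scores(stats::setNames(es, colnames(expr)),
                     method = "gsva", gene_set = nm)
  })
  names(out) <- names(sets)
  if (single) out[[1]] else out
}

# Per-gene cross-sample statistic: Gaussian kernel CDF (bandwidth sd/4) or
# cross-sample ranks. Zero-variance genes under the Gaussian kernel fall
# back to ranks (all tied -> constant statistic).
.kcdf_statistic <- function(x, kcdf) {
  n <- ncol(x)
  if (kcdf == "rank")
    return(t(apply(x, 1, rank, ties.method = "average")))
  sds <- apply(x, 1, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " gene(s) with zero variance: using rank statistic for them")
  Z <- matrix(0, nrow(x), n, dimnames = dimnames(x))
  for (i in which(!flat)) {
    h <- sds[i] / 4
    d <- outer(x[i, ], x[i, ], "-") / h
    Z[i, ] <- rowMeans(stats::pnorm(d))
  }
  for (i in which(flat)) Z[i, ] <- rank(x[i, ], ties.method = "average")
  Z
}

# Weighted KS walk on a pre-ordered statistic vector; returns v+ - v-.
.ks_walk_es <- function(stat_ord, hit_ord, tau) {
  n <- length(stat_ord)
  m <- sum(hit_ord)
  w <- abs(stat_ord)^tau * hit_ord
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else hit_ord / max(m, 1)
  dec <- (1 - hit_ord) / (n - m)
  walk <- cumsum(inc - dec)
  max(c(walk, 0)) - max(c(-walk, 0))
}

#' UCell-style rank-based signature score
#'
#' Per unit (sample, cell or cell line): genes are ranked by decreasing
#' expression with mid-ranks for ties; ranks above `max_rank` are clipped to
#' `max_rank + 1`; the Mann-Whitney statistic is
#' `U = sum(ranks of set genes) - n(n+1)/2` with `n` the number of set genes
#' present, and the score `1 - U / (n * max_rank)`, clipped to [0, 1].
#'
#' @param expr An [expression_matrix()].
#' @param set Character vector of signature genes.
#' @param max_rank Rank clipping threshold (default 1500).
#' @return A `signature_scores` object (method `"ucell"`), values in [0, 1].
#' @export
ucell_score <- function(expr, set, max_rank = 1500) {
  present <- intersect(set, rownames(expr))
  if (length(present) == 0) stop("no signature genes found in the matrix")
  n <- length(present)
  if (n > max_rank) stop("set size exceeds max_rank; score undefined")
  x <- unclass(expr)
  idx <- match(present, rownames(x))
  scores <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(-x[, j], ties.method = "average")
    r[r > max_rank] <- max_rank + 1
    u <- sum(r[idx]) - n * (n + 1) / 2
    min(max(1 - u / (n * max_rank), 0), 1)
  }, numeric(1))
  signature_scores(stats::setNames(scores, colnames(x)),
                   method = "ucell", gene_set = "set")
}

#' Construct a signature-scores vector
#'
#' @param scores Named numeric vector (names = unit ids).
#' @param method Scoring method (`"gsva"` or `"ucell"`).
#' @param gene_set Name of the scored gene set.
#' @param normalized Whether scores have been z-normalized.
#' @return Object of class `signature_scores`.
#' @export
signature_scores <- function(scores, method = c("gsva", "ucell"),
                             gene_set = "set", normalized = FALSE) {
  method <- match.arg(method)
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (is.null(names(scores))) stop("scores must carry unit ids as names")
  structure(scores, method = method, gene_set = gene_set,
            normalized = isTRUE(normalized), class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("<signature_scores> %s score of set '%s', %d units%s\n",
              attr(x, "method"), attr(x, "gene_set"), length(x),
              if (attr(x, "normalized")) " (z-normalized)" else ""))
  print(utils::head(as.numeric(x), 6)); invisible(x)
}

#' Z-score normalization of signature scores
#'
#' Centers to mean 0 and scales by the population standard deviation
#' (divisor `n`), as used when normalizing UCell scores across a cell-line
#' panel.
#'
#' @param scores A `signature_scores` object (or plain named numeric).
#' @return The normalized `signature_scores` with `normalized = TRUE`.
#' @export
zscore_normalize <- function(scores) {
  x <- as.numeric(scores)
  if (length(x) < 2) stop("need >= 2 units to normalize")
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) stop("zero standard deviation: cannot z-normalize")
  z <- (x - mu) / sd_pop
  names(z) <- names(scores)
  method <- attr(scores, "method"); if (is.null(method)) method <- "gsva"
  gs <- attr(scores, "gene_set"); if (is.null(gs)) gs <- "set"
  signature_scores(z, method = method, gene_set = gs, normalized = TRUE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-safe Spearman: Pearson correlation on mid-ranks after pairwise
#' removal of missing values; two-sided p from the t distribution with
#' n - 2 degrees of freedom. A perfect |rho| = 1 reports the smallest
#' representable positive p rather than 0 so downstream log transforms stay
#' finite.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance: correlation undefined")
  rho <- stats::cor(rx, ry)
  rho <- min(max(rho, -1), 1)
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Mean signature score by expression stratum
#'
#' Splits units (cells) into "expressing" (`expression > threshold`) and
#' "non-expressing" strata and reports each stratum's mean score and the
#' difference non-expressing minus expressing — positive when expression of
#' the gene accompanies lower signature scores.
#'
#' @param cell_scores Numeric per-cell scores (e.g. a `signature_scores`).
#' @param cell_expression_of_gene Numeric per-cell expression (counts).
#' @param threshold A cell "expresses" the gene when expression > threshold
#'   (default 0).
#' @return List with `mean_expressing`, `mean_nonexpressing`, `difference`,
#'   `n_expressing`, `n_nonexpressing`.
#' @export
score_by_expression_stratum <- function(cell_scores, cell_expression_of_gene,
                                        threshold = 0) {
  s <- as.numeric(cell_scores)
  e <- as.numeric(cell_expression_of_gene)
  if (length(s) != length(e)) stop("scores and expression must align")
  expressing <- e > threshold
  if (all(expressing) || !any(expressing))
    stop(.degenerate_stratum_error(all(expressing)))
  m_ex <- mean(s[expressing]); m_non <- mean(s[!expressing])
  list(mean_expressing = m_ex, mean_nonexpressing = m_non,
       difference = m_non - m_ex,
       n_expressing = sum(expressing), n_nonexpressing = sum(!expressing))
}

.degenerate_stratum_error <- function(all_express) {
  structure(class = c("mhcscreen_degenerate_stratum", "error", "condition"),
            list(message = if (all_express)
              "degenerate stratum: every cell expresses the gene"
              else "degenerate stratum: no cell expresses the gene",
              call = NULL))
}
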