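#' Signature-correlation filter
#'
#' Keeps genes whose expression is Spearman-anticorrelated with the MHC-I
#' signature score: rho <= `rho_signature_max` (inclusive, matching the
#' "less than or equal to -0.15" criterion) with p < `p_max`. The per-gene
#' correlation is the tie-safe mid-rank Spearman of [spearman_cor()],
#' vectorized across genes.
#'
#' @param expr An [expression_matrix()].
#' @param scores Per-sample signature scores (named; names must cover
#'   `colnames(expr)`).
#' @param thresholds A [screen_thresholds()].
#' @return List with `pass` (character vector of surviving genes, input
#'   order) and `table` (per-gene rho, p, n).
#' @export
correlation_filter <- function(expr, scores, thresholds = screen_thresholds()) {
  samples <- intersect(colnames(expr), names(scores))
  if (length(samples) < 3) stop("need >= 3 shared samples")
  X <- unclass(expr)[, samples, drop = FALSE]
  s <- as.numeric(scores[samples])
  n <- length(samples)
  rs <- rank(s, ties.method = "average")
  rs_c <- rs - mean(rs)
  R <- t(apply(X, 1, rank, ties.method = "average"))
  Rc <- R - rowMeans(R)
  denom <- sqrt(rowSums(Rc^2) * sum(rs_c^2))
  rho <- as.vector(Rc %*% rs_c) / denom
  rho[denom == 0] <- NA
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  tab <- data.frame(gene = rownames(X), rho = rho, p_value = p, n = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  pass <- tab$gene[!is.na(rho) & rho <= thresholds$rho_signature_max &
                     p < thresholds$p_max]
  list(pass = pass, table = tab)
}

#' Expression-level filter
#'
#' Keeps genes whose mean expression across samples is at least `expr_min`
#' (inclusive) on the log2(TPM + 0.001) scale; any other declared scale is
#' an error.
#'
#' @inheritParams correlation_filter
#' @return Character vector of surviving genes.
#' @export
expression_filter <- function(expr, thresholds = screen_thresholds()) {
  if (expr_scale(expr) != "log2_tpm")
    stop("expression filter is defined on the log2_tpm scale, got ",
         expr_scale(expr))
  rn <- rowMeans(unclass(expr))
  rownames(expr)[rn >= thresholds$expr_min]
}

#' Prognostic filter
#'
#' Keeps genes with a focal-cohort prognostic score strictly below
#' `prognostic_max` ("less than -12") that are risky in strictly more than
#' `min_risky_cohorts` cohorts ("more than three tumor types"). Genes with
#' an unavailable focal score are excluded with a message.
#'
#' @param prognostic A [batch_prognostic_scores()] table.
#' @param focal_cohort Cohort label driving the score threshold.
#' @param thresholds A [screen_thresholds()].
#' @return Character vector of surviving genes.
#' @export
prognostic_filter <- function(prognostic, focal_cohort,
                              thresholds = screen_thresholds()) {
  if (!focal_cohort %in% colnames(prognostic$scores))
    stop("prognostic table does not cover cohort '", focal_cohort, "'")
  sc <- prognostic$scores[, focal_cohort]
  unavailable <- is.na(sc)
  if (any(unavailable))
    message(sum(unavailable), " gene(s) with unavailable focal prognostic score excluded")
  keep <- !unavailable & sc < thresholds$prognostic_max &
    prognostic$n_cohorts_risky > thresholds$min_risky_cohorts
  rownames(prognostic$scores)[keep]
}

#' Intersection of screening criteria
#'
#' Exact set intersection of two or more gene sets, listed lexicographically.
#'
#' @param sets List of >= 2 character vectors.
#' @return Character vector (sorted).
#' @export
intersect_candidates <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) stop("need >= 2 sets")
  sort(Reduce(intersect, sets))
}

#' Tumor-infiltrating-lymphocyte correlation filter
#'
#' Keeps candidate genes whose Spearman correlation with both the CD8 T and
#' activated NK fractions is strictly below `rho_til_max` ("R < -0.1").
#'
#' @param candidates Character vector of candidate genes.
#' @param rho_matrix The `rho` matrix from
#'   [correlate_expression_with_fractions()], covering the candidates.
#' @param thresholds A [screen_thresholds()].
#' @param cell_types The two required cell-type columns.
#' @return Character vector of surviving genes.
#' @export
til_filter <- function(candidates, rho_matrix,
                       thresholds = screen_thresholds(),
                       cell_types = c("CD8_T", "NK_activated")) {
  missing_ct <- setdiff(cell_types, colnames(rho_matrix))
  if (length(missing_ct) > 0)
    stop("rho matrix lacks cell type(s): ", paste(missing_ct, collapse = ", "))
  candidates <- intersect(candidates, rownames(rho_matrix))
  keep <- vapply(candidates, function(g)
    all(!is.na(rho_matrix[g, cell_types]) &
          rho_matrix[g, cell_types] < thresholds$rho_til_max), logical(1))
  candidates[keep]
}

#' Cell-line dual-effector filter
#'
#' Keeps candidates whose cell-line expression is negatively correlated
#' with the z-normalized MHC-I score (Spearman rho < `cellline_rho_max`)
#' and whose median dependency score across lines is strictly below
#' `dependency_max` ("score < -0.5", marking essentiality). Candidates
#' absent from the dependency table are excluded with a message.
#'
#' @param candidates Character vector of candidate genes.
#' @param panel A [simulate_cellline_panel()]-style object (elements
#'   `expression`, `dependency`).
#' @param panel_scores Per-line MHC-I `signature_scores`; z-normalized
#'   across lines ([zscore_normalize()] is applied if not already).
#' @param thresholds A [screen_thresholds()].
#' @return List with `pass` (dual-effector genes) and `table` (per-gene
#'   rho, median dependency).
#' @export
cellline_dual_effector_filter <- function(candidates, panel, panel_scores,
                                          thresholds = screen_thresholds()) {
  if (!isTRUE(attr(panel_scores, "normalized"))) {
    message("z-normalizing cell-line signature scores across lines")
    panel_scores <- zscore_normalize(panel_scores)
  }
  lines <- intersect(colnames(panel$expression), names(panel_scores))
  in_dep <- candidates %in% rownames(panel$dependency) &
    candidates %in% rownames(panel$expression)
  if (any(!in_dep))
    message(sum(!in_dep), " candidate(s) absent from the cell-line panel excluded")
  candidates <- candidates[in_dep]
  rows <- lapply(candidates, function(g) {
    r <- tryCatch(spearman_cor(unclass(panel$expression)[g, lines],
                               as.numeric(panel_scores[lines])),
                  error = function(e) list(rho = NA_real_, p_value = NA_real_))
    data.frame(gene = g, rho = r$rho,
               median_dependency = stats::median(panel$dependency[g, ]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(gene = character(0), rho = numeric(0),
                                      median_dependency = numeric(0))
  pass <- tab$gene[!is.na(tab$rho) & tab$rho < thresholds$cellline_rho_max &
                     tab$median_dependency < thresholds$dependency_max]
  list(pass = pass, table = tab)
}

#' Single-cell validation of candidate genes
#'
#' Reproduces the single-cell sanity check: samples with a tumor-cell
#' proportion below 10% or above 90% (from the annotations) are excluded;
#' within each remaining sample the MHC-I program is scored per tumor cell
#' (UCell-style) and compared between cells that do or do not express each
#' gene (count > 0); and each gene's mean tumor-cell expression is
#' correlated (Spearman) with the per-sample immune-cell-type proportions.
#'
#' @param sc An `sc_cohort` from [simulate_single_cell()] (or any list with
#'   the same per-sample structure).
#' @param genes Genes to validate.
#' @param signature MHC-I signature genes (default [mhc1_signature()]).
#' @param min_tumor,max_tumor Tumor-proportion exclusion bounds.
#' @return List with `per_gene` (data.frame: mean score difference
#'   non-expressing minus expressing, fraction of samples with a positive
#'   difference, samples used) and `rho` (gene x cell-type Spearman matrix
#'   of mean tumor expression vs cell-type proportion), plus
#'   `samples_used`.
#' @export
single_cell_validation <- function(sc, genes, signature = mhc1_signature(),
                                   min_tumor = 0.10, max_tumor = 0.90) {
  props <- vapply(sc$samples, function(s)
    mean(s$cell_types == "Cancer_epithelial"), numeric(1))
  keep <- props >= min_tumor & props <= max_tumor
  if (sum(keep) < 3) stop("fewer than 3 samples survive the tumor-fraction exclusion")
  used <- names(sc$samples)[keep]
  cell_types <- sort(unique(unlist(lapply(sc$samples[keep], function(s)
    unique(s$cell_types)))))
  diffs <- matrix(NA_real_, length(genes), length(used),
                  dimnames = list(genes, used))
  mean_expr <- diffs
  type_prop <- matrix(0, length(used), length(cell_types),
                      dimnames = list(used, cell_types))
  for (sm in used) {
    s <- sc$samples[[sm]]
    tumor <- names(s$cell_types)[s$cell_types == "Cancer_epithelial"]
    type_prop[sm, ] <- vapply(cell_types, function(ct)
      mean(s$cell_types == ct), numeric(1))
    if (length(tumor) < 4) next
    cnt <- s$counts[, tumor, drop = FALSE]
    sc_scores <- ucell_score(cnt, signature,
                             max_rank = max(nrow(cnt) - 1, length(signature)))
    for (g in intersect(genes, rownames(cnt))) {
      mean_expr[g, sm] <- mean(unclass(cnt)[g, ])
      st <- tryCatch(score_by_expression_stratum(sc_scores, unclass(cnt)[g, ]),
                     error = function(e) NULL)
      if (!is.null(st)) diffs[g, sm] <- st$difference
    }
  }
  per_gene <- data.frame(
    gene = genes,
    mean_difference = rowMeans(diffs, na.rm = TRUE),
    frac_positive = apply(diffs, 1, function(d)
      if (all(is.na(d))) NA_real_ else mean(d[!is.na(d)] > 0)),
    n_samples = rowSums(!is.na(diffs)),
    row.names = NULL, stringsAsFactors = FALSE)
  rho <- matrix(NA_real_, length(genes), length(cell_types),
                dimnames = list(genes, cell_types))
  for (g in genes) {
    ok <- !is.na(mean_expr[g, ])
    if (sum(ok) >= 3) {
      for (ct in cell_types) {
        r <- tryCatch(spearman_cor(mean_expr[g, ok], type_prop[ok, ct]),
                      error = function(e) NULL)
        if (!is.null(r)) rho[g, ct] <- r$rho
      }
    }
  }
  list(per_gene = per_gene, rho = rho, samples_used = used)
}

#' Run the full screening cascade
#'
#' Executes, with per-stage provenance: (1) GSVA-style MHC-I scoring of the
#' focal cohort; (2) the signature-correlation filter over all genes;
#' (3) multi-cohort prognostic scoring of the correlation survivors and the
#' prognostic filter; (4) the expression filter; (5) intersection of the
#' three criteria into the candidate set; (6) TIL-fraction correlation and
#' the dual CD8 T / activated NK filter; (7) when a cell-line panel is
#' supplied, UCell scoring z-normalized across lines, and the dependency
#' dual-effector filter. Deterministic given identical inputs and config.
#'
#' @param cohort A `synthetic_cohort`, or any list with `expression`
#'   ([expression_matrix()]) and `clinical` ([clinical_table()]) elements
#'   (and optionally `fractions` when `fraction_source = "supplied"`).
#' @param panel Optional cell-line panel (elements `expression`,
#'   `dependency`).
#' @param config A [run_config()].
#' @return An object of class `screen_result`: per-stage gene sets and
#'   cardinalities, the final `candidates` and `dual_effectors`, thresholds
#'   and seed used, and per-stage tables.
#' @export
run_full_screen <- function(cohort, panel = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  expr <- cohort$expression
  clinical <- cohort$clinical
  focal <- config$focal_cohort
  if (is.null(focal)) focal <- unique(clinical$cohort)[1]
  focal_samples <- intersect(clinical$sample_id[clinical$cohort == focal],
                             colnames(expr))
  if (length(focal_samples) < 3) stop("focal cohort has too few samples")
  fexpr <- expr[, focal_samples]
  t0 <- proc.time()[["elapsed"]]
  stages <- list(); tables <- list()
  all_genes <- rownames(expr)
  stages$input <- all_genes

  sig_scores <- gsva_score(fexpr, config$signature, kcdf = config$kcdf)
  cf <- correlation_filter(fexpr, sig_scores, th)
  stages$correlation <- cf$pass
  tables$correlation <- cf$table

  prog <- batch_prognostic_scores(expr, clinical, genes = cf$pass,
                                  endpoints = config$endpoints,
                                  horizons = config$horizons,
                                  alpha = config$alpha,
                                  risky_threshold = th$prognostic_max,
                                  dichotomize = config$dichotomize_expression)
  stages$prognostic <- prognostic_filter(prog, focal, th)
  tables$prognostic <- summary(prog)

  stages$expression <- expression_filter(fexpr, th)
  candidates <- intersect_candidates(list(stages$correlation,
                                          stages$prognostic,
                                          stages$expression))
  stages$candidates <- candidates

  fractions <- if (config$fraction_source == "supplied") {
    if (is.null(cohort$fractions)) stop("fraction_source='supplied' but cohort has no fractions")
    cohort$fractions
  } else {
    suppressWarnings(estimate_fractions(fexpr, config$signature_matrix))
  }
  corr_til <- correlate_expression_with_fractions(fexpr, fractions,
                                                  genes = candidates)
  stages$til <- til_filter(candidates, corr_til$rho, th)
  tables$til <- corr_til$rho

  dual <- character(0); dual_table <- NULL
  if (!is.null(panel)) {
    pl_scores <- zscore_normalize(ucell_score(panel$expression, config$signature,
                                              max_rank = min(1500, nrow(panel$expression) - 1)))
    dd <- cellline_dual_effector_filter(stages$til, panel, pl_scores, th)
    dual <- dd$pass
    dual_table <- dd$table
  }
  stages$dual_effectors <- dual
  tables$dual <- dual_table

  structure(list(stages = stages,
                 cardinalities = vapply(stages, length, integer(1)),
                 candidates = candidates,
                 til_negative = stages$til,
                 dual_effectors = dual,
                 focal_cohort = focal,
                 thresholds = th, config = config, tables = tables,
                 seed = config$seed,
                 timing = proc.time()[["elapsed"]] - t0),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("MHC-I negative-regulator screen\n")
  cat(sprintf("  focal cohort: %s\n", x$focal_cohort))
  for (nm in names(x$stages))
    cat(sprintf("  %-14s %d genes\n", nm, length(x$stages[[nm]])))
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  data.frame(stage = names(object$stages),
             n_genes = unname(object$cardinalities),
             stringsAsFactors = FALSE)
}
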