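#' Screening thresholds
#'
#' The cascade's cutoffs, with defaults as printed in the source data
#' analysis: genes pass the signature-correlation filter when Spearman rho
#' <= -0.15 (inclusive) with p < 0.05; the expression filter when mean
#' log2(TPM + 0.001) >= 1; the prognostic filter when the focal-cohort
#' prognostic score is < -12 (strict) and the gene is risky in more than
#' `min_risky_cohorts` cohorts (strict >); the TIL filter when Spearman rho
#' with both CD8 T and activated NK fractions is < -0.1 (strict); and the
#' dual-effector filter when the cell-line expression-vs-MHC-I correlation
#' is < 0 and the median dependency score is < -0.5 (strict).
#'
#' @param rho_signature_max Upper bound (inclusive) on the gene-vs-signature
#'   Spearman rho.
#' @param p_max Significance cutoff for the correlation filter (strict <).
#' @param expr_min Minimum mean expression on the log2(TPM + 0.001) scale
#'   (inclusive).
#' @param prognostic_max Upper bound (strict) on the focal-cohort prognostic
#'   score.
#' @param min_risky_cohorts A gene must be risky in strictly more than this
#'   many cohorts.
#' @param rho_til_max Upper bound (strict) on the gene-vs-TIL-fraction rho,
#'   required for both CD8 T and activated NK.
#' @param dependency_max Upper bound (strict) on the median cell-line
#'   dependency score.
#' @param cellline_rho_max Upper bound (strict) on the cell-line
#'   expression-vs-MHC-I-score Spearman rho.
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(rho_signature_max = -0.15, p_max = 0.05,
                              expr_min = 1.0, prognostic_max = -12,
                              min_risky_cohorts = 3, rho_til_max = -0.1,
                              dependency_max = -0.5, cellline_rho_max = 0.0) {
  th <- list(rho_signature_max = rho_signature_max, p_max = p_max,
             expr_min = expr_min, prognostic_max = prognostic_max,
             min_risky_cohorts = min_risky_cohorts, rho_til_max = rho_til_max,
             dependency_max = dependency_max, cellline_rho_max = cellline_rho_max)
  # correlation thresholds outside [-1, 1] are permitted: they make the
  # corresponding stage trivially empty or trivially full, which is a valid
  # (if extreme) configuration for sensitivity runs
  if (th$p_max <= 0 || th$p_max > 1) stop("p_max must lie in (0, 1]")
  structure(th, class = "screen_thresholds")
}

#' Run configuration for the full screen
#'
#' Bundles thresholds, the MHC-I signature, the survival-scoring grid and
#' the fraction source into one object consumed by [run_full_screen()].
#'
#' @param thresholds A [screen_thresholds()] object.
#' @param signature Character vector: the MHC-I gene signature
#'   (default [mhc1_signature()]).
#' @param endpoints Survival endpoints entering the prognostic score.
#' @param horizons Administrative-censoring horizons in years; `Inf` means
#'   no truncation.
#' @param alpha Per-fit significance gate for prognostic contributions.
#' @param focal_cohort Cohort label on which the correlation, expression and
#'   focal prognostic filters run; `NULL` = first cohort in the data.
#' @param fraction_source `"deconvolution"` (estimate TIL fractions from the
#'   mixture with [estimate_fractions()]) or `"supplied"` (use fractions
#'   provided to [run_full_screen()]).
#' @param signature_matrix Reference [signature matrix][default_signature_matrix]
#'   for deconvolution.
#' @param kcdf Kernel for GSVA-style scoring of the bulk cohort.
#' @param dichotomize_expression Use median-dichotomized expression instead of
#'   the continuous z-scored covariate in Cox fits (sensitivity mode).
#' @param seed Integer seed recorded in provenance and used for any stochastic
#'   step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(thresholds = screen_thresholds(),
                       signature = mhc1_signature(),
                       endpoints = c("OS", "DSS", "PFS", "TTE"),
                       horizons = c(1, 3, 5, 10, Inf),
                       alpha = 0.05,
                       focal_cohort = NULL,
                       fraction_source = c("deconvolution", "supplied"),
                       signature_matrix = default_signature_matrix(),
                       kcdf = c("gaussian", "rank"),
                       dichotomize_expression = FALSE,
                       seed = 1L) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (any(horizons <= 0)) stop("horizons must be positive")
  if (length(seed) != 1 || is.na(seed) || seed != round(seed))
    stop("seed must be a single integer")
  structure(list(thresholds = thresholds, signature = signature,
                 endpoints = endpoints, horizons = horizons, alpha = alpha,
                 focal_cohort = focal_cohort,
                 fraction_source = match.arg(fraction_source),
                 signature_matrix = signature_matrix,
                 kcdf = match.arg(kcdf),
                 dichotomize_expression = isTRUE(dichotomize_expression),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Synthetic-cohort simulation settings
#'
#' Defines the study conditions the generator emulates: bulk tumor cohorts
#' whose MHC-I signature expression is driven by a latent interferon-type
#' activity, immune fractions coupled to that activity, planted negative
#' regulators anti-correlated with it, survival hazards increasing in
#' planted-gene expression across several endpoints, and a cell-line panel
#' with strongly negative dependency scores for planted dual-effectors.
#'
#' @param n_samples Samples per cohort.
#' @param n_genes Total genes (signature + markers + planted + decoys).
#' @param n_signature_genes Size of the MHC-I signature (8).
#' @param n_planted_negative Planted negative regulators.
#' @param n_planted_dual Planted dual-effectors (a subset of the planted
#'   negative regulators that additionally carry essential dependency).
#' @param noise_sd Per-gene residual noise SD on the log2 scale.
#' @param b Planted anti-correlation strength (> 0): planted expression is
#'   `mu - b * a + noise` with latent activity `a ~ N(0, 1)`.
#' @param s Signature coupling strength: signature-gene expression is
#'   `mu + s * a + noise`.
#' @param beta Per-endpoint log-hazard coefficient per planted gene
#'   (applied to mean-centered expression).
#' @param baseline_hazard Exponential baseline event rate per year.
#' @param censoring_rate Target fraction censored by independent exponential
#'   censoring, in [0, 1).
#' @param dirichlet_alpha Named concentration vector over the immune /
#'   epithelial cell types of [default_signature_matrix()].
#' @param frac_coupling Coupling `c` added as `c * a` to the CD8 T and
#'   activated-NK Dirichlet log-weights before renormalization.
#' @param n_cohorts Number of cohorts (cancer types) to simulate.
#' @param n_cell_lines Cell lines in the panel.
#' @param sc_n_samples,sc_cells_per_sample,sc_n_genes,sc_dropout,sc_effect
#'   Single-cell generator settings: number of patient samples, cells per
#'   sample, genes carried (signature + planted + decoy subset), dropout
#'   probability for planted-gene expression in tumor cells, and the
#'   log-scale reduction of MHC-I program expression in cells expressing a
#'   planted gene.
#' @param seed Integer master seed; all sub-streams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, n_genes = 2000,
                       n_signature_genes = 8, n_planted_negative = 25,
                       n_planted_dual = 5, noise_sd = 1, b = 0.8, s = 1,
                       beta = 0.08, baseline_hazard = 0.08,
                       censoring_rate = 0.3,
                       dirichlet_alpha = c(CD8_T = 3, NK_activated = 2,
                                           CD4_T = 3, T_reg = 2, B_cell = 2,
                                           Monocyte = 3, Cancer_epithelial = 15),
                       frac_coupling = 0.6,
                       n_cohorts = 6, n_cell_lines = 40,
                       sc_n_samples = 16, sc_cells_per_sample = 120,
                       sc_n_genes = 120, sc_dropout = 0.45, sc_effect = 1.0,
                       seed = 1L) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_signature_genes = n_signature_genes,
              n_planted_negative = n_planted_negative,
              n_planted_dual = n_planted_dual, noise_sd = noise_sd,
              b = b, s = s, beta = beta, baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              dirichlet_alpha = dirichlet_alpha,
              frac_coupling = frac_coupling, n_cohorts = n_cohorts,
              n_cell_lines = n_cell_lines, sc_n_samples = sc_n_samples,
              sc_cells_per_sample = sc_cells_per_sample,
              sc_n_genes = sc_n_genes, sc_dropout = sc_dropout,
              sc_effect = sc_effect, seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 2 || n_genes < 1 || n_cohorts < 1) stop("counts must be positive")
    if (n_planted_dual > n_planted_negative)
      stop("planted dual-effectors must be a subset of planted negatives")
    n_markers <- 3L * ncol(default_signature_matrix())
    if (n_signature_genes + n_planted_negative + n_markers > n_genes)
      stop("more planted/signature/marker genes than total genes")
    if (censoring_rate < 0 || censoring_rate >= 1)
      stop("censoring_rate must lie in [0, 1)")
    if (b < 0) stop("anti-correlation strength b must be >= 0")
  })
  structure(cfg, class = "sim_config")
}
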