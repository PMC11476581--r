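#' Simulate multi-cohort bulk tumor expression with survival
#'
#' Generates the statistical structure the screen assumes, per cohort: a
#' latent interferon-type activity `a ~ N(0, 1)` per sample drives the
#' MHC-I signature genes (`mu + s*a + noise`), immune fractions drawn from
#' a Dirichlet and tilted so CD8 T and activated-NK components increase
#' with `a`, planted negative regulators with expression `mu - b*a + noise`,
#' deconvolution marker genes generated as the linear signature-matrix
#' mixture of the true fractions, and independent decoy genes. Survival
#' times per endpoint follow an exponential proportional-hazards model with
#' linear predictor `sum(beta * centered planted expression)` and
#' independent exponential censoring calibrated to the configured censoring
#' rate. Expression is emitted on the log2(TPM + 0.001) scale. Identical
#' configuration and seed reproduce the cohort exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: list with `expression`
#'   (an [expression_matrix()] over all cohorts' samples), `clinical` (a
#'   [clinical_table()] with endpoints OS/DSS/PFS/TTE), `fractions` (true
#'   samples x cell-type `fraction_matrix`), `latent` (named activity
#'   vector) and `ground_truth` (planted negative-regulator ids, planted
#'   dual-effector ids, true beta, decoy ids).
#' @export
simulate_bulk_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  u <- .sim_universe(config)
  n <- config$n_samples
  S <- default_signature_matrix()
  ep_names <- c("OS", "DSS", "PFS", "TTE")
  expr_cols <- list(); lat <- list(); fr <- list(); clin_rows <- list()
  for (ci in seq_len(config$n_cohorts)) {
    co <- paste0("C", ci)
    sids <- sprintf("%s_S%03d", co, seq_len(n))
    a <- stats::rnorm(n)
    X <- matrix(0, length(u$genes), n, dimnames = list(u$genes, sids))
    X[u$sig, ] <- matrix(u$mu_sig + config$s * rep(a, each = length(u$sig)) +
                           stats::rnorm(length(u$sig) * n, sd = config$noise_sd),
                         length(u$sig), n)
    X[u$planted, ] <- matrix(u$mu_plt - config$b * rep(a, each = length(u$planted)) +
                               stats::rnorm(length(u$planted) * n, sd = config$noise_sd),
                             length(u$planted), n)
    X[u$decoys, ] <- u$mu_dcy + matrix(stats::rnorm(length(u$decoys) * n,
                                                    sd = config$noise_sd),
                                       length(u$decoys), n)
    f <- .sim_fractions(n, a, config)
    lin <- S %*% t(f) * 50                       # marker mixture, linear scale
    X[rownames(S), ] <- log2(lin * exp(stats::rnorm(length(lin), sd = 0.1)) + 0.001)
    # survival: centered planted expression enters the linear predictor
    Xp <- X[u$planted, , drop = FALSE] - u$mu_plt
    lp <- colSums(config$beta * Xp)
    eps <- list()
    for (ep in ep_names) {
      rate <- config$baseline_hazard * exp(lp)
      t_event <- stats::rexp(n, rate = rate)
      if (config$censoring_rate > 0) {
        c_rate <- config$baseline_hazard *
          config$censoring_rate / (1 - config$censoring_rate)
        t_cens <- stats::rexp(n, rate = c_rate)
      } else t_cens <- rep(Inf, n)
      eps[[ep]] <- list(time = pmin(t_event, t_cens),
                        event = as.numeric(t_event <= t_cens))
    }
    clin_rows[[co]] <- clinical_table(sids, eps, cohort = co,
                                      er_status = rep("positive", n))
    expr_cols[[co]] <- X
    lat[[co]] <- stats::setNames(a, sids)
    rownames(f) <- sids
    fr[[co]] <- f
  }
  expr <- expression_matrix(do.call(cbind, expr_cols), scale = "log2_tpm")
  clin <- do.call(rbind, lapply(clin_rows, as.data.frame))
  rownames(clin) <- NULL
  clin <- clinical_table(clin$sample_id,
                         stats::setNames(lapply(ep_names, function(ep)
                           list(time = clin[[paste0(ep, "_time")]],
                                event = clin[[paste0(ep, "_event")]])), ep_names),
                         cohort = clin$cohort, er_status = clin$er_status)
  structure(list(expression = expr, clinical = clin,
                 fractions = fraction_matrix(do.call(rbind, fr)),
                 latent = unlist(unname(lat)),
                 ground_truth = list(planted_negative = u$planted,
                                     planted_dual = u$dual,
                                     beta = stats::setNames(rep(config$beta,
                                                                length(u$planted)),
                                                            u$planted),
                                     decoys = u$decoys)),
            class = "synthetic_cohort")
}

# Shared gene universe: MHC-I signature, deconvolution markers, planted
# negative regulators (first n_planted_dual double as dual-effectors), decoys.
.sim_universe <- function(config) {
  sig <- if (config$n_signature_genes == 8) mhc1_signature()
         else sprintf("SIG_%02d", seq_len(config$n_signature_genes))
  markers <- rownames(default_signature_matrix())
  planted <- sprintf("PLT_%03d", seq_len(config$n_planted_negative))
  n_dcy <- config$n_genes - length(sig) - length(markers) - length(planted)
  decoys <- sprintf("DCY_%04d", seq_len(n_dcy))
  list(genes = c(sig, markers, planted, decoys), sig = sig,
       planted = planted, dual = planted[seq_len(config$n_planted_dual)],
       decoys = decoys, mu_sig = 5, mu_plt = 3,
       mu_dcy = stats::runif(n_dcy, 0, 5))
}

# Dirichlet fractions with CD8 T / activated NK log-weights tilted by the
# latent activity; stays on the simplex by construction.
.sim_fractions <- function(n, a, config) {
  alpha <- config$dirichlet_alpha
  types <- names(alpha)
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha), dimnames = list(NULL, types))
  tilt <- exp(config$frac_coupling * a)
  for (ct in intersect(c("CD8_T", "NK_activated"), types)) g[, ct] <- g[, ct] * tilt
  fraction_matrix(g / rowSums(g))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d samples, %d cohorts, %d planted negatives (%d dual)\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$clinical$cohort)),
              length(x$ground_truth$planted_negative),
              length(x$ground_truth$planted_dual)))
  invisible(x)
}

#' Simulate a cell-line panel with dependency scores
#'
#' Mirrors [simulate_bulk_cohort()]'s expression structure (latent activity,
#' signature coupling, planted anti-correlation) over ~40 cell lines on the
#' log-normalized scale, without survival. Dependency scores are drawn
#' N(-0.8, 0.1) for planted dual-effectors (essential: < -0.5 with
#' probability ~0.999) and N(0, 0.15) for all other genes.
#'
#' @param config A [sim_config()].
#' @return An object of class `cellline_panel`: list with `expression`
#'   (lines as samples, scale `"lognorm"`), `dependency` (gene x line
#'   matrix) and `ground_truth` dual-effector ids.
#' @export
simulate_cellline_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  u <- .sim_universe(config)
  n <- config$n_cell_lines
  ids <- sprintf("CL%02d", seq_len(n))
  a <- stats::rnorm(n)
  X <- matrix(0, length(u$genes), n, dimnames = list(u$genes, ids))
  X[u$sig, ] <- matrix(u$mu_sig + config$s * rep(a, each = length(u$sig)) +
                         stats::rnorm(length(u$sig) * n, sd = config$noise_sd),
                       length(u$sig), n)
  X[u$planted, ] <- matrix(u$mu_plt - config$b * rep(a, each = length(u$planted)) +
                             stats::rnorm(length(u$planted) * n, sd = config$noise_sd),
                           length(u$planted), n)
  others <- setdiff(u$genes, c(u$sig, u$planted))
  X[others, ] <- matrix(stats::rnorm(length(others) * n, mean = 2,
                                     sd = config$noise_sd),
                        length(others), n)
  X <- pmax(X, 0)
  dep <- matrix(stats::rnorm(length(u$genes) * n, 0, 0.15),
                length(u$genes), n, dimnames = list(u$genes, ids))
  dep[u$dual, ] <- stats::rnorm(length(u$dual) * n, -0.8, 0.1)
  structure(list(expression = expression_matrix(X, scale = "lognorm"),
                 dependency = dep,
                 ground_truth = list(planted_dual = u$dual)),
            class = "cellline_panel")
}

#' @export
print.cellline_panel <- function(x, ...) {
  cat(sprintf("<cellline_panel> %d genes x %d cell lines\n",
              nrow(x$expression), ncol(x$expression)))
  invisible(x)
}

#' Simulate annotated single-cell samples
#'
#' Per patient sample: a tumor-cell proportion drawn Uniform(0.05, 0.95)
#' assigns cells to cancer-epithelial vs immune types; each tumor cell
#' carries a latent suppressor activity `u ~ N(0, 1)` that raises the
#' probability of expressing each planted gene (zero-inflation with base
#' dropout `sc_dropout`) and lowers the Poisson mean of the MHC-I program
#' genes by `exp(-sc_effect * u / 2)`; thus cells that express planted
#' genes score lower on the MHC-I program. Counts are Poisson; "expressing"
#' downstream means count > 0.
#'
#' @param config A [sim_config()].
#' @return An object of class `sc_cohort`: list of per-sample elements
#'   (`counts`: genes x cells [expression_matrix()] on the counts scale,
#'   `cell_types`: named character vector, `tumor_prop_drawn`), plus
#'   `genes` and `ground_truth`.
#' @export
simulate_single_cell <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  u <- .sim_universe(config)
  n_dcy <- max(config$sc_n_genes - length(u$sig) - length(u$planted), 0)
  genes <- c(u$sig, u$planted, u$decoys[seq_len(min(n_dcy, length(u$decoys)))])
  immune_types <- c("CD8_T", "NK_activated", "CD4_T", "B_cell")
  samples <- vector("list", config$sc_n_samples)
  names(samples) <- sprintf("P%02d", seq_len(config$sc_n_samples))
  for (si in seq_along(samples)) {
    nc <- config$sc_cells_per_sample
    prop <- stats::runif(1, 0.05, 0.95)
    is_tumor <- stats::runif(nc) < prop
    ct <- ifelse(is_tumor, "Cancer_epithelial",
                 sample(immune_types, nc, replace = TRUE))
    cells <- sprintf("%s_c%03d", names(samples)[si], seq_len(nc))
    cnt <- matrix(0L, length(genes), nc, dimnames = list(genes, cells))
    cnt[u$decoys[seq_len(min(n_dcy, length(u$decoys)))], ] <-
      stats::rpois(min(n_dcy, length(u$decoys)) * nc, 1)
    # immune cells: high MHC-I program, rare planted expression
    n_imm <- sum(!is_tumor)
    if (n_imm > 0) {
      cnt[u$sig, !is_tumor] <- stats::rpois(length(u$sig) * n_imm, 3)
      cnt[u$planted, !is_tumor] <- stats::rpois(length(u$planted) * n_imm, 0.2)
    }
    n_tum <- sum(is_tumor)
    if (n_tum > 0) {
      act <- stats::rnorm(n_tum)                       # latent suppressor activity
      p_expr <- stats::plogis(stats::qlogis(1 - config$sc_dropout) + 1.5 * act)
      expr_flag <- matrix(stats::runif(length(u$planted) * n_tum) <
                            rep(p_expr, each = length(u$planted)),
                          length(u$planted), n_tum)
      cnt[u$planted, is_tumor] <- expr_flag * (1L + stats::rpois(length(expr_flag), 1.2))
      lam_sig <- 3 * exp(-config$sc_effect * act / 2)
      cnt[u$sig, is_tumor] <- stats::rpois(length(u$sig) * n_tum,
                                           rep(lam_sig, each = length(u$sig)))
    }
    samples[[si]] <- list(counts = expression_matrix(cnt, scale = "counts"),
                          cell_types = stats::setNames(ct, cells),
                          tumor_prop_drawn = prop)
  }
  structure(list(samples = samples, genes = genes,
                 ground_truth = list(planted_negative = u$planted,
                                     planted_dual = u$dual)),
            class = "sc_cohort")
}

#' @export
print.sc_cohort <- function(x, ...) {
  cat(sprintf("<sc_cohort> %d samples, %d genes\n",
              length(x$samples), length(x$genes)))
  invisible(x)
}
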