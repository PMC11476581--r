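#' Synthetic immune signature matrix
#'
#' A deterministic marker-gene reference covering the cell types the screen
#' needs (CD8 T, activated NK, CD4 T, regulatory T, B cells, monocytes and
#' a cancer-epithelial background), three markers per type. Each marker is
#' highly expressed in its own type and at a low basal level elsewhere; the
#' values are linear-scale reference expression. A real signature matrix
#' (e.g. LM22) can be supplied as a TSV instead wherever a
#' `signature_matrix` argument is accepted.
#'
#' @return A numeric marker-gene x cell-type matrix of class
#'   `signature_matrix`.
#' @export
default_signature_matrix <- function() {
  types <- c("CD8_T", "NK_activated", "CD4_T", "T_reg", "B_cell",
             "Monocyte", "Cancer_epithelial")
  n_marker <- 3L
  genes <- as.vector(vapply(types, function(ct)
    paste0("MRK_", ct, "_", seq_len(n_marker)), character(n_marker)))
  S <- matrix(0.5, length(genes), length(types), dimnames = list(genes, types))
  for (k in seq_along(types)) {
    rows <- (k - 1L) * n_marker + seq_len(n_marker)
    S[rows, k] <- c(60, 45, 30)   # graded marker strengths
  }
  structure(S, class = c("signature_matrix", "matrix", "array"))
}

#' Validate a signature matrix
#' @param S Numeric marker x cell-type matrix, non-negative, no all-zero
#'   column.
#' @return The validated matrix with class `signature_matrix`.
#' @export
signature_matrix <- function(S) {
  if (!is.matrix(S) || !is.numeric(S)) stop("signature matrix must be numeric")
  if (any(S < 0)) stop("signature matrix must be non-negative")
  if (is.null(rownames(S)) || is.null(colnames(S)))
    stop("signature matrix needs marker rownames and cell-type colnames")
  if (any(colSums(S) == 0)) stop("signature matrix has an all-zero column")
  structure(S, class = c("signature_matrix", "matrix", "array"))
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
.nnls <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(p); break }
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Estimate immune-cell-type fractions by constrained least squares
#'
#' Per sample, the mixture restricted to shared marker genes is regressed on
#' the signature-matrix columns by non-negative least squares and the
#' coefficients are renormalized to the simplex. This is a deterministic
#' stand-in for SVR-based deconvolution: exact on noiseless mixtures and
#' invariant to positive rescaling of a sample. Log-scale input is
#' exponentiated back to the linear scale with a warning, since
#' deconvolution is a linear-mixture model.
#'
#' @param mixture An [expression_matrix()] containing the marker genes.
#' @param signature A [signature_matrix()] (default
#'   [default_signature_matrix()]).
#' @return A `fraction_matrix`: samples x cell-types matrix of fractions
#'   (rows on the simplex), with per-sample residual norms in
#'   `attr(, "residuals")`.
#' @export
estimate_fractions <- function(mixture, signature = default_signature_matrix()) {
  shared <- intersect(rownames(signature), rownames(mixture))
  if (length(shared) == 0) stop("no marker genes shared with the signature matrix")
  M <- unclass(mixture)[shared, , drop = FALSE]
  sc <- attr(mixture, "scale")
  if (!is.null(sc) && sc != "counts") {
    warning("log-scale mixture (", sc, "): exponentiating to linear scale")
    M <- if (sc == "log2_tpm") pmax(2^M - 0.001, 0) else expm1(M)
  }
  A <- signature[shared, , drop = FALSE]
  F <- matrix(0, ncol(M), ncol(A),
              dimnames = list(colnames(M), colnames(A)))
  res <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    b <- M[, j]
    if (all(b == 0)) stop("all-zero mixture column for sample ", colnames(M)[j])
    x <- .nnls(A, b)
    res[j] <- sqrt(sum((A %*% x - b)^2))
    if (sum(x) == 0) stop("degenerate NNLS solution for sample ", colnames(M)[j])
    F[j, ] <- x / sum(x)
  }
  structure(F, residuals = stats::setNames(res, colnames(M)),
            class = c("fraction_matrix", "matrix", "array"))
}

#' Validate a samples-by-cell-type fraction matrix
#' @param F Numeric matrix, entries >= 0, rows summing to 1 within 1e-9.
#' @return The matrix with class `fraction_matrix`.
#' @export
fraction_matrix <- function(F) {
  if (any(F < 0)) stop("fractions must be non-negative")
  if (any(abs(rowSums(F) - 1) > 1e-9)) stop("fraction rows must sum to 1")
  structure(F, class = c("fraction_matrix", "matrix", "array"))
}

#' Spearman correlation of gene expression with cell-type fractions
#'
#' @param expr An [expression_matrix()].
#' @param fractions A `fraction_matrix` (samples x cell types); row names
#'   must overlap `colnames(expr)`.
#' @param genes Genes to correlate (default all).
#' @param cell_types Cell types to correlate (default all).
#' @return List of two genes x cell-types matrices, `rho` and `p_value`.
#' @export
correlate_expression_with_fractions <- function(expr, fractions,
                                                genes = rownames(expr),
                                                cell_types = colnames(fractions)) {
  shared <- intersect(colnames(expr), rownames(fractions))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  genes <- intersect(genes, rownames(expr))
  rho <- matrix(NA_real_, length(genes), length(cell_types),
                dimnames = list(genes, cell_types))
  pv <- rho
  X <- unclass(expr)[genes, shared, drop = FALSE]
  FF <- unclass(fractions)[shared, cell_types, drop = FALSE]
  for (ct in cell_types) {
    for (g in genes) {
      r <- tryCatch(spearman_cor(X[g, ], FF[, ct]), error = function(e) NULL)
      if (!is.null(r)) { rho[g, ct] <- r$rho; pv[g, ct] <- r$p_value }
    }
  }
  list(rho = rho, p_value = pv)
}
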