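#' Construct a validated expression matrix
#'
#' The central container of the package: a numeric gene-by-sample matrix
#' carrying a declared value scale. Genes are rows, samples are columns,
#' matching the UCSC Xena / TCGA convention. Gene identifiers are opaque
#' strings (typically HGNC symbols); no identifier mapping is attempted.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique, non-empty `rownames` (gene ids) and `colnames` (sample ids).
#' @param scale One of `"log2_tpm"` (log2(TPM + 0.001), the bulk-cohort
#'   convention), `"counts"` (non-negative integers) or `"lognorm"`
#'   (library-size log-normalized values, e.g. cell-line panels).
#' @return An object of class `expression_matrix`: the numeric matrix with a
#'   `scale` attribute.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m, scale = "log2_tpm")
#' expr_scale(em)
#' @export
expression_matrix <- function(values, scale = c("log2_tpm", "counts", "lognorm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  if (scale == "counts") {
    if (any(values < 0) || any(values != floor(values)))
      stop("counts scale requires non-negative integer values")
  }
  structure(values, scale = scale, class = c("expression_matrix", class(values)))
}

#' Declared value scale of an expression matrix
#' @param x An `expression_matrix`.
#' @return Character scalar: `"log2_tpm"`, `"counts"` or `"lognorm"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("object carries no `scale` attribute")
  s
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

# Subsetting keeps the class and scale; a vector result is returned plain.
#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("expression_matrix", class(unclass(out))))
  out
}

#' Construct a gene-set collection
#'
#' A named list of character vectors. Within-set duplicates are removed;
#' set names must be unique and sets non-empty.
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled metadata from GMT files).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) stop("`sets` must be a list")
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == "")))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) {
    s <- as.character(s)
    if (length(s) == 0) stop("gene sets must be non-empty")
    unique(s)
  })
  if (!is.null(descriptions)) {
    descriptions <- as.character(descriptions)
    if (length(descriptions) != length(sets))
      stop("`descriptions` must match the number of sets")
    names(descriptions) <- names(sets)
  }
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets\n", length(x)))
  nm <- utils::head(names(x), 5)
  for (n in nm) cat(sprintf("  %s (%d genes)\n", n, length(x[[n]])))
  if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], descriptions = attr(x, "descriptions")[i])
}

#' The default MHC class I signature
#'
#' The eight-gene MHC-I antigen-presentation signature used throughout the
#' screen: HLA-A, HLA-B, HLA-C, HLA-D, HLA-E, HLA-F, HLA-H and B2M. The
#' strings "HLA-D" and "HLA-H" are not single current HGNC symbols; the
#' signature is therefore configurable and these defaults are plain strings
#' matched verbatim against the expression matrix rownames.
#'
#' @return Character vector of eight gene identifiers.
#' @export
mhc1_signature <- function() {
  c("HLA-A", "HLA-B", "HLA-C", "HLA-D", "HLA-E", "HLA-F", "HLA-H", "B2M")
}

#' Construct a clinical table with multiple survival endpoints
#'
#' Holds per-sample follow-up for several survival endpoints (e.g. overall
#' survival "OS", disease-specific survival "DSS", progression-free survival
#' "PFS", time to event "TTE") together with a cohort label and optional
#' subtype / ER-status covariates. Times are stored in years. A sample with
#' missing time or event for an endpoint is retained but unavailable for
#' fits on that endpoint.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param endpoints Named list; each element a list/data.frame with numeric
#'   `time` (years, >= 0, NA allowed) and `event` (0/1, NA allowed) vectors
#'   of length `length(sample_ids)`.
#' @param cohort Character vector (or scalar, recycled) of cohort / cancer
#'   type labels.
#' @param subtype,er_status Optional character covariates.
#' @return A `clinical_table`: a data.frame with columns `sample_id`,
#'   `cohort`, optional covariates and `<endpoint>_time` / `<endpoint>_event`
#'   pairs; endpoint names in `attr(, "endpoints")`.
#' @export
clinical_table <- function(sample_ids, endpoints, cohort,
                           subtype = NULL, er_status = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  n <- length(sample_ids)
  if (!is.list(endpoints) || is.null(names(endpoints)) ||
      anyDuplicated(names(endpoints)))
    stop("`endpoints` must be a uniquely named list")
  cohort <- rep_len(as.character(cohort), n)
  if (anyNA(cohort)) stop("every sample needs a cohort label")
  df <- data.frame(sample_id = sample_ids, cohort = cohort,
                   stringsAsFactors = FALSE)
  if (!is.null(subtype)) df$subtype <- rep_len(as.character(subtype), n)
  if (!is.null(er_status)) df$er_status <- rep_len(as.character(er_status), n)
  for (ep in names(endpoints)) {
    tm <- as.numeric(endpoints[[ep]]$time)
    ev <- endpoints[[ep]]$event
    if (length(tm) != n || length(ev) != n)
      stop(sprintf("endpoint '%s': time/event length mismatch", ep))
    if (any(tm < 0, na.rm = TRUE))
      stop(sprintf("endpoint '%s': negative follow-up time", ep))
    if (!all(ev %in% c(0, 1) | is.na(ev)))
      stop(sprintf("endpoint '%s': event values must be 0/1", ep))
    df[[paste0(ep, "_time")]] <- tm
    df[[paste0(ep, "_event")]] <- as.numeric(ev)
  }
  structure(df, endpoints = names(endpoints),
            class = c("clinical_table", "data.frame"))
}

#' Endpoint names of a clinical table
#' @param x A `clinical_table`.
#' @return Character vector of endpoint names.
#' @export
endpoints <- function(x) attr(x, "endpoints")

#' Extract one endpoint's follow-up from a clinical table
#'
#' @param clinical A `clinical_table`.
#' @param endpoint Endpoint name.
#' @param samples Optional sample ids to restrict to (order preserved).
#' @return List with `sample_id`, `time`, `event` restricted to samples with
#'   complete follow-up for this endpoint.
#' @export
endpoint_followup <- function(clinical, endpoint, samples = NULL) {
  if (!endpoint %in% endpoints(clinical))
    stop(sprintf("unknown endpoint '%s'", endpoint))
  df <- as.data.frame(clinical)
  if (!is.null(samples)) df <- df[match(samples, df$sample_id), , drop = FALSE]
  tm <- df[[paste0(endpoint, "_time")]]
  ev <- df[[paste0(endpoint, "_event")]]
  ok <- !is.na(tm) & !is.na(ev)
  list(sample_id = df$sample_id[ok], time = tm[ok], event = ev[ok])
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("<clinical_table> %d samples, %d cohorts, endpoints: %s\n",
              nrow(x), length(unique(x$cohort)),
              paste(endpoints(x), collapse = ", ")))
  invisible(x)
}
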