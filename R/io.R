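#' Read a gene-by-sample expression matrix from TSV/CSV
#'
#' Expects gene identifiers in the first column and sample identifiers in
#' the header. The delimiter is taken from the file extension (`.csv` =
#' comma, anything else = tab). Duplicate gene rows are collapsed by their
#' mean with a warning; duplicate sample columns are a hard error, as is any
#' cell that does not parse as a finite number.
#'
#' @param path Path to the file.
#' @param scale Declared value scale; see [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("log2_tpm", "counts", "lognorm")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(raw) < 2) stop("expected a gene id column plus >= 1 sample column")
  genes <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0)
      stop(sprintf("cannot parse value '%s' at gene '%s', sample '%s'",
                   col[bad[1]], genes[bad[1]], sample_ids[j]))
    vals[, j] <- num
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene row(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "))
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  dimnames(vals) <- list(genes, sample_ids)
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column
#' (named `gene_id`), sample ids in the header, full double precision.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), format(unclass(x), digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are dropped. An empty file yields an empty collection.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()] with descriptions retained as metadata.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_collection(stats::setNames(list(), character(0))))
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("line %d: GMT lines need >= 3 tab-separated fields", i))
    sets[[f[1]]] <- f[-(1:2)]
    desc <- c(desc, f[2])
  }
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection to GMT
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(n)
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample clinical table with multiple survival endpoints
#'
#' @param path TSV/CSV file with a `sample_id` column, a `cohort` column,
#'   optional `subtype` / `er_status` columns, and one time + one event
#'   column per endpoint.
#' @param endpoint_spec Named list mapping endpoint name to
#'   `c(time = "<column>", event = "<column>")`.
#' @param time_unit `"years"` or `"days"`; days are converted to years
#'   (/365.25) on load.
#' @return A [clinical_table()]. Rows with missing time or event for an
#'   endpoint are retained but unavailable for that endpoint; negative times
#'   or events outside 0/1 are hard errors.
#' @export
read_clinical_table <- function(path, endpoint_spec,
                                time_unit = c("years", "days")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("missing 'sample_id' column")
  if (!"cohort" %in% colnames(df)) stop("missing 'cohort' column")
  eps <- list()
  for (ep in names(endpoint_spec)) {
    spec <- endpoint_spec[[ep]]
    tc <- spec[["time"]]; ec <- spec[["event"]]
    if (!tc %in% colnames(df)) stop(sprintf("missing time column '%s'", tc))
    if (!ec %in% colnames(df)) stop(sprintf("missing event column '%s'", ec))
    tm <- suppressWarnings(as.numeric(df[[tc]]))
    ev <- suppressWarnings(as.numeric(df[[ec]]))
    bad_ev <- which(!is.na(ev) & !ev %in% c(0, 1))
    if (length(bad_ev) > 0)
      stop(sprintf("endpoint '%s': event value %s outside {0,1} at row %d",
                   ep, df[[ec]][bad_ev[1]], bad_ev[1]))
    bad_tm <- which(!is.na(tm) & tm < 0)
    if (length(bad_tm) > 0)
      stop(sprintf("endpoint '%s': negative time at row %d", ep, bad_tm[1]))
    if (time_unit == "days") tm <- tm / 365.25
    eps[[ep]] <- list(time = tm, event = ev)
  }
  clinical_table(df$sample_id, eps, cohort = df$cohort,
                 subtype = df[["subtype"]], er_status = df[["er_status"]])
}
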