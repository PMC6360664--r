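#' Construct an expression matrix with sample annotations
#'
#' The central container of the package: a genes x samples numeric matrix of
#' log-scale expression values plus an optional per-sample annotation table.
#' Gene and sample identifiers are opaque, case-sensitive strings and must be
#' unique; values must be finite (missing values are not supported).
#'
#' @param values numeric matrix, genes in rows, samples in columns; must carry
#'   row and column names.
#' @param annotations optional `data.frame` of per-sample annotations, one row
#'   per sample, row names equal to the sample ids (order is realigned to the
#'   matrix columns).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` and `annotations`.
#' @export
expression_matrix <- function(values, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite (NA/NaN/Inf not supported)")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    if (!setequal(rownames(annotations), colnames(values)))
      stop("annotation row names must match the sample ids")
    annotations <- annotations[colnames(values), , drop = FALSE]
  }
  structure(list(values = values, annotations = annotations),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$annotations))
    cat("annotations:", paste(colnames(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a genes x samples expression table
#'
#' Reads a plain TSV (first column gene ids, header row sample ids) or a
#' GCT 1.2 file. Duplicate gene rows are collapsed to the row with the
#' largest variance (the most informative probe, mirroring common microarray
#' practice), with a warning; set `collapse = "error"` to forbid duplicates.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"gct"`.
#' @param collapse duplicate-gene policy, `"max_variance"` or `"error"`.
#' @param annotations optional per-sample annotation `data.frame`.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, format = c("tsv", "gct"),
                                  collapse = c("max_variance", "error"),
                                  annotations = NULL) {
  format <- match.arg(format)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             stringsAsFactors = FALSE)
    genes <- tab[[1L]]
    samples <- colnames(tab)[-1L]
    raw <- tab[, -1L, drop = FALSE]
  } else {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2"))
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    tab <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                             header = TRUE, sep = "\t", check.names = FALSE,
                             colClasses = "character", stringsAsFactors = FALSE)
    genes <- tab[[1L]]
    samples <- colnames(tab)[-(1:2)]
    raw <- tab[, -(1:2), drop = FALSE]
  }
  if (anyDuplicated(samples))
    stop("duplicate sample ids in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  values <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   raw[[j]][bad[1L]], genes[bad[1L]], samples[j]))
    values[, j] <- v
  }
  if (anyDuplicated(genes)) {
    if (collapse == "error")
      stop("duplicate gene ids: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("%d duplicate gene id(s) collapsed by maximum variance: %s",
                    length(dup), paste(dup, collapse = ", ")))
    vars <- apply(values, 1L, stats::var)
    keep <- vapply(split(seq_along(genes), genes)[unique(genes)],
                   function(idx) idx[which.max(vars[idx])], integer(1L))
    values <- values[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(values) <- genes
  expression_matrix(values, annotations = annotations)
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (format == "tsv") {
    tab <- data.frame(gene_id = gene_ids(x), x$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(x$values), ncol(x$values), sep = "\t")), con)
    tab <- data.frame(Name = gene_ids(x), Description = "na", x$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution,
#' namely the mean of the column-sorted values; within-column ranks are
#' preserved and ties receive the average of the tied target quantiles.
#' The operation is idempotent.
#'
#' @param x an `ExpressionMatrix`.
#' @return a quantile-normalized `ExpressionMatrix`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  expression_matrix(v, annotations = x$annotations)
}
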