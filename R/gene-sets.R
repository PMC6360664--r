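#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids; names must be
#'   unique and every set non-empty. Duplicate genes within a set are dropped
#'   (first occurrence kept).
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled from `""`.
#' @return an object of class `GeneSetCollection`: the named list of gene
#'   vectors with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a fully named list of gene-id vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop("`descriptions` must have one entry per set")
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (%s genes)\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, `name TAB description TAB gene...`, at least
#' one gene per line. Line order is preserved; duplicate genes within a set
#' are deduplicated.
#'
#' @param path path to the GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields (name, description, genes...)",
                 short[1L]))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  gene_set_collection(sets,
                      descriptions = vapply(fields, `[[`, character(1L), 2L))
}

#' Write a gene-set collection to GMT
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  desc <- attr(collection, "descriptions")
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[[i]], collection[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
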