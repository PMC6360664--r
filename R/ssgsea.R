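#' Single-sample GSEA enrichment score
#'
#' Per sample, genes are ranked by expression descending (expression ties get
#' average ranks; the walking order is made deterministic by breaking
#' residual ties on gene id). Walking down the ranked list, the in-set
#' cumulative distribution uses rank-derived weights `r^alpha` (r is the
#' ascending rank, so the top gene carries weight `N^alpha`) normalized to 1,
#' while the out-of-set cumulative is the unweighted empirical step function.
#' The score is the sum of their differences over all positions — the
#' rank-weighted running-sum statistic of ssGSEA. It depends only on the
#' within-sample ranks, so any strictly increasing per-sample transform
#' leaves it unchanged.
#'
#' @param x an `ExpressionMatrix`.
#' @param gene_set character vector of gene ids; the overlap with the matrix
#'   genes must be non-empty and proper (non-empty complement).
#' @param alpha rank-weight exponent >= 0 (default 0.25, the published
#'   ssGSEA default).
#' @return named numeric vector of per-sample enrichment scores, with an
#'   `n_overlap` attribute recording the in-matrix set size.
#' @export
ssgsea_score <- function(x, gene_set, alpha = 0.25) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (alpha < 0) stop("`alpha` must be >= 0")
  genes <- gene_ids(x)
  in_set <- genes %in% unique(as.character(gene_set))
  m <- sum(in_set)
  if (m == 0) stop("gene set has empty overlap with the matrix genes")
  if (m == length(genes)) stop("gene set covers all genes (empty complement)")
  scores <- vapply(seq_len(ncol(x$values)), function(j) {
    v <- x$values[, j]
    r <- rank(v, ties.method = "average")          # ascending; top gene = N
    ord <- order(-v, genes, method = "radix")      # descending walk order
    ins <- in_set[ord]
    w <- r[ord]^alpha
    p_in <- cumsum(w * ins) / sum(w * ins)
    p_out <- cumsum(!ins) / (length(genes) - m)
    sum(p_in - p_out)
  }, numeric(1L))
  names(scores) <- sample_ids(x)
  attr(scores, "n_overlap") <- m
  scores
}

#' Score a gene-set collection per sample
#'
#' Applies [ssgsea_score()] to every set of the collection; sets with no
#' overlap with the matrix genes are skipped with a warning (an error if all
#' are skipped).
#'
#' @param x an `ExpressionMatrix`.
#' @param collection a `GeneSetCollection`.
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize `"none"`, or `"minmax"`, which divides every score by
#'   (max - min) over the entire score matrix of this run (the scale contract
#'   needed for cross-cohort comparisons; within-cohort correlation and
#'   rank-split results are invariant to this choice).
#' @return an object of class `ScoreMatrix`: list with `scores`
#'   (signatures x samples matrix), `alpha`, `normalized` and `skipped`.
#' @export
score_collection <- function(x, collection, alpha = 0.25,
                             normalize = c("none", "minmax")) {
  stopifnot(inherits(x, "ExpressionMatrix"),
            inherits(collection, "GeneSetCollection"))
  normalize <- match.arg(normalize)
  genes <- gene_ids(x)
  keep <- vapply(collection, function(s) any(s %in% genes), logical(1L))
  if (!any(keep)) stop("all gene sets were skipped (no overlap with matrix genes)")
  if (any(!keep))
    warning("skipped set(s) with no overlap: ",
            paste(names(collection)[!keep], collapse = ", "))
  scores <- t(vapply(which(keep),
                     function(i) as.numeric(ssgsea_score(x, collection[[i]], alpha)),
                     numeric(ncol(x$values))))
  dimnames(scores) <- list(names(collection)[keep], sample_ids(x))
  if (normalize == "minmax") {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(list(scores = scores, alpha = alpha,
                 normalized = normalize != "none",
                 skipped = names(collection)[!keep]),
            class = "ScoreMatrix")
}

#' @export
print.ScoreMatrix <- function(x, ...) {
  cat(sprintf("ScoreMatrix: %d signatures x %d samples (alpha=%g%s)\n",
              nrow(x$scores), ncol(x$scores), x$alpha,
              if (x$normalized) ", minmax-normalized" else ""))
  invisible(x)
}

#' Write a score matrix to TSV
#'
#' @param scores a `ScoreMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  tab <- data.frame(signature = rownames(scores$scores), scores$scores,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
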