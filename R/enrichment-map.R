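#' Fisher-exact over-representation of a gene list in a collection
#'
#' One-sided (upper-tail / over-representation) hypergeometric test of the
#' 2x2 table (list membership x set membership over the universe), for every
#' set of the collection; each set is intersected with the universe before
#' testing. No multiple-testing correction is applied to the filter (the raw
#' threshold convention of enrichment-map construction); a BH-FDR column is
#' emitted for reference.
#'
#' @param gene_list character vector, must be a subset of `universe`.
#' @param collection a `GeneSetCollection`.
#' @param universe character vector of background gene ids.
#' @param p_threshold keep results with p below this (default 0.01).
#' @return `data.frame` of class `enrichment_result` with columns
#'   `set_name`, `set_size`, `list_size`, `overlap`, `universe_size`,
#'   `p_value`, `fdr`, sorted by ascending p (ties by set name), filtered to
#'   `p_value < p_threshold`.
#' @export
fisher_enrichment <- function(gene_list, collection, universe,
                              p_threshold = 0.01) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(as.character(gene_list))
  off <- setdiff(gene_list, universe)
  if (length(off))
    stop("gene(s) in list absent from universe: ", paste(off, collapse = ", "))
  nu <- length(universe)
  nl <- length(gene_list)
  res <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    k <- length(intersect(gene_list, s))
    p <- stats::phyper(k - 1, length(s), nu - length(s), nl, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(s), list_size = nl,
               overlap = k, universe_size = nu, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[res$p_value < p_threshold, , drop = FALSE]
  res <- res[order(res$p_value, res$set_name, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Build the gene-set overlap network of enriched sets
#'
#' For every pair of enriched sets, tests the significance of their gene
#' overlap with a one-sided Fisher exact (hypergeometric upper tail) test
#' over the universe; pairs with p below `edge_p_threshold` become edges.
#' The network is undirected and has no self-edges.
#'
#' @param enriched an `enrichment_result` from [fisher_enrichment()] (or any
#'   data frame with `set_name`, `overlap`, `p_value` columns).
#' @param collection the `GeneSetCollection` the sets come from.
#' @param universe background gene ids.
#' @param edge_p_threshold edge significance threshold (default 1e-10).
#' @return an object of class `EnrichmentNetwork`: list with `nodes`
#'   (set_name, n_genes in-universe, overlap with the tested list,
#'   enrichment p) and `edges` (set_a, set_b, overlap, p_value).
#' @export
overlap_network <- function(enriched, collection, universe,
                            edge_p_threshold = 1e-10) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (nrow(enriched) < 1) stop("need at least one enriched set")
  universe <- unique(as.character(universe))
  nu <- length(universe)
  sets <- lapply(collection[enriched$set_name], intersect, y = universe)
  nodes <- data.frame(set_name = enriched$set_name,
                      n_genes = lengths(sets),
                      overlap = enriched$overlap,
                      enrichment_p = enriched$p_value,
                      stringsAsFactors = FALSE)
  edges <- data.frame(set_a = character(), set_b = character(),
                      overlap = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  nm <- names(sets)
  if (length(sets) >= 2) {
    pairs <- utils::combn(seq_along(sets), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(q) {
      i <- pairs[1, q]; j <- pairs[2, q]
      k <- length(intersect(sets[[i]], sets[[j]]))
      p <- stats::phyper(k - 1, length(sets[[i]]), nu - length(sets[[i]]),
                         length(sets[[j]]), lower.tail = FALSE)
      if (p < edge_p_threshold)
        data.frame(set_a = nm[i], set_b = nm[j], overlap = k, p_value = p,
                   stringsAsFactors = FALSE)
      else NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  structure(list(nodes = nodes, edges = edges,
                 edge_p_threshold = edge_p_threshold),
            class = "EnrichmentNetwork")
}

#' @export
print.EnrichmentNetwork <- function(x, ...) {
  cat(sprintf("EnrichmentNetwork: %d nodes, %d edges (edge p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$edge_p_threshold))
  invisible(x)
}

#' Export an enrichment network as SIF plus attribute tables
#'
#' Writes `<prefix>.sif` (`A pp B`), `<prefix>_edges.tsv` (overlap, p) and
#' `<prefix>_nodes.tsv` (set size, enrichment p), consumable by standard
#' graph viewers.
#'
#' @param network an `EnrichmentNetwork`.
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "EnrichmentNetwork"))
  sif <- paste0(prefix, ".sif")
  if (nrow(network$edges)) {
    writeLines(paste(network$edges$set_a, "pp", network$edges$set_b), sif)
  } else {
    writeLines(network$nodes$set_name, sif)
  }
  ep <- paste0(prefix, "_edges.tsv")
  np <- paste0(prefix, "_nodes.tsv")
  utils::write.table(network$edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, ep, np))
}
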