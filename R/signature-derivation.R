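#' Signal-to-noise ratio differential-expression statistic
#'
#' For each gene, SNR = (mean_a - mean_b) / (sd_a + sd_b), with each group
#' standard deviation floored at max(0.2 * |group mean|, 1e-8) — the
#' convention of the desktop GSEA tool from which the metric originates. The
#' floor matters mainly for raw-intensity-scale data; on centred log-scale
#' data it is near-inert. The statistic is exactly antisymmetric under group
#' swap.
#'
#' @param x an `ExpressionMatrix`.
#' @param group_a,group_b disjoint character vectors of sample ids, each with
#'   at least 2 samples.
#' @param sd_floor apply the 0.2 * |mean| floor (default `TRUE`).
#' @param unbiased use the n-1 (sample) standard deviation (default `TRUE`);
#'   `FALSE` uses the population (n) denominator.
#' @return a `data.frame` of class `snr_table` with columns `gene_id`, `snr`,
#'   `mean_a`, `mean_b`, in matrix gene order.
#' @export
compute_snr <- function(x, group_a, group_b, sd_floor = TRUE, unbiased = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  unknown <- setdiff(c(group_a, group_b), sample_ids(x))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples (sd undefined otherwise)")
  grp_stats <- function(ids) {
    v <- x$values[, ids, drop = FALSE]
    n <- length(ids)
    m <- rowMeans(v)
    ss <- rowSums(v * v) - n * m * m
    ss[ss < 0] <- 0  # guard against negative rounding residue
    s <- sqrt(ss / (if (unbiased) n - 1 else n))
    if (sd_floor) s <- pmax(s, 0.2 * abs(m))
    s <- pmax(s, 1e-8)
    list(mean = m, sd = s)
  }
  a <- grp_stats(group_a); b <- grp_stats(group_b)
  structure(data.frame(gene_id = gene_ids(x),
                       snr = (a$mean - b$mean) / (a$sd + b$sd),
                       mean_a = a$mean, mean_b = b$mean,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("snr_table", "data.frame"))
}

#' Derive an up/down signature pair from a sorted-cell experiment
#'
#' Up genes are those whose pooled SNR (all positive arms vs all negative
#' arms, across cell lines) exceeds `up_threshold` AND whose mean difference
#' is positive in every cell line separately (the "commonly upregulated"
#' condition); down genes are the mirror image under `down_threshold`. Both
#' conjuncts are switchable. The resulting lists are disjoint by construction
#' and ordered by decreasing |SNR| (ties broken by gene id).
#'
#' @param x an `ExpressionMatrix` whose annotations contain the two keys.
#' @param status_key annotation column with the sort status.
#' @param cell_line_key annotation column with the cell line.
#' @param up_threshold,down_threshold SNR thresholds (defaults +1, -1).
#' @param positive_level value of `status_key` marking the positive fraction
#'   (default `"pos"`; all other values form the negative fraction).
#' @param require_consistency require the per-cell-line sign condition
#'   (default `TRUE`).
#' @param sd_floor,unbiased passed to [compute_snr()].
#' @param name signature name (default `"CD133"`).
#' @return an object of class `SignaturePair`: list with `name`, `up_genes`,
#'   `down_genes`, the thresholds, `provenance`, and the pooled `snr_table`.
#' @export
derive_signature <- function(x, status_key = "cd133_status",
                             cell_line_key = "cell_line",
                             up_threshold = 1, down_threshold = -1,
                             positive_level = "pos",
                             require_consistency = TRUE,
                             sd_floor = TRUE, unbiased = TRUE,
                             name = "CD133") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (up_threshold <= down_threshold)
    stop("`up_threshold` must exceed `down_threshold`")
  ann <- x$annotations
  for (key in c(status_key, cell_line_key))
    if (is.null(ann) || !key %in% colnames(ann))
      stop("annotation key '", key, "' not found")
  status <- ifelse(ann[[status_key]] == positive_level, "pos", "neg")
  lines <- as.character(ann[[cell_line_key]])
  for (cl in unique(lines)) {
    arms <- unique(status[lines == cl])
    if (!all(c("pos", "neg") %in% arms))
      stop("cell line '", cl, "' is missing a sort arm")
  }
  pos <- sample_ids(x)[status == "pos"]
  neg <- sample_ids(x)[status == "neg"]
  snr <- compute_snr(x, pos, neg, sd_floor = sd_floor, unbiased = unbiased)

  diffs <- vapply(unique(lines), function(cl) {
    p <- sample_ids(x)[status == "pos" & lines == cl]
    n <- sample_ids(x)[status == "neg" & lines == cl]
    rowMeans(x$values[, p, drop = FALSE]) - rowMeans(x$values[, n, drop = FALSE])
  }, numeric(nrow(x$values)))
  diffs <- matrix(diffs, nrow = nrow(x$values))
  all_pos <- apply(diffs > 0, 1L, all)
  all_neg <- apply(diffs < 0, 1L, all)
  if (!require_consistency) all_pos <- all_neg <- rep(TRUE, nrow(snr))

  pick <- function(keep, decreasing) {
    g <- snr$gene_id[keep]
    s <- snr$snr[keep]
    g[order(if (decreasing) -s else s, g, method = "radix")]
  }
  up <- pick(snr$snr > up_threshold & all_pos, decreasing = TRUE)
  down <- pick(snr$snr < down_threshold & all_neg, decreasing = FALSE)
  structure(list(name = name, up_genes = up, down_genes = down,
                 up_threshold = up_threshold, down_threshold = down_threshold,
                 provenance = sprintf(
                   "pooled SNR (%s sd%s) thresholds (%g, %g), consistency=%s, %d cell lines",
                   if (unbiased) "n-1" else "n",
                   if (sd_floor) ", 0.2|mean| floor" else "",
                   up_threshold, down_threshold, require_consistency,
                   length(unique(lines))),
                 snr_table = snr),
            class = "SignaturePair")
}

#' @export
print.SignaturePair <- function(x, ...) {
  cat(sprintf("SignaturePair '%s': %d up, %d down (SNR > %g / < %g)\n",
              x$name, length(x$up_genes), length(x$down_genes),
              x$up_threshold, x$down_threshold))
  invisible(x)
}

#' Convert a signature pair to a two-set collection
#'
#' @param pair a `SignaturePair`.
#' @return a [gene_set_collection()] with sets `<name>-up` and `<name>-down`
#'   (empty halves are dropped).
#' @export
signature_collection <- function(pair) {
  stopifnot(inherits(pair, "SignaturePair"))
  sets <- list(pair$up_genes, pair$down_genes)
  names(sets) <- paste0(pair$name, c("-up", "-down"))
  gene_set_collection(sets[lengths(sets) > 0])
}

#' Select the most variable genes
#'
#' @param x an `ExpressionMatrix`.
#' @param n number of genes to keep (<= gene count).
#' @param statistic `"mad"` (median absolute deviation) or `"variance"`.
#' @return character vector of `n` gene ids sorted by the statistic
#'   descending, ties broken lexicographically by gene id, so the result for
#'   `n` is always a prefix of the result for `n + 1`.
#' @export
select_top_variable <- function(x, n, statistic = c("mad", "variance")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  statistic <- match.arg(statistic)
  if (n > nrow(x$values)) stop("`n` exceeds the gene count")
  stat <- switch(statistic,
                 mad = apply(x$values, 1L, stats::mad),
                 variance = apply(x$values, 1L, stats::var))
  g <- gene_ids(x)
  g[order(-stat, g, method = "radix")][seq_len(n)]
}

#' Reduce signatures to a core gene list
#'
#' Genes appearing in at least `min_count` of the input lists (each list
#' counted as a set: a gene counts once per list even if duplicated),
#' returned sorted lexicographically.
#'
#' @param signatures list of >= 2 gene-id vectors.
#' @param min_count minimum number of lists a gene must appear in (>= 2).
#' @return character vector of core gene ids.
#' @export
build_core_signature <- function(signatures, min_count = 2) {
  if (!is.list(signatures) || length(signatures) < 2)
    stop("need at least 2 input gene lists")
  if (min_count < 2) stop("`min_count` must be >= 2")
  if (min_count > length(signatures))
    stop("`min_count` exceeds the number of lists")
  counts <- table(unlist(lapply(signatures, function(g) unique(as.character(g)))))
  core <- names(counts)[counts >= min_count]
  core[order(core, method = "radix")]
}

#' Hierarchical clustering of matrix rows
#'
#' @param m numeric matrix; rows are the items to cluster (>= 2).
#' @param distance `"correlation"` (1 - Pearson r) or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @param k optional number of clusters to cut into.
#' @return list with `hclust` (the merge tree) and `labels` (integer cluster
#'   labels if `k` was given, else `NULL`).
#' @export
hierarchical_cluster <- function(m, distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete"), k = NULL) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 items to cluster")
  if (is.null(rownames(m))) rownames(m) <- sprintf("item%d", seq_len(nrow(m)))
  if (distance == "correlation") {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance item(s) under correlation distance: ",
           paste(rownames(m)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m)
  }
  fit <- stats::hclust(d, method = linkage)
  list(hclust = fit,
       labels = if (is.null(k)) NULL else stats::cutree(fit, k = k))
}
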