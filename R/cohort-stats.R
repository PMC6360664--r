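#' Pairwise correlation structure of signature scores
#'
#' Computes the signature x signature correlation matrix of a `ScoreMatrix`
#' and clusters the signatures hierarchically under correlation distance
#' (1 - Pearson r of the score rows) — the standard view of how signature
#' families (stemness/proliferation vs stromal/immune) group in a cohort.
#'
#' @param scores a `ScoreMatrix` with >= 2 signatures and >= 3 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param k number of clusters to cut the signature dendrogram into
#'   (default 2).
#' @return list with `correlation` (symmetric, unit-diagonal matrix),
#'   `clustering` (see [hierarchical_cluster()]), `method`.
#' @export
correlate_scores <- function(scores, method = c("pearson", "spearman"), k = 2) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  method <- match.arg(method)
  m <- scores$scores
  if (nrow(m) < 2) stop("need >= 2 signatures")
  if (ncol(m) < 3) stop("need >= 3 samples")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance signature row(s): ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  cc <- stats::cor(t(m), method = method)
  list(correlation = cc,
       clustering = hierarchical_cluster(m, distance = "correlation",
                                         linkage = "average", k = k),
       method = method)
}

#' Gene-membership overlap of two signatures
#'
#' @param sig_a,sig_b non-empty gene-id vectors (treated as sets).
#' @return list with `overlap` (intersection count) and `jaccard`.
#' @export
signature_gene_overlap <- function(sig_a, sig_b) {
  sig_a <- unique(as.character(sig_a)); sig_b <- unique(as.character(sig_b))
  if (!length(sig_a) || !length(sig_b)) stop("empty input gene list")
  ov <- length(intersect(sig_a, sig_b))
  list(overlap = ov, jaccard = ov / length(union(sig_a, sig_b)))
}

#' Associate a per-sample score with a clinical feature
#'
#' Test dispatch by feature type: 2-level categorical features get a Welch
#' two-sample t-test (pooled-variance available via `test = "t_pooled"`),
#' categorical features with >= 3 levels a one-way ANOVA (Kruskal-Wallis via
#' `test = "kruskal"`), continuous features a Pearson correlation test. All
#' tests are two-sided. Samples with a missing feature value are dropped and
#' counted.
#'
#' @param score named numeric vector of per-sample scores (names = sample ids).
#' @param clinical a [cohort_clinical()].
#' @param feature feature (column) name.
#' @param test `"auto"` (dispatch by type) or one of `"t"`, `"t_pooled"`,
#'   `"anova"`, `"kruskal"`, `"pearson"`, `"spearman"`.
#' @return `data.frame` of class `association_result` with `feature_name`,
#'   `test_name`, `statistic`, `p_value`, `n`, `n_dropped`, plus a
#'   `group_summaries` attribute (per-level mean/median for categorical
#'   features).
#' @export
associate_feature <- function(score, clinical, feature, test = "auto") {
  stopifnot(inherits(clinical, "CohortClinical"))
  if (!feature %in% colnames(clinical)) stop("feature '", feature, "' not found")
  test <- match.arg(test, c("auto", "t", "t_pooled", "anova", "kruskal",
                            "pearson", "spearman"))
  ids <- as.character(clinical[[attr(clinical, "sample_col")]])
  common <- intersect(names(score), ids)
  f <- clinical[[feature]][match(common, ids)]
  s <- score[common]
  ok <- !is.na(f) & !is.na(s)
  n_dropped <- sum(!ok)
  f <- f[ok]; s <- s[ok]
  if (length(s) < 3) stop("fewer than 3 paired non-missing observations")
  types <- attr(clinical, "feature_types")
  categorical <- identical(unname(types[feature]), "categorical") ||
    is.character(f) || is.factor(f)
  if (length(unique(f)) < 2) stop("feature '", feature, "' is constant")

  summaries <- NULL
  if (categorical || test %in% c("t", "t_pooled", "anova", "kruskal")) {
    f <- factor(f)
    if (any(table(f) < 2))
      stop("every level of '", feature, "' needs >= 2 samples")
    summaries <- do.call(rbind, lapply(levels(f), function(l) {
      data.frame(level = l, n = sum(f == l), mean = mean(s[f == l]),
                 median = stats::median(s[f == l]), stringsAsFactors = FALSE)
    }))
    if (test == "auto") test <- if (nlevels(f) == 2) "t" else "anova"
  } else if (test == "auto") test <- "pearson"

  res <- switch(test,
    t = {
      h <- stats::t.test(s ~ f)
      c("two-group location test (Welch t)", unname(h$statistic), h$p.value)
    },
    t_pooled = {
      h <- stats::t.test(s ~ f, var.equal = TRUE)
      c("two-group location test (pooled t)", unname(h$statistic), h$p.value)
    },
    anova = {
      h <- summary(stats::aov(s ~ f))[[1]]
      c("multi-group location test (ANOVA)", h[["F value"]][1], h[["Pr(>F)"]][1])
    },
    kruskal = {
      h <- stats::kruskal.test(s, f)
      c("multi-group location test (Kruskal-Wallis)", unname(h$statistic), h$p.value)
    },
    pearson = {
      h <- stats::cor.test(s, as.numeric(f), method = "pearson")
      c("correlation test (Pearson)", unname(h$estimate), h$p.value)
    },
    spearman = {
      h <- suppressWarnings(stats::cor.test(s, as.numeric(f), method = "spearman"))
      c("correlation test (Spearman)", unname(h$estimate), h$p.value)
    })
  out <- data.frame(feature_name = feature, test_name = res[1],
                    statistic = as.numeric(res[2]), p_value = as.numeric(res[3]),
                    n = length(s), n_dropped = n_dropped,
                    stringsAsFactors = FALSE)
  attr(out, "group_summaries") <- summaries
  structure(out, class = c("association_result", "data.frame"))
}

#' kNN leave-one-out cross-validation of a two-class label
#'
#' Each sample is predicted by the majority label of its `k` nearest
#' neighbors among all other samples. Distance ties are broken by the
#' smaller sample index; a tied vote falls back to the class of the single
#' nearest neighbor. Deterministic by construction.
#'
#' @param x an `ExpressionMatrix` (or numeric genes x samples matrix).
#' @param labels two-class labels: either an annotation column name or a
#'   vector of length `n`.
#' @param k neighbor count (< n; default 3).
#' @param distance `"euclidean-zscored"` (Euclidean on per-gene z-scored
#'   values) or `"correlation"` (1 - Pearson r between sample profiles).
#' @param genes optional gene subset used for the distance.
#' @return list with `accuracy` and a `predictions` data frame
#'   (sample_id, truth, predicted, correct).
#' @export
knn_loocv <- function(x, labels, k = 3,
                      distance = c("euclidean-zscored", "correlation"),
                      genes = NULL) {
  distance <- match.arg(distance)
  if (inherits(x, "ExpressionMatrix")) {
    if (is.character(labels) && length(labels) == 1) {
      if (is.null(x$annotations) || !labels %in% colnames(x$annotations))
        stop("annotation key '", labels, "' not found")
      labels <- x$annotations[[labels]]
    }
    v <- x$values
  } else v <- as.matrix(x)
  n <- ncol(v)
  if (n < 3) stop("need >= 3 samples")
  if (k >= n) stop("`k` must be smaller than the sample count")
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required")
  if (length(unique(labels)) != 2) stop("exactly two classes required")
  if (!is.null(genes)) v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  if (distance == "euclidean-zscored") {
    sds <- apply(v, 1L, stats::sd)
    z <- (v - rowMeans(v)) / ifelse(sds > 0, sds, 1)
    d <- as.matrix(stats::dist(t(z)))
  } else {
    d <- 1 - stats::cor(v)
  }
  pred <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(d[i, others], others, method = "radix")]
    nb <- labels[ord[seq_len(k)]]
    tab <- table(nb)
    if (length(tab) == 2 && tab[1] == tab[2]) nb[1]
    else names(tab)[which.max(tab)]
  }, character(1L))
  predictions <- data.frame(sample_id = colnames(v), truth = labels,
                            predicted = pred, correct = pred == labels,
                            stringsAsFactors = FALSE)
  list(accuracy = mean(predictions$correct), predictions = predictions)
}
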