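#' Validate a pipeline configuration
#'
#' A configuration is a named list (or path to a YAML file) with entries:
#' \describe{
#'   \item{sorted_expression}{path to the sorted-cell expression TSV}
#'   \item{cohort_expression}{path to the cohort expression TSV}
#'   \item{cohort_clinical}{optional path to the clinical TSV (with `time`
#'     and `event` columns for the survival stage)}
#'   \item{gene_sets}{optional path to a GMT collection to score alongside
#'     the derived signature and to enrich against}
#'   \item{status_key, cell_line_key}{annotation keys of the sorted design
#'     (defaults `"cd133_status"`, `"cell_line"`)}
#'   \item{up_threshold, down_threshold}{SNR thresholds (defaults +1, -1)}
#'   \item{enrichment_p, edge_p}{enrichment-map thresholds (defaults 0.01,
#'     1e-10)}
#'   \item{core_min_count}{core-signature membership count (default 2)}
#'   \item{alpha, normalize}{ssGSEA exponent and normalization (defaults
#'     0.25, `"none"`)}
#'   \item{features}{clinical feature names to associate with the up-signature
#'     score (default: all typed features)}
#'   \item{km_split}{survival split rule, `"median"` or `"quantile"`}
#'   \item{seed}{integer seed (default 1)}
#' }
#'
#' @param config named list or YAML path.
#' @return the validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  defaults <- list(status_key = "cd133_status", cell_line_key = "cell_line",
                   up_threshold = 1, down_threshold = -1,
                   enrichment_p = 0.01, edge_p = 1e-10, core_min_count = 2,
                   alpha = 0.25, normalize = "none", features = NULL,
                   km_split = "median", seed = 1L,
                   cohort_clinical = NULL, gene_sets = NULL)
  config <- utils::modifyList(defaults, config)
  for (key in c("sorted_expression", "cohort_expression"))
    if (is.null(config[[key]])) stop("config entry '", key, "' is required")
  for (key in c("sorted_expression", "cohort_expression", "cohort_clinical",
                "gene_sets"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("config path '", key, "' does not exist: ", config[[key]])
  if (config$up_threshold <= config$down_threshold)
    stop("up_threshold must exceed down_threshold")
  if (config$alpha < 0) stop("alpha must be >= 0")
  if (!config$normalize %in% c("none", "minmax"))
    stop("normalize must be 'none' or 'minmax'")
  if (!config$km_split %in% c("median", "quantile"))
    stop("km_split must be 'median' or 'quantile'")
  structure(config, class = c("pipeline_config", "list"))
}

# deterministic 32-bit polynomial rolling hash of the deparsed config
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Run the end-to-end signature analysis pipeline
#'
#' Orchestrates derive -> score -> correlate -> associate -> enrich ->
#' survive from a single validated config, writing every stage output plus a
#' provenance log (config hash, package version, per-stage counts) to
#' `out_dir`. Rerunning with an identical config and inputs is bit-identical.
#' A stage error aborts with the stage name; outputs of completed stages are
#' preserved.
#'
#' @param config a [pipeline_config()] (or list/YAML path coercible to one).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory stage results: `signature`,
#'   `scores`, `correlation`, `associations`, `network`, `survival`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))
  log_lines <- c(sprintf("stemsig %s", as.character(utils::packageVersion("stemsig"))),
                 sprintf("config_hash %s", config_hash(config)))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "provenance.txt"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sorted <- stage("read_sorted", read_expression_table(config$sorted_expression))
  note("read_sorted genes=%d samples=%d", nrow(sorted$values), ncol(sorted$values))
  # the sorted reader cannot know the design; annotations come from the
  # sample-id convention of the synthetic generator (<line>_<status>_r<rep>)
  if (is.null(sorted$annotations)) {
    parts <- strsplit(sample_ids(sorted), "_", fixed = TRUE)
    if (all(lengths(parts) == 3L)) {
      ann <- data.frame(cell_line = vapply(parts, `[[`, "", 1L),
                        cd133_status = vapply(parts, `[[`, "", 2L),
                        row.names = sample_ids(sorted),
                        stringsAsFactors = FALSE)
      sorted <- expression_matrix(sorted$values, annotations = ann)
    }
  }

  signature <- stage("derive", derive_signature(
    sorted, status_key = config$status_key, cell_line_key = config$cell_line_key,
    up_threshold = config$up_threshold, down_threshold = config$down_threshold))
  note("derive up=%d down=%d", length(signature$up_genes),
       length(signature$down_genes))
  sig_coll <- signature_collection(signature)
  write_gmt(sig_coll, file.path(out_dir, "signature.gmt"))

  cohort <- stage("read_cohort", read_expression_table(config$cohort_expression))
  note("read_cohort genes=%d samples=%d", nrow(cohort$values), ncol(cohort$values))

  extra <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets) else NULL
  all_sets <- if (is.null(extra)) sig_coll else
    gene_set_collection(c(unclass(sig_coll)[seq_along(sig_coll)], unclass(extra)[seq_along(extra)]))
  scores <- stage("score", score_collection(cohort, all_sets,
                                            alpha = config$alpha,
                                            normalize = config$normalize))
  note("score signatures=%d skipped=%d", nrow(scores$scores),
       length(scores$skipped))
  write_scores(scores, file.path(out_dir, "scores.tsv"))

  correlation <- NULL
  if (nrow(scores$scores) >= 2) {
    correlation <- stage("correlate", correlate_scores(scores))
    utils::write.table(correlation$correlation,
                       file.path(out_dir, "score_correlation.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    note("correlate signatures=%d", nrow(correlation$correlation))
  }

  network <- NULL
  if (!is.null(extra)) {
    universe <- intersect(gene_ids(sorted),
                          unique(unlist(extra[seq_along(extra)])))
    if (length(universe) && all(signature$up_genes %in% universe)) {
      enriched <- stage("enrich", fisher_enrichment(
        signature$up_genes, extra, universe, p_threshold = config$enrichment_p))
      note("enrich sets_tested=%d enriched=%d", length(extra), nrow(enriched))
      if (nrow(enriched)) {
        network <- stage("map", overlap_network(enriched, extra, universe,
                                                edge_p_threshold = config$edge_p))
        write_network(network, file.path(out_dir, "enrichment_map"))
        note("map nodes=%d edges=%d", nrow(network$nodes), nrow(network$edges))
      }
    } else note("enrich skipped (universe does not cover the signature)")
  }

  associations <- NULL
  surv <- NULL
  if (!is.null(config$cohort_clinical)) {
    clinical <- stage("read_clinical", read_clinical_table(
      config$cohort_clinical,
      time_col = if ("time" %in% colnames(utils::read.delim(config$cohort_clinical, nrows = 1)))
        "time" else NULL,
      event_col = if ("event" %in% colnames(utils::read.delim(config$cohort_clinical, nrows = 1)))
        "event" else NULL))
    up_row <- paste0(signature$name, "-up")
    up_score <- scores$scores[up_row, ]
    feats <- config$features
    if (is.null(feats)) feats <- names(attr(clinical, "feature_types"))
    assoc_rows <- lapply(feats, function(f) {
      tryCatch(associate_feature(up_score, clinical, f),
               error = function(e) { note("associate %s skipped: %s", f,
                                          conditionMessage(e)); NULL })
    })
    assoc_rows <- assoc_rows[!vapply(assoc_rows, is.null, logical(1L))]
    if (length(assoc_rows)) {
      associations <- do.call(rbind, assoc_rows)
      utils::write.table(associations, file.path(out_dir, "associations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("associate features=%d", nrow(associations))
    }
    if (!is.null(attr(clinical, "time_col"))) {
      ids <- as.character(clinical[[attr(clinical, "sample_col")]])
      common <- intersect(names(up_score), ids)
      idx <- match(common, ids)
      grp <- stage("survive", dichotomize(up_score[common], rule = config$km_split))
      km <- stage("survive", km_logrank(clinical[[attr(clinical, "time_col")]][idx],
                                        clinical[[attr(clinical, "event_col")]][idx],
                                        grp))
      surv <- data.frame(analysis = "km_logrank",
                         group_rule = config$km_split,
                         cutoff = attr(grp, "cutoff"),
                         chisq = km$chisq, p_value = km$p_value,
                         n = km$n, n_events = km$n_events)
      utils::write.table(surv, file.path(out_dir, "survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("survive logrank_p=%.4g", km$p_value)
    }
  }

  writeLines(log_lines, file.path(out_dir, "provenance.txt"))
  invisible(list(signature = signature, scores = scores,
                 correlation = correlation, associations = associations,
                 network = network, survival = surv,
                 provenance = log_lines))
}
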