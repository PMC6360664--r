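#' Construct a cohort clinical table
#'
#' Per-sample clinical covariates with optional survival time and event
#' columns. Event must be coded 0 (censored) / 1 (death observed); times must
#' be positive. Feature typing (categorical vs continuous) is inferred from
#' the column class and can be overridden with `categorical`.
#'
#' @param data a `data.frame` with one row per sample.
#' @param sample_col name of the sample-id column (ids matched
#'   case-sensitively to expression sample ids downstream).
#' @param time_col,event_col optional names of the survival columns.
#' @param categorical optional character vector of feature names to force to
#'   categorical regardless of column class.
#' @return the data frame with class `CohortClinical` and typing attributes.
#' @export
cohort_clinical <- function(data, sample_col = "sample_id",
                            time_col = NULL, event_col = NULL,
                            categorical = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!sample_col %in% colnames(data))
    stop("sample-id column '", sample_col, "' not found")
  ids <- as.character(data[[sample_col]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (xor(is.null(time_col), is.null(event_col)))
    stop("`time_col` and `event_col` must be given together")
  if (!is.null(time_col)) {
    for (cc in c(time_col, event_col))
      if (!cc %in% colnames(data)) stop("column '", cc, "' not found")
    tm <- data[[time_col]]
    if (!is.numeric(tm)) stop("survival time column must be numeric")
    if (any(tm < 0)) stop("negative survival time in column '", time_col, "'")
    ev <- data[[event_col]]
    if (!is.numeric(ev) || !all(ev %in% c(0, 1)))
      stop("event column '", event_col,
           "' must be coded 0 (censored) / 1 (event); recode it numerically")
  }
  feat <- setdiff(colnames(data), c(sample_col, time_col, event_col))
  types <- vapply(feat, function(f) {
    if (f %in% categorical || is.character(data[[f]]) ||
        is.factor(data[[f]]) || is.logical(data[[f]])) "categorical"
    else "continuous"
  }, character(1L))
  structure(data, class = c("CohortClinical", "data.frame"),
            sample_col = sample_col, time_col = time_col,
            event_col = event_col, feature_types = types)
}

#' Read a clinical table from TSV
#'
#' @inheritParams cohort_clinical
#' @param path path to a tab-delimited table with a header row.
#' @return a [cohort_clinical()].
#' @export
read_clinical_table <- function(path, sample_col = "sample_id",
                                time_col = NULL, event_col = NULL,
                                categorical = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  cohort_clinical(tab, sample_col = sample_col, time_col = time_col,
                  event_col = event_col, categorical = categorical)
}

#' @export
print.CohortClinical <- function(x, ...) {
  cat(sprintf("CohortClinical: %d samples, %d features%s\n", nrow(x),
              length(attr(x, "feature_types")),
              if (is.null(attr(x, "time_col"))) "" else ", survival present"))
  NextMethod()
}
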