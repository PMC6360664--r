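#' Dichotomize per-sample scores into high/low groups
#'
#' @param scores numeric vector (>= 2 samples, not all equal).
#' @param rule `"median"` or `"quantile"`.
#' @param q quantile for `rule = "quantile"` (default 0.5, which equals the
#'   median rule).
#' @return factor with levels `c("low", "high")`; `high` is score > cutoff,
#'   `low` is score <= cutoff. The cutoff is attached as attribute `cutoff`.
#' @export
dichotomize <- function(scores, rule = c("median", "quantile"), q = 0.5) {
  rule <- match.arg(rule)
  if (length(scores) < 2) stop("need >= 2 samples")
  if (max(scores) == min(scores)) stop("all scores equal: no split possible")
  cutoff <- if (rule == "median") stats::median(scores)
            else stats::quantile(scores, q, names = FALSE)
  g <- factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
  if (any(table(g) == 0))
    stop("cutoff ", signif(cutoff, 6), " produces an empty group")
  attr(g, "cutoff") <- cutoff
  g
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimate per group and the two-group log-rank
#' statistic (observed minus expected event counts with hypergeometric
#' variance summed over distinct event times), with p from a chi-square on
#' 1 degree of freedom.
#'
#' @param time positive survival times.
#' @param event event indicator, 1 = death observed, 0 = censored.
#' @param groups two-level factor or vector of group labels; both groups
#'   must contain at least one event.
#' @return list of class `km_logrank` with `fit` (a [survival::survfit()]
#'   object), `chisq`, `p_value`, `n`, `n_events`.
#' @export
km_logrank <- function(time, event, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  stopifnot(length(time) == length(event), length(time) == length(groups))
  if (!all(event %in% c(0, 1))) stop("event must be coded 0/1")
  ev_per_group <- tapply(event, groups, sum)
  if (any(ev_per_group == 0))
    stop("group '", names(ev_per_group)[ev_per_group == 0][1],
         "' has zero events; merge groups or revisit the split")
  df <- data.frame(time = time, event = event, g = groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  chisq <- unname(sd_$chisq)
  structure(list(
    fit = survival::survfit(survival::Surv(time, event) ~ g, data = df),
    chisq = chisq,
    p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    n = length(time), n_events = sum(event)
  ), class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.4g, p = %.4g (n = %d, events = %d)\n",
              x$chisq, x$p_value, x$n, x$n_events))
  invisible(x)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron tie handling. With
#' `standardize = TRUE` (default) covariates are z-scored first, so hazard
#' ratios are per standard deviation and the fit is invariant to affine
#' rescaling of the inputs — which is what makes per-sample enrichment-score
#' normalization choices immaterial to the survival conclusions.
#'
#' @param time positive survival times.
#' @param event 0/1 event indicators.
#' @param covariates data frame or matrix of numeric covariates (one column
#'   per covariate); no constant columns.
#' @param standardize z-score covariates (default `TRUE`).
#' @return object of class `cox_fit`: list with `table` (per covariate:
#'   coefficient, hazard_ratio, se, z, p_value, ci_lower, ci_upper), `n`,
#'   `n_events`, `tie_method`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(time, event, covariates, standardize = TRUE) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(time) == length(event), nrow(covariates) == length(time))
  if (!all(event %in% c(0, 1))) stop("event must be coded 0/1")
  if (!all(vapply(covariates, is.numeric, logical(1L))))
    stop("all covariates must be numeric")
  sds <- vapply(covariates, stats::sd, numeric(1L))
  if (any(sds == 0))
    stop("constant covariate(s): ",
         paste(colnames(covariates)[sds == 0], collapse = ", "))
  if (standardize) covariates[] <- scale(covariates)
  nev <- sum(event)
  if (nev < 10 * ncol(covariates))
    warning(sprintf("only %d events for %d covariate(s); estimates may be unstable",
                    nev, ncol(covariates)))
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", colnames(covariates)),
                                       collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|Ran out of iterations", conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  tab <- data.frame(covariate = colnames(covariates),
                    coefficient = unname(stats::coef(fit)),
                    hazard_ratio = unname(exp(stats::coef(fit))),
                    se = sm$coefficients[, "se(coef)"],
                    z = sm$coefficients[, "z"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    ci_lower = sm$conf.int[, "lower .95"],
                    ci_upper = sm$conf.int[, "upper .95"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n = length(time), n_events = nev,
                 tie_method = "efron", coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties): n = %d, events = %d\n", x$n, x$n_events))
  print(x$table, digits = 4)
  invisible(x)
}

#' Per-tumor-type multivariate Cox fits of signature scores
#'
#' Fits the same multivariate Cox model (the named score rows as covariates,
#' per-SD hazard ratios) independently in every cohort; cohorts whose fit
#' fails (constant covariate, separation, too few events) are skipped with a
#' logged reason rather than aborting the table.
#'
#' @param cohorts named list; each element a list with `scores` (a
#'   `ScoreMatrix`) and `clinical` (a [cohort_clinical()] with survival
#'   columns).
#' @param covariate_names signature (score row) names to use as covariates.
#' @param p_threshold significance flag threshold (default 0.05).
#' @return list with `table` (one row per cohort x covariate: cohort,
#'   covariate, coefficient, hazard_ratio, ci, p_value, significant, n,
#'   n_events) and `skipped` (named character vector of failure reasons).
#' @export
pan_cohort_cox <- function(cohorts, covariate_names, p_threshold = 0.05) {
  if (!length(cohorts)) stop("empty cohort map")
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    stop("cohorts must be named by tumor type")
  rows <- list(); skipped <- character()
  for (ct in names(cohorts)) {
    co <- cohorts[[ct]]
    res <- tryCatch({
      stopifnot(inherits(co$scores, "ScoreMatrix"),
                inherits(co$clinical, "CohortClinical"))
      clin <- co$clinical
      tc <- attr(clin, "time_col"); ec <- attr(clin, "event_col")
      if (is.null(tc)) stop("no survival columns")
      ids <- as.character(clin[[attr(clin, "sample_col")]])
      common <- intersect(colnames(co$scores$scores), ids)
      miss <- setdiff(covariate_names, rownames(co$scores$scores))
      if (length(miss)) stop("missing score row(s): ", paste(miss, collapse = ", "))
      covs <- as.data.frame(t(co$scores$scores[covariate_names, common,
                                               drop = FALSE]))
      idx <- match(common, ids)
      fit <- cox_fit(clin[[tc]][idx], clin[[ec]][idx], covs, standardize = TRUE)
      cbind(cohort = ct, fit$table,
            significant = fit$table$p_value < p_threshold,
            n = fit$n, n_events = fit$n_events)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) skipped[ct] <- res else rows[[ct]] <- res
  }
  if (!length(rows))
    stop("all cohorts failed: ",
         paste(sprintf("%s (%s)", names(skipped), skipped), collapse = "; "))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, skipped = skipped)
}
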