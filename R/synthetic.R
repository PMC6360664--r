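#' Ground truth for a synthetic sorted-cell experiment
#'
#' Describes a marker-sorted cell-line experiment: `n_cell_lines` cell lines,
#' each separated into marker-positive and marker-negative fractions with
#' `replicates_per_arm` profiles per fraction. Expression is generated on a
#' median-centred log2-intensity scale as
#' gene baseline (N(0,1)) + per-gene cell-line batch offset (N(0, batch_sd))
#' + condition shift (+`effect_size` for planted up genes and -`effect_size`
#' for planted down genes, in positive arms only) + N(0, noise_sd) noise.
#'
#' @param n_genes total number of genes.
#' @param n_planted_up,n_planted_down numbers of genes shifted up/down in the
#'   marker-positive fraction.
#' @param effect_size condition shift in noise-sd units (default 3).
#' @param n_cell_lines number of cell lines (default 3).
#' @param replicates_per_arm profiles per sorted fraction per line (default 2).
#' @param batch_sd sd of the per-gene cell-line offsets (default 0.5).
#' @param noise_sd sd of the i.i.d. measurement noise (default 1).
#' @param seed RNG seed; the same truth always generates the same matrix.
#' @return an object of class `SortedExperimentTruth` with fields
#'   `planted_up` and `planted_down` holding the planted gene ids.
#' @export
sorted_experiment_truth <- function(n_genes = 2000, n_planted_up = 30,
                                    n_planted_down = 30, effect_size = 3,
                                    n_cell_lines = 3, replicates_per_arm = 2,
                                    batch_sd = 0.5, noise_sd = 1, seed = 1) {
  stopifnot(n_genes >= 1, n_cell_lines >= 1, replicates_per_arm >= 1,
            batch_sd >= 0, noise_sd >= 0, n_planted_up >= 0, n_planted_down >= 0)
  if (n_planted_up + n_planted_down > n_genes)
    stop("planted gene count exceeds total genes")
  genes <- sprintf("g%05d", seq_len(n_genes))
  structure(list(
    genes = genes,
    planted_up = if (n_planted_up) genes[seq_len(n_planted_up)] else character(),
    planted_down = if (n_planted_down)
      genes[n_planted_up + seq_len(n_planted_down)] else character(),
    effect_size = effect_size, n_cell_lines = n_cell_lines,
    replicates_per_arm = replicates_per_arm, batch_sd = batch_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "SortedExperimentTruth")
}

#' Simulate a sorted-cell expression experiment
#'
#' @param truth a [sorted_experiment_truth()].
#' @return a list with elements `expression` (an [expression_matrix()] whose
#'   annotations carry `cell_line` and `cd133_status` in `{"pos","neg"}`) and
#'   `truth`.
#' @export
simulate_sorted_experiment <- function(truth) {
  stopifnot(inherits(truth, "SortedExperimentTruth"))
  set.seed(truth$seed)
  ng <- length(truth$genes)
  lines <- sprintf("CL%d", seq_len(truth$n_cell_lines))
  ann <- expand.grid(replicate = seq_len(truth$replicates_per_arm),
                     cd133_status = c("pos", "neg"), cell_line = lines,
                     stringsAsFactors = FALSE)
  ann <- ann[, c("cell_line", "cd133_status", "replicate")]
  samples <- sprintf("%s_%s_r%d", ann$cell_line, ann$cd133_status, ann$replicate)
  rownames(ann) <- samples
  baseline <- stats::rnorm(ng)
  batch <- matrix(stats::rnorm(ng * truth$n_cell_lines, 0, truth$batch_sd),
                  ng, truth$n_cell_lines, dimnames = list(NULL, lines))
  shift <- numeric(ng)
  shift[match(truth$planted_up, truth$genes)] <- truth$effect_size
  shift[match(truth$planted_down, truth$genes)] <- -truth$effect_size
  values <- matrix(0, ng, nrow(ann), dimnames = list(truth$genes, samples))
  for (j in seq_len(nrow(ann))) {
    values[, j] <- baseline + batch[, ann$cell_line[j]] +
      (if (ann$cd133_status[j] == "pos") shift else 0) +
      stats::rnorm(ng, 0, truth$noise_sd)
  }
  list(expression = expression_matrix(values, annotations = ann[, 1:2]),
       truth = truth)
}

#' Ground truth for a synthetic purity-mixed tumor cohort
#'
#' Each bulk sample is an affine mixture of a tumor component and a single
#' stromal/immune component weighted by tumor purity:
#' `expr_i = purity_i * (tumor_profile + activity_i * stemness_indicator) +
#' (1 - purity_i) * stromal_profile + noise`. The tumor profile elevates the
#' stemness genes by `stemness_elevation`; the stromal profile elevates the
#' stromal marker genes by `stromal_elevation`. Purity and stemness activity
#' are drawn independently, so any anticorrelation between stemness and
#' stromal enrichment scores downstream arises purely from the mixing.
#'
#' Survival times are exponential with hazard
#' `baseline_hazard * exp(beta_stemness * z(activity) + beta_stromal *
#' z(1 - purity))` and uniform administrative censoring whose horizon is
#' solved numerically so the expected censored fraction equals `censor_rate`.
#'
#' @param n_genes total genes; the first `n_stemness` are stemness markers,
#'   the next `n_stromal` stromal markers.
#' @param n_stemness,n_stromal marker-set sizes (default 100 each).
#' @param stemness_elevation,stromal_elevation log-scale elevations of the
#'   marker genes in their own component (defaults 2 and 3).
#' @param activity_sd sd of the latent per-sample stemness activity.
#' @param purity_shape length-2 Beta shape parameters for purity
#'   (default `c(2, 2)`).
#' @param noise_sd sd of the measurement noise (default 0.3).
#' @param beta_stemness,beta_stromal log-hazard per SD of stemness activity
#'   and of (1 - purity) (defaults 0.5 and 1.0).
#' @param baseline_hazard events per time unit (default 0.1).
#' @param censor_rate expected censored fraction in [0, 1) (default 0.3).
#' @param subtype_log_odds log-odds of the "intestinal" subtype per SD of
#'   stemness activity (default 1).
#' @param mutation_burden if `TRUE`, emit a Poisson(10) mutation-count column.
#' @param tumor_profile,stromal_profile optional named per-gene mean vectors
#'   overriding the generated profiles; both must be given together over an
#'   identical gene universe, with the first `n_stemness` + `n_stromal` genes
#'   taken as the marker sets.
#' @param seed RNG seed.
#' @return an object of class `CohortTruth`.
#' @export
cohort_truth <- function(n_genes = 2000, n_stemness = 100, n_stromal = 100,
                         stemness_elevation = 2, stromal_elevation = 3,
                         activity_sd = 1, purity_shape = c(2, 2),
                         noise_sd = 0.3, beta_stemness = 0.5,
                         beta_stromal = 1.0, baseline_hazard = 0.1,
                         censor_rate = 0.3, subtype_log_odds = 1,
                         mutation_burden = FALSE,
                         tumor_profile = NULL, stromal_profile = NULL,
                         seed = 1) {
  if (!is.null(tumor_profile) || !is.null(stromal_profile)) {
    if (is.null(tumor_profile) || is.null(stromal_profile))
      stop("`tumor_profile` and `stromal_profile` must be given together")
    if (!identical(names(tumor_profile), names(stromal_profile)))
      stop("mismatched gene universes between tumor and stromal profiles")
    n_genes <- length(tumor_profile)
  }
  stopifnot(n_genes >= 1, n_stemness >= 1, n_stromal >= 1,
            n_stemness + n_stromal <= n_genes, noise_sd >= 0,
            baseline_hazard > 0, censor_rate >= 0, censor_rate < 1,
            length(purity_shape) == 2, all(purity_shape > 0))
  genes <- if (is.null(tumor_profile)) sprintf("g%05d", seq_len(n_genes))
           else names(tumor_profile)
  structure(list(
    genes = genes,
    stemness_genes = genes[seq_len(n_stemness)],
    stromal_genes = genes[n_stemness + seq_len(n_stromal)],
    stemness_elevation = stemness_elevation,
    stromal_elevation = stromal_elevation,
    activity_sd = activity_sd, purity_shape = purity_shape,
    noise_sd = noise_sd, beta_stemness = beta_stemness,
    beta_stromal = beta_stromal, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, subtype_log_odds = subtype_log_odds,
    mutation_burden = mutation_burden,
    fixed_tumor_profile = tumor_profile,
    fixed_stromal_profile = stromal_profile, seed = as.integer(seed)
  ), class = "CohortTruth")
}

# Uniform(0, tau) administrative censoring horizon giving the target expected
# censored fraction for exponential event times with rates `rates`.
censor_horizon <- function(rates, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  p_cens <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - censor_rate
  # p_cens(tau) -> 1 as tau -> 0 and -> 0 as tau -> Inf; bracket and solve
  lo <- 1e-8; hi <- 1
  while (p_cens(hi) > 0 && hi < 1e12) hi <- hi * 10
  stats::uniroot(p_cens, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a purity-mixed tumor cohort with survival
#'
#' @param truth a [cohort_truth()].
#' @param n_samples number of tumor samples (>= 1).
#' @param expression if `FALSE`, skip generating the expression matrix
#'   (clinical covariates and survival only; useful for large survival
#'   simulations).
#' @return a list with elements `expression` (an [expression_matrix()], or
#'   `NULL`), `clinical` (a [cohort_clinical()] with columns `purity`,
#'   `stemness_activity`, `subtype`, `time`, `event` and optionally
#'   `mutation_burden`) and `truth` (with realized `purity`,
#'   `stemness_activity`, `tumor_profile` and `stromal_profile` filled in).
#' @export
simulate_tumor_cohort <- function(truth, n_samples, expression = TRUE) {
  stopifnot(inherits(truth, "CohortTruth"))
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("`n_samples` must be a positive count")
  n <- as.integer(n_samples)
  set.seed(truth$seed)
  ng <- length(truth$genes)
  i_stem <- match(truth$stemness_genes, truth$genes)
  i_strom <- match(truth$stromal_genes, truth$genes)
  if (is.null(truth$fixed_tumor_profile)) {
    baseline <- stats::rnorm(ng)
    tumor_profile <- baseline
    tumor_profile[i_stem] <- tumor_profile[i_stem] + truth$stemness_elevation
    stromal_profile <- baseline
    stromal_profile[i_strom] <- stromal_profile[i_strom] + truth$stromal_elevation
  } else {
    tumor_profile <- unname(truth$fixed_tumor_profile)
    stromal_profile <- unname(truth$fixed_stromal_profile)
  }
  purity <- stats::rbeta(n, truth$purity_shape[1], truth$purity_shape[2])
  activity <- stats::rnorm(n, 0, truth$activity_sd)
  samples <- sprintf("T%04d", seq_len(n))

  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  lp <- truth$beta_stemness * zs(activity) + truth$beta_stromal * zs(1 - purity)
  rates <- truth$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rates)
  tau <- censor_horizon(rates, truth$censor_rate)
  t_cens <- if (is.finite(tau)) stats::runif(n, 0, tau) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  subtype <- ifelse(
    stats::runif(n) < stats::plogis(truth$subtype_log_odds * zs(activity)),
    "intestinal", "diffuse")
  clin <- data.frame(sample_id = samples, purity = purity,
                     stemness_activity = activity, subtype = subtype,
                     time = time, event = event, stringsAsFactors = FALSE)
  if (isTRUE(truth$mutation_burden))
    clin$mutation_burden <- stats::rpois(n, 10)
  clinical <- cohort_clinical(clin, sample_col = "sample_id",
                              time_col = "time", event_col = "event")

  expr <- NULL
  if (isTRUE(expression)) {
    stem_ind <- numeric(ng); stem_ind[i_stem] <- 1
    values <- matrix(0, ng, n, dimnames = list(truth$genes, samples))
    for (i in seq_len(n)) {
      values[, i] <- purity[i] * (tumor_profile + activity[i] * stem_ind) +
        (1 - purity[i]) * stromal_profile +
        stats::rnorm(ng, 0, truth$noise_sd)
    }
    ann <- clin[, c("purity", "subtype")]
    rownames(ann) <- samples
    expr <- expression_matrix(values, annotations = ann)
  }
  truth$purity <- purity
  truth$stemness_activity <- activity
  truth$tumor_profile <- tumor_profile
  truth$stromal_profile <- stromal_profile
  list(expression = expr, clinical = clinical, truth = truth)
}
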