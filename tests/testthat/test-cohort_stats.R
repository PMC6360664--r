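make_scorematrix <- function(m, alpha = 0.25) {
  structure(list(scores = m, alpha = alpha, normalized = FALSE,
                 skipped = character()), class = "ScoreMatrix")
}

test_that("score correlation matrix is symmetric with unit diagonal", {
  set.seed(61)
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("sig", 1:4), paste0("s", 1:10)))
  m[2, ] <- -m[1, ]                      # exact negation
  cs <- correlate_scores(make_scorematrix(m))
  expect_equal(diag(cs$correlation), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cs$correlation, t(cs$correlation), tolerance = 1e-12)
  expect_equal(cs$correlation["sig1", "sig2"], -1, tolerance = 1e-12)

  m[3, ] <- 5
  expect_error(correlate_scores(make_scorematrix(m)), "zero-variance.*sig3")
})

test_that("stemness and stromal signature families separate in the 2-cut", {
  truth <- cohort_truth(n_genes = 1500, seed = 19)
  sim <- simulate_tumor_cohort(truth, 120)
  half <- function(g) list(a = g[seq(1, length(g), 2)],
                           b = g[seq(2, length(g), 2)])
  st <- half(truth$stemness_genes); sr <- half(truth$stromal_genes)
  coll <- gene_set_collection(list(stem1 = st$a, stem2 = st$b,
                                   strom1 = sr$a, strom2 = sr$b))
  cs <- correlate_scores(score_collection(sim$expression, coll), k = 2)
  labs <- cs$clustering$labels
  expect_identical(labs[["stem1"]], labs[["stem2"]])
  expect_identical(labs[["strom1"]], labs[["strom2"]])
  expect_false(labs[["stem1"]] == labs[["strom1"]])
})

test_that("signature gene overlap follows set arithmetic", {
  expect_equal(signature_gene_overlap(c("A", "B", "C"), c("A", "B", "C")),
               list(overlap = 3L, jaccard = 1))
  expect_equal(signature_gene_overlap(c("A", "B"), c("C", "D")),
               list(overlap = 0L, jaccard = 0))
  expect_equal(signature_gene_overlap(c("A", "B", "C"), c("B", "C", "D", "E")),
               list(overlap = 2L, jaccard = 2 / 5))
  expect_error(signature_gene_overlap(character(), "A"), "empty")
})

test_that("feature association dispatches by type with sane null behavior", {
  ids <- sprintf("s%02d", 1:40)
  clin <- cohort_clinical(data.frame(
    sample_id = ids,
    grp2 = rep(c("x", "y"), 20),
    grp3 = rep(c("p", "q", "r"), length.out = 40),
    cont = seq(0, 1, length.out = 40),
    stringsAsFactors = FALSE))
  score <- setNames(rep(c(1, 2, 2, 1), 10), ids)  # same distribution in x vs y
  res <- associate_feature(score, clin, "grp2")
  expect_match(res$test_name, "Welch")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  set.seed(9)
  score2 <- setNames(rnorm(40), ids)
  expect_match(associate_feature(score2, clin, "grp3")$test_name, "ANOVA")
  expect_match(associate_feature(score2, clin, "cont")$test_name, "Pearson")
  expect_match(associate_feature(score2, clin, "grp3",
                                 test = "kruskal")$test_name, "Kruskal")
  clin_const <- cohort_clinical(data.frame(sample_id = ids, f = "same",
                                           stringsAsFactors = FALSE))
  expect_error(associate_feature(score2, clin_const, "f"), "constant")
})

test_that("two-level dispatch agrees in direction with the dummy correlation", {
  for (seed in 71:75) {
    set.seed(seed)
    ids <- sprintf("s%02d", 1:30)
    grp <- rep(c("a", "b"), 15)
    score <- setNames(rnorm(30) + (grp == "b") * rnorm(1), ids)
    clin <- cohort_clinical(data.frame(sample_id = ids, grp = grp,
                                       dummy = as.numeric(grp == "b"),
                                       stringsAsFactors = FALSE))
    t_stat <- associate_feature(score, clin, "grp")$statistic
    r_stat <- associate_feature(score, clin, "dummy")$statistic
    # Welch t is group a minus b; correlation with the b-dummy flips the sign
    expect_identical(sign(t_stat), -sign(r_stat))
  }
})

test_that("a planted 1-sd group shift is detected with high power", {
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    ids <- sprintf("s%03d", 1:200)
    grp <- rep(c("lo", "hi"), each = 100)
    score <- setNames(rnorm(200) + (grp == "hi"), ids)
    clin <- cohort_clinical(data.frame(sample_id = ids, grp = grp,
                                       stringsAsFactors = FALSE))
    associate_feature(score, clin, "grp")$p_value < 0.01
  }, logical(1L))
  expect_gte(mean(hits), 0.99)
})

test_that("kNN-LOOCV is exact on separated clusters and null on permuted labels", {
  set.seed(41)
  n <- 12
  v <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:n)))
  labels <- rep(c("pos", "neg"), each = n / 2)
  # give each class its own pattern so both distance metrics can see it
  v[1:10, labels == "pos"] <- v[1:10, labels == "pos"] + 5
  v[11:20, labels == "neg"] <- v[11:20, labels == "neg"] + 5
  em <- expression_matrix(v, annotations = data.frame(
    cd133_status = labels, row.names = colnames(v)))
  expect_equal(knn_loocv(em, "cd133_status", k = 3)$accuracy, 1)
  expect_equal(knn_loocv(em, "cd133_status", k = 3,
                         distance = "correlation")$accuracy, 1)

  # permutation null: accuracy collapses to chance level (LOOCV excludes the
  # held-out sample, so with balanced permuted labels the null mean sits
  # slightly below 0.5 rather than exactly at it)
  set.seed(42)
  acc <- vapply(1:200, function(i)
    knn_loocv(em, sample(labels), k = 3)$accuracy, numeric(1L))
  expect_lt(abs(mean(acc) - 0.5), 0.1)
  expect_lt(mean(acc), 0.6)
})

test_that("kNN-LOOCV is order-invariant away from ties and errors on misuse", {
  set.seed(43)
  v <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  labels <- rep(c("A", "B"), 5)
  base <- knn_loocv(v, labels, k = 3)
  perm <- sample(10)
  shuffled <- knn_loocv(v[, perm], labels[perm], k = 3)
  expect_identical(
    shuffled$predictions$predicted[order(perm)],
    base$predictions$predicted)

  expect_error(knn_loocv(v, labels, k = 10), "smaller than the sample count")
  expect_error(knn_loocv(v, rep("A", 10), k = 3), "two classes")

  # degenerate geometry: all samples identical; k = 1 falls back to the
  # smallest-index neighbour, so predictions follow the documented tie-break
  same <- matrix(1, 5, 4, dimnames = list(sprintf("g%d", 1:5),
                                          sprintf("s%d", 1:4)))
  out <- knn_loocv(same, c("A", "B", "A", "B"), k = 1)
  expect_identical(out$predictions$predicted, c("B", "A", "A", "A"))
})
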