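test_that("SNR matches the hand-computed example and basic contracts", {
  em <- two_group_matrix(c(1, 2, 3), c(4, 5, 6))
  snr <- compute_snr(em, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  # sample sds are 1 and 1; (2 - 5) / (1 + 1) = -1.5; floors (0.4, 1.0) inert
  expect_identical(snr$snr, -1.5)

  # constant and equal in both groups -> zero numerator
  em0 <- two_group_matrix(c(2, 2), c(2, 2))
  expect_identical(compute_snr(em0, c("a1", "a2"), c("b1", "b2"))$snr, 0)

  expect_error(compute_snr(em, c("a1", "a2"), c("zz", "b1")), "unknown sample")
  expect_error(compute_snr(em, c("a1", "a2"), c("a2", "b1")), "disjoint")
  expect_error(compute_snr(em, "a1", c("b1", "b2")), ">= 2 samples")
})

test_that("SNR is exactly antisymmetric under group swap", {
  em <- random_expression(200, 10, seed = 3)
  a <- sprintf("S%02d", 1:5); b <- sprintf("S%02d", 6:10)
  expect_identical(compute_snr(em, a, b)$snr, -compute_snr(em, b, a)$snr)
})

test_that("the population-sd switch changes the convention as documented", {
  em <- two_group_matrix(c(1, 2, 3), c(4, 5, 6))
  snr <- compute_snr(em, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                     unbiased = FALSE, sd_floor = FALSE)
  expect_equal(snr$snr, -3 / (2 * sqrt(2 / 3)), tolerance = 1e-12)
  # with the floor on, group b's sd (0.816) is lifted to 0.2 * 5 = 1
  snr_f <- compute_snr(em, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                       unbiased = FALSE)
  expect_equal(snr_f$snr, -3 / (sqrt(2 / 3) + 1), tolerance = 1e-12)
})

test_that("signature derivation recovers planted genes and stays disjoint", {
  for (seed in c(2, 14, 31)) {
    truth <- sorted_experiment_truth(seed = seed)  # effect 3, noise 1 defaults
    sim <- simulate_sorted_experiment(truth)
    sig <- derive_signature(sim$expression)
    sens_up <- mean(truth$planted_up %in% sig$up_genes)
    sens_dn <- mean(truth$planted_down %in% sig$down_genes)
    fpr <- mean(setdiff(gene_ids(sim$expression), truth$planted_up) %in%
                  sig$up_genes)
    expect_gt(sens_up, 0.75)
    expect_gt(sens_dn, 0.75)
    expect_lt(fpr, 0.01)
    expect_length(intersect(sig$up_genes, sig$down_genes), 0L)
  }
})

test_that("derived signatures are stable under gene-row permutation", {
  truth <- sorted_experiment_truth(n_genes = 300, seed = 8)
  sim <- simulate_sorted_experiment(truth)
  sig <- derive_signature(sim$expression)
  set.seed(1)
  perm <- sample(nrow(sim$expression$values))
  em_p <- expression_matrix(sim$expression$values[perm, ],
                            annotations = sim$expression$annotations)
  sig_p <- derive_signature(em_p)
  expect_identical(sig_p$up_genes, sig$up_genes)
  expect_identical(sig_p$down_genes, sig$down_genes)
})

test_that("cross-cell-line sign consistency excludes discordant genes", {
  # gene up strongly in lines 1-2, down in line 3: pooled SNR passes the
  # threshold but the consistency conjunct must exclude it
  lines <- rep(c("L1", "L2", "L3"), each = 4)
  status <- rep(c("pos", "pos", "neg", "neg"), 3)
  samples <- sprintf("%s_%s_%d", lines, status, seq_along(lines))
  vals <- c(10, 10.1, 0, 0.1,   10.2, 10, 0.1, 0,   4.9, 5, 5.9, 6)
  em <- expression_matrix(
    tiny_matrix(rep(vals, each = 1), genes = "gX", samples = samples),
    annotations = data.frame(cell_line = lines, cd133_status = status,
                             row.names = samples))
  pooled <- compute_snr(em, samples[status == "pos"], samples[status == "neg"])
  expect_gt(pooled$snr, 1)  # pooled alone would call it up
  sig <- derive_signature(em)
  expect_length(sig$up_genes, 0L)
  sig_nc <- derive_signature(em, require_consistency = FALSE)
  expect_identical(sig_nc$up_genes, "gX")
})

test_that("vacuous thresholds give an empty signature; missing arms error", {
  truth <- sorted_experiment_truth(n_genes = 100, seed = 4)
  sim <- simulate_sorted_experiment(truth)
  sig <- derive_signature(sim$expression, up_threshold = Inf,
                          down_threshold = -Inf)
  expect_length(sig$up_genes, 0L)
  expect_length(sig$down_genes, 0L)

  keep <- sim$expression$annotations$cd133_status == "pos" |
    sim$expression$annotations$cell_line != "CL2"
  em <- expression_matrix(sim$expression$values[, keep],
                          annotations = sim$expression$annotations[keep, ])
  expect_error(derive_signature(em), "CL2.*missing")
})

test_that("top-variable selection honors dominance, ties and nesting", {
  em <- tiny_expression(c(1, 5, 5, 1.1, 5, 5, 0.9, 5, 5, 1, 5, 5),
                        genes = c("big", "flat1", "flat2"))
  expect_identical(select_top_variable(em, 1), "big")
  expect_identical(select_top_variable(em, 1, statistic = "variance"), "big")

  const <- tiny_expression(rep(1, 10), genes = sprintf("g%d", c(3, 1, 5, 2, 4)),
                           samples = c("s1", "s2"))
  expect_identical(select_top_variable(const, 5),
                   c("g1", "g2", "g3", "g4", "g5"))

  rnd <- random_expression(50, 6, seed = 17)
  full <- select_top_variable(rnd, 50)
  for (n in c(1, 10, 49))
    expect_identical(select_top_variable(rnd, n), full[seq_len(n)])
  expect_error(select_top_variable(rnd, 51), "exceeds")
})

test_that("core-signature reduction counts per-list membership", {
  expect_identical(build_core_signature(list(c("A", "B"), c("B", "C"),
                                             c("C", "D")), 2), c("B", "C"))
  # duplicates within a list count once
  expect_identical(build_core_signature(list(c("A", "A", "B"), c("C", "B"),
                                             c("D")), 2), "B")
  same <- c("x", "y", "z")
  expect_identical(build_core_signature(list(same, same, same), 3),
                   sort(same))
  expect_error(build_core_signature(list(c("A")), 2), "at least 2")
  expect_error(build_core_signature(list("A", "B"), 3), "exceeds the number")
})

test_that("hierarchical clustering separates structure deterministically", {
  m <- rbind(id1 = c(1, 2, 3, 4), id2 = c(1, 2, 3, 4))
  hc <- hierarchical_cluster(m, distance = "correlation")
  expect_equal(hc$hclust$height, 0)

  m3 <- rbind(a = c(1, 2, 3, 4, 5), b = c(1.1, 2, 3.2, 4, 5.1),
              c = c(5, 4, 3, 2, 1))
  labs <- hierarchical_cluster(m3, distance = "correlation", k = 2)$labels
  expect_identical(labs[["a"]], labs[["b"]])
  expect_false(labs[["a"]] == labs[["c"]])

  expect_error(hierarchical_cluster(rbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                                    distance = "correlation"),
               "zero-variance.*a")
})

test_that("scores of a sorted experiment cluster samples by sort status", {
  truth <- sorted_experiment_truth(seed = 12)
  sim <- simulate_sorted_experiment(truth)
  sig <- derive_signature(sim$expression)
  sc <- score_collection(sim$expression, signature_collection(sig))
  labs <- hierarchical_cluster(t(sc$scores), distance = "euclidean",
                               k = 2)$labels
  status <- sim$expression$annotations$cd133_status
  expect_equal(length(unique(labs[status == "pos"])), 1L)
  expect_equal(length(unique(labs[status == "neg"])), 1L)
  expect_false(labs[status == "pos"][1] == labs[status == "neg"][1])
})
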