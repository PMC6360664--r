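# Small in-code fixtures shared across test files.

# genes x samples matrix with named dims
tiny_matrix <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes) && is.null(samples))
    stop("give at least one of genes/samples")
  if (is.null(genes)) {
    m <- matrix(values, ncol = length(samples))
    genes <- sprintf("g%d", seq_len(nrow(m)))
  } else {
    m <- matrix(values, nrow = length(genes))
    if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  }
  dimnames(m) <- list(genes, samples)
  m
}

tiny_expression <- function(values, genes = NULL, samples = NULL, ...) {
  expression_matrix(tiny_matrix(values, genes, samples), ...)
}

# one-gene matrix holding the two groups side by side
two_group_matrix <- function(a, b) {
  tiny_expression(c(a, b), genes = "g1",
                  samples = c(sprintf("a%d", seq_along(a)),
                              sprintf("b%d", seq_along(b))))
}

# random expression fixture for property tests
random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  tiny_expression(rnorm(n_genes * n_samples, 8, 2),
                  genes = sprintf("G%04d", seq_len(n_genes)),
                  samples = sprintf("S%02d", seq_len(n_samples)))
}

# direct hypergeometric upper-tail summation, independent of phyper
brute_hyper_tail <- function(overlap, set_size, list_size, universe) {
  k <- overlap:min(set_size, list_size)
  sum(choose(set_size, k) * choose(universe - set_size, list_size - k)) /
    choose(universe, list_size)
}
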