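# Independent oracles used across the suite. Each re-derives its quantity by
# brute force or closed form, never through the code path it checks.

# Floyd-Warshall all-pairs shortest paths on a binary adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# hypergeometric upper-tail p by exhaustive enumeration of all size-n targets
# drawn from a universe of N genes of which the first K carry the term
enum_hypergeom_p <- function(N, K, n, x) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= x)
}

# one-sided Fisher p for a 2x2 table by tail summation with choose()
enum_fisher_p <- function(tab) {
  a <- tab[1, 1]
  K <- sum(tab[, 1])          # total with site
  n1 <- sum(tab[1, ])         # target group size
  N <- sum(tab)
  js <- max(0, K - (N - n1)):min(K, n1)
  probs <- choose(n1, js) * choose(N - n1, K - js) / choose(N, K)
  sum(probs[js >= a])
}

# closed-form simple linear regression
ols_closed_form <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2); sxy <- sum((x - xm) * (y - ym))
  syy <- sum((y - ym)^2)
  list(slope = sxy / sxx, intercept = ym - (sxy / sxx) * xm,
       r_squared = sxy^2 / (sxx * syy))
}

# wrap a symmetric |r| matrix for the network functions
as_corr <- function(m) {
  diag(m) <- 0
  class(m) <- c("correlation_matrix", class(m))
  m
}

# wrap an igraph graph as a coexpression_network (for topology tests that
# start from an explicit graph rather than a correlation matrix)
as_network <- function(g, tau = 0.5) {
  structure(list(graph = g, threshold = tau, species = NA_character_,
                 selection = NULL),
            class = "coexpression_network")
}

# small module spec builder
toy_modules <- function(sizes, rho, terms = NULL) {
  lapply(seq_along(sizes), function(i) {
    list(module_id = paste0("M", i), gene_count = sizes[i],
         within_correlation = rho,
         annotation_terms = if (is.null(terms)) paste0("term_M", i)
                            else terms[[i]])
  })
}

# annotation fixture: universe of n genes, terms annotating index sets
toy_annotation_acc <- function(n_universe, term_genes) {
  universe <- sprintf("u%03d", seq_len(n_universe))
  mapping <- do.call(rbind, lapply(names(term_genes), function(tm) {
    data.frame(gene = universe[term_genes[[tm]]], term = tm,
               stringsAsFactors = FALSE)
  }))
  go_annotation(mapping, universe)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
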