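sample_compendium <- function(values) {
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  md <- data.frame(sample_id = colnames(values),
                   condition = c("control",
                                 paste0("c", seq_len(ncol(values) - 1))),
                   control_condition = "control",
                   is_control = c(TRUE, rep(FALSE, ncol(values) - 1)),
                   platform = "rnaseq", stringsAsFactors = FALSE)
  expression_compendium(values, md)
}

test_that("absolute Pearson correlation matches hand computations", {
  v <- rbind(a = c(1, 2, 3), copy = c(1, 2, 3), anti = c(3, 2, 1),
             near = c(1, 2, 4))
  comp <- sample_compendium(v)
  cc <- correlation_matrix(comp)
  expect_equal(cc["a", "copy"], 1, tolerance = 1e-12)
  expect_equal(cc["a", "anti"], 1, tolerance = 1e-12)
  # r((1,2,3),(1,2,4)) = 1.5 / sqrt(7/3), by the definitional formula
  expect_equal(cc["a", "near"], 1.5 * sqrt(3 / 7), tolerance = 1e-6)
  expect_equal(unname(diag(cc)), rep(0, 4))
  expect_true(isSymmetric(unclass(cc)))

  flat <- sample_compendium(rbind(a = c(1, 2, 3), z = c(5, 5, 5)))
  expect_warning(ccf <- correlation_matrix(flat), "zero-variance")
  expect_equal(ccf["a", "z"], 0)

  two <- rbind(a = c(1, 2), b = c(2, 1))
  colnames(two) <- c("s1", "s2")
  md <- data.frame(sample_id = c("s1", "s2"), condition = c("control", "c1"),
                   control_condition = "control",
                   is_control = c(TRUE, FALSE), platform = "rnaseq")
  expect_error(correlation_matrix(expression_compendium(two, md)),
               "3 samples")
})

test_that("degree distributions count non-isolated nodes", {
  tri <- as_corr(matrix(0.95, 3, 3, dimnames = list(letters[1:3],
                                                    letters[1:3])))
  dd <- degree_distribution(tri, tau = 0.9)
  expect_equal(dd, data.frame(k = 2L, count = 3L))

  star <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  star["a", 2:5] <- star[2:5, "a"] <- 0.95
  dd <- degree_distribution(as_corr(star), tau = 0.9)
  expect_equal(dd, data.frame(k = c(1L, 4L), count = c(4L, 1L)))

  # planted two-block matrix: every node has degree block_size - 1
  blocks <- matrix(0.1, 12, 12)
  blocks[1:6, 1:6] <- 0.9
  blocks[7:12, 7:12] <- 0.9
  dimnames(blocks) <- list(paste0("g", 1:12), paste0("g", 1:12))
  dd <- degree_distribution(as_corr(blocks), tau = 0.5)
  expect_equal(dd, data.frame(k = 5L, count = 12L))
})

test_that("scale-free fit recovers exact power laws and matches closed-form OLS", {
  # counts 16/4/1 at k = 1/2/4: an exact k^-2 law
  fit <- scale_free_fit(data.frame(k = c(1L, 2L, 4L),
                                   count = c(16L, 4L, 1L)))
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_false(fit$low_support)

  two <- scale_free_fit(data.frame(k = c(1L, 3L), count = c(9L, 2L)))
  expect_equal(two$r_squared, 1, tolerance = 1e-12)
  expect_true(two$low_support)

  dd <- data.frame(k = 1:4, count = c(100L, 30L, 12L, 6L))
  fit <- scale_free_fit(dd)
  oracle <- ols_closed_form(log10(dd$k), log10(dd$count / sum(dd$count)))
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
})

test_that("threshold selection honors the band, ties and fallback contracts", {
  blocks <- matrix(0.1, 20, 20)
  blocks[1:10, 1:10] <- 0.9
  blocks[11:20, 11:20] <- 0.9
  dimnames(blocks) <- list(paste0("g", 1:20), paste0("g", 1:20))
  corr <- as_corr(blocks)

  one <- select_threshold(corr, grid = 0.5, band = c(1, 50))
  expect_equal(one$threshold, 0.5)

  # complete graph at every threshold <= 0.95: band unreachable
  dense <- as_corr(matrix(0.95, 30, 30,
                          dimnames = list(paste0("g", 1:30),
                                          paste0("g", 1:30))))
  expect_warning(
    sel <- select_threshold(dense, grid = c(0.5, 0.7, 0.9), band = c(5, 10)),
    "falling back")
  expect_false(sel$band_reached)
  # all thresholds give mean degree 29; the first minimizer is returned
  expect_equal(sel$chosen$mean_degree, 29)
  expect_error(select_threshold(dense, grid = numeric(0)), "empty")
})

test_that("grid scan equals a brute-force scan and separates planted modules", {
  spec <- compendium_spec(63, 21, 3, toy_modules(c(21, 21, 21), 0.95),
                          seed = 5)
  comp <- generate_compendium(spec)
  corr <- correlation_matrix(comp)
  sel <- select_threshold(corr)

  # brute-force oracle over the same grid
  m <- unclass(corr)
  brute <- t(vapply(seq(0.50, 0.99, by = 0.01), function(tau) {
    deg <- rowSums(m >= tau); deg <- deg[deg > 0]
    md <- if (length(deg)) mean(deg) else 0
    tab <- table(deg)
    r2 <- if (length(tab) >= 2) {
      ols_closed_form(log10(as.numeric(names(tab))),
                      log10(as.numeric(tab) / sum(tab)))$r_squared
    } else if (length(tab) == 1) 0 else 0
    c(tau = tau, mean_degree = md, r2 = r2)
  }, c(tau = 0, mean_degree = 0, r2 = 0)))
  expect_equal(sel$scan$mean_degree, unname(brute[, "mean_degree"]),
               tolerance = 1e-10)
  expect_equal(sel$scan$r_squared, unname(brute[, "r2"]), tolerance = 1e-10)
  in_band <- brute[, "mean_degree"] >= 15 & brute[, "mean_degree"] <= 25
  expect_true(any(in_band))
  best_r2 <- max(brute[in_band, "r2"])
  expect_equal(sel$chosen$r_squared, best_r2, tolerance = 1e-12)
  expect_equal(sel$threshold,
               max(brute[in_band & abs(brute[, "r2"] - best_r2) < 1e-12,
                         "tau"]))

  # the chosen threshold keeps modules apart
  net <- build_network(corr, sel$threshold)
  e <- coexflow:::network_edge_df(net)
  mod_of <- rep(c("M1", "M2", "M3"), each = 21)
  names(mod_of) <- unlist(comp$truth$modules, use.names = FALSE)
  expect_true(all(mod_of[e$gene_a] == mod_of[e$gene_b]))
  expect_gt(sel$threshold, 0.3)
  expect_true(sel$band_reached)
})

test_that("network construction thresholds exactly and drops isolated genes", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 0.95
  m["b", "c"] <- m["c", "b"] <- 0.95
  m["a", "c"] <- m["c", "a"] <- 0.10
  # d correlates with nobody
  net <- build_network(as_corr(m), 0.9)
  expect_setequal(network_genes(net), c("a", "b", "c"))
  e <- coexflow:::network_edge_df(net)
  expect_equal(nrow(e), 2)
  expect_setequal(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)),
                  c("a b", "b c"))

  empty <- build_network(as_corr(m), 1.0)
  expect_equal(igraph::ecount(empty$graph), 0)
})

test_that("thresholded edge sets equal a brute-force matrix filter", {
  set.seed(77)
  n <- 150
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  dimnames(m) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  corr <- as_corr(m)
  for (tau in c(0.8, 0.95, 0.99)) {
    net <- build_network(corr, tau)
    e <- coexflow:::network_edge_df(net)
    got <- sort(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)))
    idx <- which(upper.tri(m) & unclass(corr) >= tau, arr.ind = TRUE)
    want <- sort(paste(pmin(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]]),
                       pmax(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]])))
    expect_identical(got, want)
  }
})

test_that("mean degree is non-increasing in the threshold", {
  spec <- compendium_spec(60, 10, 3, toy_modules(c(30, 30), 0.9), seed = 31)
  comp <- generate_compendium(spec)
  sel <- select_threshold(correlation_matrix(comp), band = c(1, 60))
  md <- sel$scan$mean_degree
  nz <- md[sel$scan$nodes > 0]
  # over thresholds that retain any node, 2E/N computed on all DEGs would be
  # monotone; with isolated-node exclusion monotonicity holds for total edges
  expect_true(all(diff(sel$scan$edges) <= 0))
  expect_true(all(diff(sel$scan$nodes) <= 0))
})

test_that("preferential-attachment graphs score higher scale-free R2 than ER", {
  r2 <- function(g) {
    deg <- igraph::degree(g); deg <- deg[deg > 0]
    tab <- table(deg)
    scale_free_fit(data.frame(k = as.integer(names(tab)),
                              count = as.integer(tab)))$r_squared
  }
  diffs <- vapply(1:10, function(s) {
    set.seed(s)
    pa <- igraph::sample_pa(300, m = 3, directed = FALSE)
    er <- igraph::sample_gnm(300, igraph::ecount(pa))
    r2(pa) - r2(er)
  }, 0)
  expect_gt(median(diffs), 0)
})

test_that("network export formats round-trip and validate", {
  m <- matrix(0, 6, 6, dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  for (i in 1:5) m[i, i + 1] <- m[i + 1, i] <- 0.90 + i / 100
  m[1, 6] <- m[6, 1] <- 0.99
  net <- build_network(as_corr(m), 0.9)
  td <- withr::local_tempdir()

  tsv <- file.path(td, "net.tsv")
  export_network(net, tsv, "tsv")
  back <- import_network_tsv(tsv)
  key <- function(nn) {
    e <- coexflow:::network_edge_df(nn)
    sort(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b), e$abs_r))
  }
  expect_identical(key(back), key(net))

  one <- build_network(as_corr(matrix(c(0, .95, .95, 0), 2,
                                      dimnames = list(c("x", "y"),
                                                      c("x", "y")))), 0.9)
  sif <- file.path(td, "net.sif")
  export_network(one, sif, "sif")
  expect_identical(readLines(sif), "x\tco\ty")

  gml <- file.path(td, "net.graphml")
  export_network(net, gml, "graphml")
  doc <- xml2::read_xml(gml)  # well-formed XML in the GraphML namespace
  expect_equal(xml2::xml_name(doc), "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
  expect_setequal(igraph::V(g2)$name %||% igraph::V(g2)$id,
                  network_genes(net))

  expect_error(export_network(net, file.path(td, "x"), "gexf"))
})
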