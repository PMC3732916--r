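toy_annotation <- function(n_universe, term_genes) {
  universe <- sprintf("u%03d", seq_len(n_universe))
  mapping <- do.call(rbind, lapply(names(term_genes), function(tm) {
    data.frame(gene = universe[term_genes[[tm]]], term = tm,
               stringsAsFactors = FALSE)
  }))
  go_annotation(mapping, universe)
}

test_that("hypergeometric enrichment matches combinatorial hand values", {
  # a term annotating the whole universe can never be enriched
  ann <- toy_annotation(10, list(everything = 1:10))
  et <- hypergeometric_enrichment(sprintf("u%03d", 1:4), ann)
  expect_equal(et$p, 1.0, tolerance = 1e-12)

  # target exactly the 5 annotated genes out of 10: p = 1/C(10,5) = 1/252
  ann <- toy_annotation(10, list(hit = 1:5))
  et <- hypergeometric_enrichment(sprintf("u%03d", 1:5), ann)
  expect_equal(et$p, 1 / 252, tolerance = 1e-9)
  expect_equal(et$x, 5)
  expect_equal(et$fold, (5 / 5) / (5 / 10))

  # genes outside the universe are dropped with a warning
  expect_warning(
    et2 <- hypergeometric_enrichment(c(sprintf("u%03d", 1:5), "alien"), ann),
    "outside the universe")
  expect_equal(et2$p, et$p)
  expect_error(
    hypergeometric_enrichment("u001", go_annotation(
      data.frame(gene = character(0), term = character(0)), character(0))),
    "empty")
})

test_that("enrichment p-values equal exhaustive enumeration for N <= 12", {
  ann <- toy_annotation(12, list(t5 = 1:5, t3 = c(2, 7, 9)))
  set.seed(1)
  for (n in c(4, 6)) {
    target <- sample(sprintf("u%03d", 1:12), n)
    et <- hypergeometric_enrichment(target, ann)
    for (i in seq_len(nrow(et))) {
      K <- et$K[i]
      expect_equal(et$p[i], enum_hypergeom_p(12, K, n, et$x[i]),
                   tolerance = 1e-10,
                   info = paste("term", et$term[i], "n", n))
    }
  }
})

test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # order preserved and capped at 1
  q <- bh_adjust(c(0.9, 0.001, 0.5))
  expect_equal(order(q), order(c(0.9, 0.001, 0.5)))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("cross-species term classes follow the ordered-suffix rule", {
  mk_table <- function(terms_q) {
    structure(data.frame(term = names(terms_q), x = 1, n = 5, K = 2, N = 50,
                         fold = 2, p = unname(terms_q), q = unname(terms_q),
                         stringsAsFactors = FALSE),
              class = c("enrichment_table", "data.frame"))
  }
  tabs <- list(
    alga  = mk_table(c(core = 0.01, chem = 0.8, alg_only = 0.01, odd = 0.01)),
    moss  = mk_table(c(core = 0.02, chem = 0.01, alg_only = 0.9, odd = 0.9)),
    plant = mk_table(c(core = 0.03, chem = 0.02, alg_only = 0.9, odd = 0.01)))
  cmp <- compare_across_species(tabs, c("alga", "moss", "plant"))
  cls <- setNames(cmp$class, cmp$term)
  expect_equal(cls[["core"]], "conserved_all")
  # enriched in moss + plant only: a process gained after the alga
  expect_equal(cls[["chem"]], "shared_derived")
  expect_equal(cls[["alg_only"]], "species_specific")
  # non-contiguous pattern (alga + plant, not moss) is species_specific
  expect_equal(cls[["odd"]], "species_specific")

  # permutation invariance to insertion order of the tables list
  cmp2 <- compare_across_species(tabs[c("plant", "alga", "moss")],
                                 c("alga", "moss", "plant"))
  expect_equal(cmp, cmp2)
})

test_that("marker correlation handles identity, degeneracy and planted modules", {
  spec <- compendium_spec(60, 12, 3, toy_modules(c(20, 20), 0.9), seed = 41)
  comp <- generate_compendium(spec)
  m1 <- comp$truth$modules$M1
  m2 <- comp$truth$modules$M2
  markers <- data.frame(gene = c(m1[1], m2[1]),
                        label = c("light", "starch"),
                        stringsAsFactors = FALSE)
  mc <- marker_correlation(comp, focal = c(m1[1], m1[2], m2[2]),
                           markers = markers)
  expect_equal(mc[m1[1], m1[1]], 1)  # a focal gene that is its own marker
  expect_gt(mean(mc[c(m1[1], m1[2]), m1[1]]), 0.9 - 0.1)
  expect_lt(mc[m2[2], m1[1]], 0.5)

  comp$values[m1[2], ] <- 7  # constant profile
  expect_warning(mc2 <- marker_correlation(comp, c(m1[1], m1[2]), markers),
                 "constant")
  expect_equal(unname(mc2[m1[2], ]), c(0, 0))
  expect_error(marker_correlation(comp, "nope", markers), "nope")
})

test_that("focal-gene grouping separates block profiles deterministically", {
  rows <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
  colnames(rows) <- c("mk1", "mk2")
  grp <- cluster_focal_groups(structure(rows,
    class = c("marker_correlation_matrix", "matrix")), n_groups = 2)
  expect_equal(grp[["a"]], grp[["b"]])
  expect_equal(grp[["c"]], grp[["d"]])
  expect_true(grp[["a"]] != grp[["c"]])
  expect_error(cluster_focal_groups(structure(rows[1, , drop = FALSE],
    class = c("marker_correlation_matrix", "matrix")), 2), "fewer")
})

test_that("planted ancestral vs derived focal groups are recovered", {
  ok <- vapply(1:10, function(s) {
    spec <- compendium_spec(44, 12, 3, toy_modules(c(20, 20), 0.9),
                            seed = 200 + s)
    comp <- generate_compendium(spec)
    m1 <- comp$truth$modules$M1
    m2 <- comp$truth$modules$M2
    markers <- data.frame(gene = c(m1[1:2], m2[1:2]),
                          label = rep(c("anc", "dev"), each = 2))
    focal <- c(m1[3:5], m2[3:5])
    mc <- marker_correlation(comp, focal, markers)
    grp <- cluster_focal_groups(mc, 2)
    length(unique(grp[m1[3:5]])) == 1 &&
      length(unique(grp[m2[3:5]])) == 1 &&
      grp[[m1[3]]] != grp[[m2[3]]]
  }, TRUE)
  expect_gte(sum(ok), 9)
})

test_that("hypergeometric test controls type-I error under the null", {
  set.seed(7)
  universe <- sprintf("u%04d", 1:500)
  ann <- go_annotation(data.frame(gene = universe[1:60], term = "t"),
                       universe)
  alpha <- 0.05
  p <- vapply(1:1000, function(i) {
    target <- sample(universe, 40)
    et <- hypergeometric_enrichment(target, ann)
    if (nrow(et) == 0) 1 else et$p
  }, 0)
  se <- sqrt(alpha * (1 - alpha) / 1000)
  expect_lte(mean(p <= alpha), alpha + 3 * se)
})

test_that("planted module terms outrank annotation noise terms", {
  ok <- vapply(1:20, function(s) {
    spec <- compendium_spec(220, 8, 3,
                            toy_modules(20, 0.95,
                                        terms = list("planted_process")),
                            seed = 300 + s)
    comp <- generate_compendium(spec)
    ann <- generate_annotations(comp, terms_per_gene_noise = 0.15,
                                term_pool = c("planted_process",
                                              paste0("noise", 1:9)),
                                seed = 300 + s)
    # a realistic target: the planted module plus a few stray background
    # genes, so noise terms also reach the target
    target <- c(comp$truth$modules$M1,
                coexflow:::with_seed(s, sample(comp$truth$background_genes,
                                               15)))
    et <- hypergeometric_enrichment(target, ann)
    min_noise <- min(c(et$p[et$term != "planted_process"], Inf))
    et$p[et$term == "planted_process"] < min_noise
  }, TRUE)
  expect_gte(sum(ok), 19)
})
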