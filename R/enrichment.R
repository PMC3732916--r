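#' GO annotation container
#'
#' @param mapping Data frame with columns `gene` and `term`, one pair per
#'   row (the flat gene-to-term annotation).
#' @param universe Character vector of all genome genes used as enrichment
#'   background; must contain every annotated gene.
#' @return Object of class `go_annotation`.
#' @export
go_annotation <- function(mapping, universe) {
  if (!all(c("gene", "term") %in% names(mapping))) {
    stop("mapping must have columns `gene` and `term`", call. = FALSE)
  }
  mapping <- unique(mapping[, c("gene", "term")])
  stray <- setdiff(mapping$gene, universe)
  if (length(stray) > 0) {
    stop("annotated genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(mapping = mapping, universe = unique(universe)),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf("go_annotation: %d gene-term pairs, %d terms, universe %d genes\n",
              nrow(x$mapping), length(unique(x$mapping$term)),
              length(x$universe)))
  invisible(x)
}

#' Read a flat annotation TSV (gene TAB term per line)
#' @param path Path to the two-column TSV (header `gene`, `term` optional).
#' @param universe Background universe; defaults to all annotated genes.
#' @return A [go_annotation()].
#' @export
read_annotation_table <- function(path, universe = NULL) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("gene", "term")
  if (tab$gene[1] == "gene" && tab$term[1] == "term") tab <- tab[-1, ]
  go_annotation(tab, universe %||% unique(tab$gene))
}

#' Write a flat annotation TSV
#' @param annotation A [go_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(annotation, path) {
  utils::write.table(annotation$mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Hypergeometric GO-term enrichment
#'
#' One-sided over-representation test of each term in a target gene set
#' against the annotation universe (the genome background): with `N` universe
#' genes, `K` of them annotated with the term, and a target of size `n`
#' containing `x` annotated genes, `p = P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)`. Terms absent from the target (`x = 0`) are
#' omitted. Benjamini-Hochberg q-values are attached across the tested
#' terms.
#'
#' @param target Character vector of target genes; genes outside the
#'   universe are dropped with a warning.
#' @param annotation A [go_annotation()].
#' @return Object of class `enrichment_table`: data frame with `term`, `x`,
#'   `n`, `K`, `N`, `fold` (`(x/n)/(K/N)`), `p`, `q`, sorted by `p`.
#' @export
hypergeometric_enrichment <- function(target, annotation) {
  N <- length(annotation$universe)
  if (N == 0) stop("empty annotation universe", call. = FALSE)
  outside <- setdiff(target, annotation$universe)
  if (length(outside) > 0) {
    warning(length(outside), " target gene(s) outside the universe dropped")
  }
  target <- unique(intersect(target, annotation$universe))
  n <- length(target)
  term_K <- table(annotation$mapping$term)
  in_target <- annotation$mapping$gene %in% target
  term_x <- table(annotation$mapping$term[in_target])
  terms <- names(term_x)
  if (length(terms) == 0 || n == 0) {
    res <- data.frame(term = character(0), x = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), fold = numeric(0),
                      p = numeric(0), q = numeric(0))
    return(structure(res, class = c("enrichment_table", "data.frame")))
  }
  x <- as.integer(term_x[terms])
  K <- as.integer(term_K[terms])
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term = terms, x = x, n = n, K = K, N = N,
                    fold = (x / n) / (K / N), p = p,
                    q = bh_adjust(p), stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_table", "data.frame"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control:
#' `q_(i) = min_{j >= i} ( p_(j) * m / j )`, capped at 1, mapped back to the
#' input order.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify term conservation across species
#'
#' Given per-species enrichment tables and the species' evolutionary order
#' (e.g. alga, moss, angiosperm), each term is classed as:
#' `conserved_all` (enriched in every species), `shared_derived` (enriched
#' in a contiguous suffix of at least two later species, the pattern of a
#' process gained after the first species and then retained),
#' `species_specific` (any other pattern with at least one enrichment), or
#' `not_enriched`.
#'
#' @param tables Named list of [hypergeometric_enrichment()] tables, one per
#'   species.
#' @param species_order Character vector giving the evolutionary order of
#'   the species; defaults to `names(tables)`.
#' @param q_cutoff Enrichment calls use `q <= q_cutoff` (default 0.05).
#' @return Object of class `term_comparison`: data frame with `term`, one
#'   logical `enriched_<species>` column per species, and `class`.
#' @export
compare_across_species <- function(tables, species_order = names(tables),
                                   q_cutoff = 0.05) {
  if (length(tables) < 2) stop("need at least two species", call. = FALSE)
  if (is.null(names(tables)) || !setequal(names(tables), species_order)) {
    stop("`tables` must be named to match `species_order`", call. = FALSE)
  }
  tables <- tables[species_order]
  all_terms <- sort(unique(unlist(lapply(tables, function(t) t$term))))
  flags <- vapply(tables, function(t) {
    all_terms %in% t$term[t$q <= q_cutoff]
  }, logical(length(all_terms)))
  flags <- matrix(flags, nrow = length(all_terms),
                  dimnames = list(all_terms, species_order))
  classify <- function(f) {
    s <- length(f)
    if (all(f)) return("conserved_all")
    if (!any(f)) return("not_enriched")
    first <- which(f)[1]
    if (first > 1 && all(f[first:s]) && sum(f) >= 2) return("shared_derived")
    "species_specific"
  }
  res <- data.frame(term = all_terms,
                    stringsAsFactors = FALSE)
  for (sp in species_order) res[[paste0("enriched_", sp)]] <- flags[, sp]
  res$class <- apply(flags, 1, classify)
  rownames(res) <- NULL
  structure(res, class = c("term_comparison", "data.frame"))
}

#' Marker-correlation matrix for focal genes
#'
#' Absolute Pearson correlation of each focal gene against a panel of
#' process-marker genes, across all samples; the plot behind this matrix
#' separates focal genes by the biological processes they track. Constant
#' profiles yield a row/column of 0 with a warning.
#'
#' @param compendium An [expression_compendium()].
#' @param focal Character vector of focal genes.
#' @param markers Data frame with columns `gene` and `label` (the process
#'   each marker represents).
#' @return Object of class `marker_correlation_matrix`: numeric matrix
#'   (focal x markers) with a `marker_labels` attribute.
#' @export
marker_correlation <- function(compendium, focal, markers) {
  if (!all(c("gene", "label") %in% names(markers))) {
    stop("`markers` must have columns `gene` and `label`", call. = FALSE)
  }
  missing <- setdiff(c(focal, markers$gene), rownames(compendium$values))
  if (length(missing) > 0) {
    stop("genes absent from compendium: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fm <- compendium$values[focal, , drop = FALSE]
  mm <- compendium$values[markers$gene, , drop = FALSE]
  flat <- c(rownames(fm)[apply(fm, 1, stats::sd) == 0],
            rownames(mm)[apply(mm, 1, stats::sd) == 0])
  if (length(flat) > 0) {
    warning("constant profile(s), correlations set to 0: ",
            paste(unique(flat), collapse = ", "))
  }
  cc <- suppressWarnings(abs(stats::cor(t(fm), t(mm))))
  cc[is.na(cc)] <- 0
  structure(cc, marker_labels = stats::setNames(markers$label, markers$gene),
            class = c("marker_correlation_matrix", class(cc)))
}

#' Group focal genes by their marker-correlation profiles
#'
#' Agglomerative clustering (average linkage on Euclidean distances between
#' the rows of the marker-correlation matrix) cut at `n_groups`. Rows are
#' processed in lexicographic gene order, making the result deterministic.
#' Group labels are renumbered in order of first appearance.
#'
#' @param m A `marker_correlation_matrix`.
#' @param n_groups Number of groups (default 2).
#' @return Named integer vector: group per focal gene.
#' @export
cluster_focal_groups <- function(m, n_groups = 2) {
  if (nrow(m) < n_groups) {
    stop("fewer focal genes (", nrow(m), ") than groups (", n_groups, ")",
         call. = FALSE)
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  cl <- stats::cutree(stats::hclust(stats::dist(m), method = "average"),
                      k = n_groups)
  relabel <- match(cl, unique(cl))
  stats::setNames(relabel, rownames(m))
}
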