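#' Absolute Pearson correlation matrix
#'
#' Computes `|r|` between gene expression profiles across all samples of the
#' compendium, the co-expression measure used throughout. Zero-variance
#' profiles cannot be correlated; their entries are set to 0 with a warning.
#' The diagonal is set to 0 (self-correlation is never an edge).
#'
#' @param compendium An [expression_compendium()].
#' @param genes Genes to include (e.g. the selected DEG set); default all.
#' @return Symmetric matrix of class `correlation_matrix` with values in
#'   `[0, 1]` and zero diagonal.
#' @export
correlation_matrix <- function(compendium, genes = NULL) {
  genes <- genes %||% rownames(compendium$values)
  missing <- setdiff(genes, rownames(compendium$values))
  if (length(missing) > 0) {
    stop("genes absent from compendium: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- compendium$values[genes, , drop = FALSE]
  if (ncol(m) < 3) {
    stop("at least 3 samples are required for correlation", call. = FALSE)
  }
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance profile(s) set to correlation 0: ",
            paste(utils::head(genes[flat], 5), collapse = ", "),
            if (sum(flat) > 5) ", ..." else "")
  }
  cc <- suppressWarnings(abs(stats::cor(t(m))))
  cc[is.na(cc)] <- 0
  diag(cc) <- 0
  class(cc) <- c("correlation_matrix", class(cc))
  cc
}

#' Node degree distribution at a correlation threshold
#'
#' Degrees are counted on the graph whose edges are gene pairs with
#' `|r| >= tau`; isolated (degree-0) genes are excluded, matching networks
#' that only contain connected genes.
#'
#' @param x A `correlation_matrix` (with `tau`) or a
#'   [build_network()] result (threshold already applied).
#' @param tau Correlation threshold in `(0, 1)`; required for matrices.
#' @return Data frame with columns `k` (degree, `>= 1`) and `count`; counts
#'   sum to the number of non-isolated nodes.
#' @export
degree_distribution <- function(x, tau = NULL) {
  deg <- if (inherits(x, "coexpression_network")) {
    igraph::degree(x$graph)
  } else {
    if (is.null(tau) || tau <= 0 || tau >= 1) {
      stop("`tau` must be in (0, 1)", call. = FALSE)
    }
    rowSums(unclass(x) >= tau)
  }
  deg <- deg[deg > 0]
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Scale-free fit of a degree distribution
#'
#' Ordinary least squares of `log10 P(k)` on `log10 k` over the distinct
#' observed degrees, where `P(k) = count(k) / sum(count)`. A degree
#' distribution following a power law `P(k) ~ k^gamma` is linear on these
#' axes with slope `gamma`. Fits on fewer than 3 distinct degrees are
#' flagged `low_support` (two points fit any line exactly); a single degree
#' yields `r_squared = 0`.
#'
#' @param dd Degree distribution from [degree_distribution()].
#' @return Object of class `scale_free_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value` (two-sided t on the slope), `n_degrees`,
#'   `low_support`.
#' @export
scale_free_fit <- function(dd) {
  if (nrow(dd) == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = 0, p_value = NA_real_, n_degrees = 0L,
                          low_support = TRUE), class = "scale_free_fit"))
  }
  p_k <- dd$count / sum(dd$count)
  if (nrow(dd) == 1) {
    return(structure(list(slope = NA_real_, intercept = log10(p_k),
                          r_squared = 0, p_value = NA_real_, n_degrees = 1L,
                          low_support = TRUE), class = "scale_free_fit"))
  }
  fit <- stats::lm(log10(p_k) ~ log10(dd$k))
  # summary.lm warns on exact power laws ("essentially perfect fit");
  # a perfect fit is a legitimate input here
  sm <- suppressWarnings(summary(fit))
  p_value <- if (nrow(dd) > 2) sm$coefficients[2, 4] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p_value,
                 n_degrees = nrow(dd),
                 low_support = nrow(dd) < 3),
            class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("scale_free_fit: slope %.4f, R^2 %.4f, p %.3g (%d degrees%s)\n",
              x$slope, x$r_squared, x$p_value, x$n_degrees,
              if (x$low_support) ", low support" else ""))
  invisible(x)
}

#' Select a correlation threshold by scale-free criterion
#'
#' Scans a grid of candidate thresholds; at each, the network's mean degree
#' (`2 * edges / nodes`, isolated genes excluded) and the scale-free
#' regression R-squared are computed. Among thresholds whose mean degree
#' falls in `band` (operationalizing a target of about `target_mean_degree`
#' neighbors per gene), the one maximizing R-squared is chosen, ties broken
#' toward the higher (sparser) threshold. If no threshold reaches the band,
#' the threshold minimizing `|mean degree - target|` is returned with a
#' warning.
#'
#' @param corr A `correlation_matrix`.
#' @param grid Ascending candidate thresholds in `(0, 1)`.
#' @param target_mean_degree Target neighbors per gene (default 20).
#' @param band Acceptable mean-degree interval (default `c(15, 25)`).
#' @return Object of class `threshold_selection`: list with `threshold`,
#'   `chosen` (the selected scan row), `scan` (full audit data frame:
#'   `tau`, `nodes`, `edges`, `mean_degree`, `slope`, `r_squared`,
#'   `p_value`, `low_support`, `in_band`) and `band_reached`.
#' @export
select_threshold <- function(corr, grid = seq(0.50, 0.99, by = 0.01),
                             target_mean_degree = 20, band = c(15, 25)) {
  if (length(grid) == 0) stop("empty threshold grid", call. = FALSE)
  if (any(grid <= 0 | grid >= 1)) {
    stop("grid thresholds must lie in (0, 1)", call. = FALSE)
  }
  if (is.unsorted(grid)) stop("grid must be ascending", call. = FALSE)
  if (length(band) != 2 || band[1] > band[2]) {
    stop("band must be an ascending pair", call. = FALSE)
  }
  m <- unclass(corr)
  scan <- do.call(rbind, lapply(grid, function(tau) {
    deg <- rowSums(m >= tau)
    deg <- deg[deg > 0]
    nodes <- length(deg)
    edges <- sum(deg) / 2
    mean_degree <- if (nodes > 0) 2 * edges / nodes else 0
    fit <- scale_free_fit(
      if (nodes > 0) {
        tab <- table(deg)
        data.frame(k = as.integer(names(tab)), count = as.integer(tab))
      } else {
        data.frame(k = integer(0), count = integer(0))
      })
    data.frame(tau = tau, nodes = nodes, edges = edges,
               mean_degree = mean_degree, slope = fit$slope,
               r_squared = fit$r_squared, p_value = fit$p_value,
               low_support = fit$low_support)
  }))
  scan$in_band <- scan$nodes > 0 & scan$mean_degree >= band[1] &
    scan$mean_degree <= band[2]
  if (any(scan$in_band)) {
    cand <- scan[scan$in_band, ]
    best <- cand[cand$r_squared == max(cand$r_squared), ]
    chosen <- best[which.max(best$tau), ]
    band_reached <- TRUE
  } else {
    warning("no grid threshold reaches mean degree in [", band[1], ", ",
            band[2], "]; falling back to the threshold closest to the ",
            "target of ", target_mean_degree)
    i <- which.min(abs(scan$mean_degree - target_mean_degree))
    chosen <- scan[i, ]
    band_reached <- FALSE
  }
  structure(list(threshold = chosen$tau, chosen = chosen, scan = scan,
                 target_mean_degree = target_mean_degree, band = band,
                 band_reached = band_reached),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf(
    "threshold_selection: tau = %.2f (mean degree %.1f, R^2 %.4f%s)\n",
    x$threshold, x$chosen$mean_degree, x$chosen$r_squared,
    if (!x$band_reached) ", band NOT reached" else ""))
  invisible(x)
}

#' Build a co-expression network at a threshold
#'
#' Creates the undirected graph whose edges link gene pairs with
#' `|r| >= tau`, weighted by `|r|`. Genes with no surviving edge are
#' dropped; node counts refer to connected genes only.
#'
#' @param corr A `correlation_matrix`.
#' @param tau Correlation threshold in `(0, 1]` (at `tau = 1` only perfect
#'   correlations survive, typically an empty network).
#' @param species Optional species tag.
#' @param selection Optional `threshold_selection` audit trail to attach.
#' @return Object of class `coexpression_network`: list with `graph` (an
#'   [igraph] graph with edge attribute `weight`), `threshold`, `species`,
#'   `selection`.
#' @export
build_network <- function(corr, tau, species = NA_character_,
                          selection = NULL) {
  if (tau <= 0 || tau > 1) stop("`tau` must be in (0, 1]", call. = FALSE)
  m <- unclass(corr)
  idx <- which(upper.tri(m) & m >= tau, arr.ind = TRUE)
  edges <- data.frame(from = rownames(m)[idx[, 1]],
                      to = colnames(m)[idx[, 2]],
                      weight = m[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = g, threshold = tau, species = species,
                 selection = selection),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d genes, %d edges (|r| >= %.2f%s), mean degree %.1f\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold,
    if (!is.na(x$species)) paste0(", ", x$species) else "",
    mean_degree(x)))
  invisible(x)
}

#' Mean degree (neighbors per gene) of a network
#' @param net A `coexpression_network`.
#' @return `2 * edges / nodes`, or 0 for an empty network.
#' @export
mean_degree <- function(net) {
  n <- igraph::vcount(net$graph)
  if (n == 0) return(0)
  2 * igraph::ecount(net$graph) / n
}

#' Genes present (connected) in a network
#' @param net A `coexpression_network`.
#' @return Character vector of node names.
#' @export
network_genes <- function(net) igraph::V(net$graph)$name

network_edge_df <- function(net) {
  e <- igraph::as_data_frame(net$graph, what = "edges")
  names(e) <- c("gene_a", "gene_b", "abs_r")[seq_len(ncol(e))]
  e
}

#' Export a co-expression network
#'
#' Supported formats: `tsv` (edge list `gene_a`, `gene_b`, `abs_r`; the
#' round-trippable format, see [import_network_tsv()]), `sif` (Cytoscape
#' simple interaction format, relation `co`), `graphml` (with a `weight`
#' edge attribute).
#'
#' @param net A `coexpression_network` (non-empty).
#' @param path Output file path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (igraph::ecount(net$graph) == 0) {
    stop("refusing to export an empty network", call. = FALSE)
  }
  e <- network_edge_df(net)
  switch(format,
    tsv = write_tsv_plain(e, path),
    sif = writeLines(paste(e$gene_a, "co", e$gene_b, sep = "\t"), path),
    graphml = write_graphml(e, path)
  )
  invisible(path)
}

# minimal hand-rolled GraphML (node ids + numeric edge weight)
write_graphml <- function(edges, path) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<graphml xmlns="http://graphml.graphdrawing.org/xmlns" ',
           'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance" ',
           'xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns ',
           'http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">'),
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', nodes), con)
  writeLines(sprintf(
    '    <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
    edges$gene_a, edges$gene_b, edges$abs_r), con)
  writeLines(c('  </graph>', '</graphml>'), con)
}

#' Import a network from a TSV edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `abs_r`.
#' @param threshold Threshold to record on the rebuilt network (defaults to
#'   the minimum edge weight).
#' @param species Optional species tag.
#' @return A `coexpression_network`.
#' @export
import_network_tsv <- function(path, threshold = NULL,
                               species = NA_character_) {
  e <- read_tsv_strict(path)
  need <- c("gene_a", "gene_b", "abs_r")
  if (!all(need %in% names(e))) {
    stop("edge list must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$gene_a, to = e$gene_b, weight = e$abs_r),
    directed = FALSE)
  structure(list(graph = g, threshold = threshold %||% min(e$abs_r),
                 species = species, selection = NULL),
            class = "coexpression_network")
}
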