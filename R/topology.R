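#' Kleinberg (HITS) hub scores
#'
#' On an undirected graph the HITS hub score is the principal eigenvector of
#' the adjacency matrix (hub and authority scores coincide). Scores are
#' computed by power iteration per connected component (tolerance 1e-10, at
#' most 1000 iterations), each component's eigenvector scaled by its leading
#' eigenvalue, and the whole vector normalized to maximum 1, so scores from
#' the dominant component dominate.
#'
#' By default the binary adjacency is used (edge weights ignored); set
#' `weighted = TRUE` to use `|r|` weights.
#'
#' @param net A non-empty `coexpression_network`.
#' @param weighted Use edge weights instead of the binary adjacency.
#' @param tol,max_iter Power-iteration controls.
#' @return Object of class `hub_score_table`: data frame with `gene`,
#'   `score` (max 1), `percentile` (rank percentile in `[0, 1]`).
#' @export
hits_hub_scores <- function(net, weighted = FALSE, tol = 1e-10,
                            max_iter = 1000) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network", call. = FALSE)
  A <- igraph::as_adjacency_matrix(
    g, sparse = FALSE, attr = if (weighted) "weight" else NULL)
  comp <- igraph::components(g)$membership
  score <- stats::setNames(numeric(nrow(A)), rownames(A))
  # a positive diagonal shift makes the Perron eigenvalue strictly dominant
  # (bipartite components otherwise oscillate between the +/- eigenpair)
  shift <- if (weighted) max(A) else 1
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    Ac <- A[idx, idx, drop = FALSE]
    diag(Ac) <- diag(Ac) + shift
    x <- rep(1 / sqrt(length(idx)), length(idx))
    lambda <- 0
    for (i in seq_len(max_iter)) {
      y <- drop(Ac %*% x)
      lambda <- sqrt(sum(y^2))
      if (lambda == 0) break
      y <- y / lambda
      if (max(abs(y - x)) < tol) {
        x <- y
        break
      }
      x <- y
    }
    score[idx] <- abs(x) * max(lambda - shift, 0)
  }
  score <- score / max(score)
  ord <- rank(score, ties.method = "average")
  structure(
    data.frame(gene = names(score), score = unname(score),
               percentile = unname(ord / length(score)),
               stringsAsFactors = FALSE),
    class = c("hub_score_table", "data.frame"))
}

#' Degree-based hub scores
#'
#' Alternative hub statistic: node degree normalized to maximum 1. Provided
#' because top-fraction hub calling is sometimes done on degree rather than
#' eigenvector-style scores.
#'
#' @inheritParams hits_hub_scores
#' @return A `hub_score_table` as in [hits_hub_scores()].
#' @export
degree_hub_scores <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network", call. = FALSE)
  deg <- igraph::degree(g)
  score <- deg / max(deg)
  structure(
    data.frame(gene = names(score), score = unname(score),
               percentile = unname(rank(score, ties.method = "average") /
                                     length(score)),
               stringsAsFactors = FALSE),
    class = c("hub_score_table", "data.frame"))
}

#' Call hubs as the top fraction of scores
#'
#' The hub count is `ceiling(fraction * n)`; all genes tied with the cutoff
#' score are included, so the hub set can exceed that count under ties.
#'
#' @param scores A `hub_score_table`.
#' @param fraction Top fraction to call (default 0.05, i.e. top 5%).
#' @return Character vector of hub gene ids.
#' @export
call_hubs <- function(scores, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(scores)
  k <- ceiling(fraction * n)
  cutoff <- sort(scores$score, decreasing = TRUE)[k]
  scores$gene[scores$score >= cutoff]
}

#' k-hop neighborhood of focal genes
#'
#' Breadth-first expansion: all genes whose shortest-path distance from any
#' seed is at most `k` edges. Seeds are members of their own neighborhood at
#' distance 0. Seeds absent from the network are reported with a warning;
#' if none are present, an error is raised.
#'
#' @param net A `coexpression_network`.
#' @param seeds Character vector of focal gene ids.
#' @param k Radius in edges (default 3).
#' @return Object of class `neighborhood`: data frame with `gene` and
#'   `distance` (`<= k`), plus attributes `seeds` and `k`.
#' @export
k_hop_neighborhood <- function(net, seeds, k = 3) {
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  present <- intersect(seeds, network_genes(net))
  absent <- setdiff(seeds, present)
  if (length(present) == 0) {
    stop("none of the seed genes are in the network", call. = FALSE)
  }
  if (length(absent) > 0) {
    warning("seed gene(s) absent from network: ",
            paste(absent, collapse = ", "))
  }
  d <- igraph::distances(net$graph, v = present)
  dmin <- apply(d, 2, min)
  keep <- dmin <= k
  out <- data.frame(gene = colnames(d)[keep],
                    distance = unname(dmin[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("neighborhood", "data.frame"),
            seeds = present, k = k)
}

#' Neighbor count (degree) of a gene
#'
#' @param net A `coexpression_network`.
#' @param gene Gene id; must be a connected node of the network.
#' @return Integer degree.
#' @export
neighbor_count <- function(net, gene) {
  if (!gene %in% network_genes(net)) {
    stop("gene not in network: ", gene, call. = FALSE)
  }
  unname(igraph::degree(net$graph, v = gene))
}
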