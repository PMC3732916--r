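#' Read an aligned FASTA of amino-acid sequences
#'
#' @param path Aligned FASTA; all sequences must have equal length and
#'   unique ids. Gaps are `-`.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  aln <- stats::setNames(as.character(ss), names(ss))
  validate_alignment(aln)
  aln
}

#' Write an alignment to FASTA
#' @param aln Named character vector of aligned sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  validate_alignment(aln)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln), path)
  invisible(path)
}

validate_alignment <- function(aln) {
  if (length(aln) < 2) stop("alignment needs >= 2 sequences", call. = FALSE)
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    stop("alignment sequence ids must be present and unique", call. = FALSE)
  }
  if (length(unique(nchar(aln))) != 1) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  invisible(aln)
}

#' Pairwise distances from a protein alignment
#'
#' The p-distance is the fraction of mismatched residues over pairwise
#' comparable columns (columns with a gap in either sequence are excluded
#' for that pair). The Poisson distance corrects for multiple hits:
#' `d = -ln(1 - p)`; saturated pairs (`p = 1`) are set to `poisson_cap`
#' with a warning.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param model `"p"` or `"poisson"`.
#' @param poisson_cap Distance assigned at saturation (default 5).
#' @return Symmetric numeric matrix with zero diagonal and a `model`
#'   attribute.
#' @export
pairwise_distance <- function(aln, model = c("p", "poisson"),
                              poisson_cap = 5) {
  model <- match.arg(model)
  validate_alignment(aln)
  ids <- names(aln)
  chars <- do.call(rbind, strsplit(unname(aln), ""))
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      n_ok <- sum(ok)
      if (n_ok == 0) {
        stop("no comparable sites between ", ids[i], " and ", ids[j],
             call. = FALSE)
      }
      p <- sum(chars[i, ok] != chars[j, ok]) / n_ok
      d <- if (model == "p") {
        p
      } else if (p >= 1) {
        warning("saturated pair ", ids[i], "/", ids[j],
                "; Poisson distance capped at ", poisson_cap)
        poisson_cap
      } else {
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "model") <- model
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining. Negative branch lengths, an
#' artifact of noisy distances, are clamped to zero with the deficit
#' transferred to the adjacent branch so leaf-to-leaf path lengths are
#' preserved where possible.
#'
#' @param D Symmetric non-negative distance matrix (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tree <- ape::nj(D)
  clamp_negative_branches(tree)
}

# set negative branch lengths to 0, moving the deficit to the adjacent edge
# (the other edge incident to the child node when one exists, else the
# sibling edge), preserving path lengths through the node
clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    adj <- which(tree$edge[, 1] == child)
    if (length(adj) == 0) {
      parent <- tree$edge[e, 1]
      adj <- setdiff(which(tree$edge[, 1] == parent), e)
    }
    if (length(adj) > 0) {
      tree$edge.length[adj[1]] <- max(tree$edge.length[adj[1]] + deficit, 0)
    }
  }
  tree
}

#' Bootstrap majority-rule consensus tree
#'
#' Resamples alignment columns with replacement, rebuilds a
#' neighbor-joining tree per replicate, and returns the majority-rule
#' consensus topology; node labels carry bootstrap support, the percentage
#' of replicates containing each internal bipartition.
#'
#' @param aln Named character vector of aligned sequences.
#' @param replicates Number of bootstrap replicates (>= 1; 1000 is the
#'   conventional default).
#' @param model Distance model, see [pairwise_distance()].
#' @param seed Integer seed for the column resampling.
#' @return An [ape::phylo] consensus tree with numeric node labels in
#'   `[0, 100]` (bootstrap support) and attribute `replicates`.
#' @export
bootstrap_consensus <- function(aln, replicates = 1000, model = "p",
                                seed = 1L) {
  validate_alignment(aln)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  chars <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(chars) <- names(aln)
  L <- ncol(chars)
  trees <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- stats::setNames(
        apply(chars[, cols, drop = FALSE], 1, paste, collapse = ""),
        names(aln))
      neighbor_joining(pairwise_distance(rep_aln, model = model))
    })
  })
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- replicates  # trivial (root) partition
  cons$node.label <- as.character(round(100 * counts / replicates, 1))
  attr(cons, "replicates") <- replicates
  cons
}

#' Write a tree as Newick
#' @param tree An [ape::phylo] tree.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a Newick tree
#' @param x Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  tree <- tryCatch(
    if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x),
    error = function(e) {
      stop("malformed Newick input: ", conditionMessage(e), call. = FALSE)
    })
  if (is.null(tree)) stop("malformed Newick input", call. = FALSE)
  tree
}
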