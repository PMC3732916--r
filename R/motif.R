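# IUPAC nucleotide codes and the base sets they match
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                      H = "D", V = "B", N = "N")

#' IUPAC motif pattern
#'
#' @param pattern Non-empty string over the IUPAC nucleotide alphabet
#'   (A, C, G, T, R, Y, S, W, K, M, B, D, H, V, N).
#' @param label Optional label (e.g. the binding-site name).
#' @return Object of class `motif_pattern`.
#' @export
motif_pattern <- function(pattern, label = pattern) {
  if (inherits(pattern, "motif_pattern")) return(pattern)
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0) stop("empty motif pattern", call. = FALSE)
  codes <- strsplit(pattern, "")[[1]]
  bad <- which(!codes %in% names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop("invalid IUPAC code '", codes[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  structure(list(pattern = pattern, label = label), class = "motif_pattern")
}

#' Reverse complement of an IUPAC sequence
#' @param seq Character scalar over the IUPAC alphabet.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  codes <- rev(strsplit(toupper(seq), "")[[1]])
  paste(IUPAC_COMPLEMENT[codes], collapse = "")
}

# regex character class per pattern code; a pattern N also accepts a subject
# N, any other code never matches subject N (conservative wildcard rule)
pattern_to_regex <- function(pattern) {
  codes <- strsplit(pattern, "")[[1]]
  paste(vapply(codes, function(cc) {
    set <- IUPAC_CODES[[cc]]
    if (cc == "N") set <- c(set, "N")
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Scan a DNA sequence for IUPAC motif matches
#'
#' Counts all (overlapping) matches of the motif on both strands. Degenerate
#' IUPAC codes in the pattern match their base sets; an `N` in the subject
#' sequence is matched only by a pattern `N`.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param pattern A [motif_pattern()] or IUPAC string.
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return List with `count` (total matches), `forward` (1-based start
#'   offsets on the given strand) and `reverse` (1-based start offsets on
#'   the reverse-complement strand, in its own 5'-to-3' coordinates).
#' @export
scan_sequence <- function(seq, pattern, both_strands = TRUE) {
  pat <- motif_pattern(pattern)
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop("invalid sequence character '", chars[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  }
  if (nchar(pat$pattern) > nchar(seq)) {
    return(list(count = 0L, forward = integer(0), reverse = integer(0)))
  }
  re <- paste0("(?=", pattern_to_regex(pat$pattern), ")")
  hit_starts <- function(s) {
    m <- gregexpr(re, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  fwd <- hit_starts(seq)
  rev_ <- if (both_strands) hit_starts(reverse_complement(seq)) else integer(0)
  list(count = length(fwd) + length(rev_), forward = fwd, reverse = rev_)
}

#' Motif presence table for target vs background promoters
#'
#' Counts, per group, the promoters containing at least one motif site
#' (presence, not site count). Target and background gene sets must be
#' disjoint and every gene must have a promoter record.
#'
#' @param promoters Named [Biostrings::DNAStringSet] or named character
#'   vector of promoter sequences.
#' @param target,background Disjoint character vectors of gene ids.
#' @param pattern A [motif_pattern()] or IUPAC string.
#' @return 2x2 integer matrix with rows `target`, `background` and columns
#'   `with_site`, `without_site`.
#' @export
presence_table <- function(promoters, target, background, pattern) {
  if (length(intersect(target, background)) > 0) {
    stop("target and background gene sets overlap", call. = FALSE)
  }
  seqs <- stats::setNames(as.character(promoters), names(promoters))
  missing <- setdiff(c(target, background), names(seqs))
  if (length(missing) > 0) {
    stop("genes without promoter records: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pat <- motif_pattern(pattern)
  has_site <- function(genes) {
    vapply(genes, function(g) scan_sequence(seqs[[g]], pat)$count > 0, TRUE)
  }
  t_hit <- sum(has_site(target))
  b_hit <- sum(has_site(background))
  matrix(c(t_hit, length(target) - t_hit,
           b_hit, length(background) - b_hit),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("target", "background"),
                         c("with_site", "without_site")))
}

#' Fisher's exact test for motif enrichment
#'
#' One-sided test of motif-presence over-representation in the target group
#' relative to background (hypergeometric tail of the 2x2 table).
#'
#' @param table 2x2 matrix as from [presence_table()] (rows target and
#'   background, columns with/without site).
#' @param label Motif label carried into the result.
#' @return Object of class `motif_enrichment`: list with `label`,
#'   `target_n`, `target_hits`, `target_fraction`, `background_n`,
#'   `background_hits`, `background_fraction`, `p`.
#' @export
fisher_enrichment <- function(table, label = NA_character_) {
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    stop("`table` must be a non-negative 2x2 matrix", call. = FALSE)
  }
  t_n <- sum(table[1, ]); b_n <- sum(table[2, ])
  if (t_n == 0 || b_n == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  p <- stats::fisher.test(table, alternative = "greater")$p.value
  structure(list(label = label,
                 target_n = t_n, target_hits = table[1, 1],
                 target_fraction = table[1, 1] / t_n,
                 background_n = b_n, background_hits = table[2, 1],
                 background_fraction = table[2, 1] / b_n,
                 p = p),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf(
    "motif_enrichment%s: %.1f%% of %d target vs %.1f%% of %d background (one-sided Fisher p = %.4g)\n",
    if (!is.na(x$label)) paste0(" [", x$label, "]") else "",
    100 * x$target_fraction, x$target_n,
    100 * x$background_fraction, x$background_n, x$p))
  invisible(x)
}
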