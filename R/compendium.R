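#' Expression compendium container
#'
#' An expression compendium is a non-negative gene-by-sample matrix (FPKM for
#' RNA-seq-like data, normalized intensities for microarray-like data)
#' together with per-sample metadata linking each condition to its control.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be `>= 0`.
#' @param metadata Data frame with columns `sample_id`, `condition`,
#'   `control_condition` (the condition serving as control for this sample's
#'   condition; a control condition references itself), `is_control`
#'   (logical) and `platform`.
#' @param species Optional species tag (character scalar).
#' @param truth Optional list describing planted structure when the
#'   compendium is synthetic (see [generate_compendium()]); `NULL` for real
#'   data.
#' @return An object of class `expression_compendium`.
#' @seealso [read_expression_table()], [generate_compendium()]
#' @export
expression_compendium <- function(values, metadata, species = NA_character_,
                                  truth = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    stop("duplicated gene ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  need <- c("sample_id", "condition", "control_condition", "is_control")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    stop("metadata lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(colnames(values), metadata$sample_id)
  if (length(absent) > 0) {
    stop("samples missing from metadata: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  bad_ctrl <- setdiff(metadata$control_condition, metadata$condition)
  if (length(bad_ctrl) > 0) {
    stop("control conditions not present in metadata: ",
         paste(unique(bad_ctrl), collapse = ", "), call. = FALSE)
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(
    list(values = values, metadata = metadata, species = species,
         truth = truth),
    class = "expression_compendium"
  )
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("expression_compendium: %d genes x %d samples (%d conditions)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$metadata$condition))))
  if (!is.na(x$species)) cat("  species:", x$species, "\n")
  if (!is.null(x$truth)) {
    cat(sprintf("  synthetic truth: %d modules, %d hub genes\n",
                length(x$truth$modules), length(x$truth$hub_genes)))
  }
  invisible(x)
}

#' @export
dim.expression_compendium <- function(x) dim(x$values)

#' Gene ids of a compendium
#' @param x An `expression_compendium`.
#' @return Character vector of gene ids.
#' @export
genes <- function(x) UseMethod("genes")

#' @export
genes.expression_compendium <- function(x) rownames(x$values)

#' Read an expression compendium from TSV files
#'
#' The expression table has one header row of sample ids, one row per gene,
#' first column `gene`. The metadata table has columns `sample_id`,
#' `condition`, `control_condition`, `is_control`, `platform`.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample-metadata TSV.
#' @param species Optional species tag.
#' @return An [expression_compendium()].
#' @export
read_expression_table <- function(path, metadata_path, species = NA_character_) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2) stop("expression table needs a gene column and >=1 sample",
                          call. = FALSE)
  gene_ids <- as.character(tab[[1]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("duplicated gene ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  meta <- read_tsv_strict(metadata_path)
  if ("is_control" %in% names(meta)) {
    meta$is_control <- as.logical(meta$is_control)
  }
  expression_compendium(values, meta, species = species)
}

#' Write an expression compendium to TSV files
#'
#' Inverse of [read_expression_table()]; `read(write(x))` reproduces the
#' matrix and metadata exactly.
#'
#' @param compendium An `expression_compendium`.
#' @param path Output path for the expression TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(compendium, path, metadata_path) {
  df <- data.frame(gene = rownames(compendium$values),
                   compendium$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  write_tsv_plain(compendium$metadata, metadata_path)
  invisible(path)
}

#' Derive condition-vs-control contrasts from sample metadata
#'
#' One contrast per non-control condition, pairing its samples with the
#' samples of its declared control condition.
#'
#' @param compendium An `expression_compendium`.
#' @return A list of contrasts, each a list with `condition`, `control`,
#'   `condition_samples`, `control_samples`.
#' @export
contrasts_from_metadata <- function(compendium) {
  md <- compendium$metadata
  conds <- unique(md$condition[!md$is_control])
  lapply(conds, function(cc) {
    ctrl <- unique(md$control_condition[md$condition == cc])
    if (length(ctrl) != 1) {
      stop("condition ", cc, " references multiple controls", call. = FALSE)
    }
    list(condition = cc, control = ctrl,
         condition_samples = md$sample_id[md$condition == cc],
         control_samples = md$sample_id[md$condition == ctrl])
  })
}
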