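#' Validate a pipeline configuration
#'
#' A configuration is a nested list (typically read from YAML with
#' [read_pipeline_config()]) with elements:
#' \describe{
#'   \item{species}{List of per-species entries, each with `name`,
#'     `expression`, `metadata`, `annotation` (file paths), `focal_genes`
#'     (path to a one-id-per-line file), and optionally `markers` (TSV with
#'     columns `gene`, `label`).}
#'   \item{params}{Optional overrides: `fold_threshold`, `z_threshold`,
#'     `pseudocount`, `grid` (list `from`, `to`, `by`), `target_degree`,
#'     `band` (length 2), `hub_fraction`, `k`, `q_cutoff`.}
#'   \item{species_order}{Optional evolutionary order for the cross-species
#'     comparison; defaults to input order.}
#'   \item{out_dir, seed}{Output directory and integer seed.}
#' }
#'
#' @param config Configuration list.
#' @return Character vector of violated constraints; empty when runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  if (is.null(config$species) || length(config$species) == 0) {
    note("no species entries")
  }
  for (sp in config$species) {
    nm <- sp$name %||% "<unnamed>"
    if (is.null(sp$name)) note("species entry without a name")
    for (f in c("expression", "metadata", "annotation", "focal_genes")) {
      if (is.null(sp[[f]])) {
        note("species ", nm, ": missing `", f, "` path")
      } else if (!file.exists(sp[[f]])) {
        note("species ", nm, ": file not found: ", sp[[f]])
      }
    }
    if (!is.null(sp$markers) && !file.exists(sp$markers)) {
      note("species ", nm, ": file not found: ", sp$markers)
    }
  }
  p <- config$params %||% list()
  chk_pos <- function(name) {
    if (!is.null(p[[name]]) && p[[name]] <= 0) {
      note("params$", name, " must be > 0")
    }
  }
  chk_pos("fold_threshold"); chk_pos("z_threshold"); chk_pos("target_degree")
  if (!is.null(p$pseudocount) && p$pseudocount < 0) {
    note("params$pseudocount must be >= 0")
  }
  if (!is.null(p$hub_fraction) &&
      (p$hub_fraction <= 0 || p$hub_fraction >= 1)) {
    note("params$hub_fraction must be in (0, 1)")
  }
  if (!is.null(p$k) && p$k < 0) note("params$k must be >= 0")
  if (!is.null(p$band)) {
    b <- unlist(p$band)
    if (length(b) != 2 || b[1] > b[2]) {
      note("params$band must be an ascending pair")
    }
  }
  if (!is.null(p$grid)) {
    g <- p$grid
    if (any(vapply(c("from", "to", "by"), function(k) is.null(g[[k]]), TRUE)) ||
        g$from >= g$to || g$by <= 0 || g$from <= 0 || g$to >= 1) {
      note("params$grid must define 0 < from < to < 1 with by > 0")
    }
  }
  if (!is.null(p$q_cutoff) && (p$q_cutoff <= 0 || p$q_cutoff > 1)) {
    note("params$q_cutoff must be in (0, 1]")
  }
  if (!is.null(config$species_order)) {
    nms <- vapply(config$species, function(s) s$name %||% "", "")
    if (!setequal(config$species_order, nms)) {
      note("species_order does not match species names")
    }
  }
  problems
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

pipeline_defaults <- function() {
  list(fold_threshold = 2, z_threshold = 2, pseudocount = 1,
       grid = list(from = 0.50, to = 0.99, by = 0.01),
       target_degree = 20, band = c(15, 25), hub_fraction = 0.05, k = 3,
       q_cutoff = 0.05)
}

#' Run the full co-expression pipeline
#'
#' For every species: differential-gene selection, correlation matrix,
#' automatic threshold selection, network construction and export, hub
#' scoring and calling, k-hop neighborhood of the focal genes, GO-term
#' enrichment of the neighborhood against the annotation universe; then a
#' cross-species term-conservation comparison. All stage outputs are TSVs
#' under `out_dir/<species>/`, and a JSON run manifest records the package
#' version, configuration hash, seed, per-file checksums and warnings.
#'
#' @param config Configuration list or path to a YAML file (see
#'   [validate_config()]).
#' @param seed Optional seed overriding `config$seed`.
#' @param out_dir Optional output directory overriding `config$out_dir`.
#' @return Invisibly, the manifest list (also written as
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  seed <- seed %||% config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- seq(params$grid$from, params$grid$to, by = params$grid$by)
  band <- unlist(params$band)
  warnings_log <- character(0)
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  outputs <- character(0)
  save_tsv <- function(df, ...) {
    path <- file.path(out_dir, ...)
    write_tsv_plain(df, path)
    outputs <<- c(outputs, path)
    path
  }

  enrich_tables <- list()
  stage <- "setup"
  result <- withCallingHandlers(tryCatch({
    for (sp in config$species) {
      spd <- file.path(out_dir, sp$name)
      dir.create(spd, recursive = TRUE, showWarnings = FALSE)
      stage <- paste0(sp$name, ":load")
      comp <- read_expression_table(sp$expression, sp$metadata,
                                    species = sp$name)
      annot <- read_annotation_table(sp$annotation,
                                     universe = genes(comp))
      focal <- readLines(sp$focal_genes)
      focal <- focal[nzchar(focal)]

      stage <- paste0(sp$name, ":differential")
      deg <- select_differential(comp, fold_threshold = params$fold_threshold,
                                 z_threshold = params$z_threshold,
                                 pseudocount = params$pseudocount)
      save_tsv(deg$table, sp$name, "deg.tsv")

      stage <- paste0(sp$name, ":network")
      corr <- correlation_matrix(comp, deg_genes(deg))
      sel <- select_threshold(corr, grid = grid,
                              target_mean_degree = params$target_degree,
                              band = band)
      save_tsv(sel$scan, sp$name, "threshold_scan.tsv")
      net <- build_network(corr, sel$threshold, species = sp$name,
                           selection = sel)
      export_network(net, file.path(spd, "network.tsv"), "tsv")
      export_network(net, file.path(spd, "network.sif"), "sif")
      outputs <- c(outputs, file.path(spd, "network.tsv"),
                   file.path(spd, "network.sif"))

      stage <- paste0(sp$name, ":topology")
      scores <- hits_hub_scores(net)
      hubs <- call_hubs(scores, params$hub_fraction)
      scores$hub <- scores$gene %in% hubs
      save_tsv(scores, sp$name, "hubs.tsv")
      nb <- k_hop_neighborhood(net, focal, k = params$k)
      save_tsv(nb, sp$name, "neighborhood.tsv")

      stage <- paste0(sp$name, ":enrichment")
      et <- hypergeometric_enrichment(nb$gene, annot)
      save_tsv(et, sp$name, "enrichment.tsv")
      enrich_tables[[sp$name]] <- et

      if (!is.null(sp$markers)) {
        stage <- paste0(sp$name, ":markers")
        mk <- read_tsv_strict(sp$markers)
        mc <- marker_correlation(comp, intersect(focal, genes(comp)), mk)
        mc_df <- data.frame(gene = rownames(mc), as.data.frame(unclass(mc)),
                            check.names = FALSE)
        if (nrow(mc) >= 2) {
          mc_df$group <- cluster_focal_groups(mc)[mc_df$gene]
        }
        save_tsv(mc_df, sp$name, "marker_correlation.tsv")
      }
    }
    stage <- "cross_species"
    if (length(enrich_tables) >= 2) {
      order_ <- config$species_order %||% names(enrich_tables)
      cmp <- compare_across_species(enrich_tables, species_order = order_,
                                    q_cutoff = params$q_cutoff)
      save_tsv(cmp, "term_comparison.tsv")
    }
    TRUE
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  }), warning = log_warning)

  manifest <- list(
    package = "coexflow",
    version = as.character(utils::packageVersion("coexflow")),
    seed = seed,
    config_hash = object_md5(config[c("species", "params", "species_order")]),
    params = params,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)),
      sub(paste0("^", gsub("([\\W])", "\\\\\\1", out_dir, perl = TRUE), "/?"),
          "", outputs))),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
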