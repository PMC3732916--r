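#' Specify a synthetic multi-condition expression compendium
#'
#' Describes the statistical structure of a simulated compendium: a set of
#' co-expression modules whose genes share a condition-response signal, an
#' optional set of hub genes bridging several modules, and uncorrelated (or
#' weakly correlated) background genes. Within-module correlation is induced
#' by adding gene-specific Gaussian noise to the shared module signal; the
#' target correlation rho maps analytically to the noise variance through
#' rho = var(signal) / (var(signal) + var(noise)).
#'
#' @param n_genes Total number of genes (modules + hubs + background).
#' @param n_conditions Number of non-control conditions; a single shared
#'   control condition is added automatically.
#' @param replicates_per_condition Replicates per condition (and control).
#' @param modules List of module descriptions, each a list with
#'   `module_id`, `gene_count`, `within_correlation` (target pairwise
#'   absolute Pearson correlation, in (0, 1]), `annotation_terms` (character),
#'   and optionally `conditions` (indices of responsive conditions; by
#'   default conditions are dealt round-robin so modules respond to disjoint
#'   sets).
#' @param background_correlation Pairwise correlation among background genes,
#'   in `[0, 1)`; must be below every module's `within_correlation`.
#' @param hub_spec List of hub descriptions, each a list with `gene` (id) and
#'   `modules` (character vector of bridged module ids). A hub's profile is
#'   the average of its modules' signals plus noise.
#' @param noise_sd Standard deviation of background-gene noise, in expression
#'   units.
#' @param baseline_expression Baseline expression level (FPKM-like units).
#' @param fold_change_range Length-2 numeric, the range responsive-condition
#'   fold changes are drawn from (uniformly). Must be `>= 1`.
#' @param p_down Probability that a responsive condition is down- rather than
#'   up-regulated (down uses `baseline / fc`). The balanced default (0.5)
#'   keeps module profiles centred near baseline, which decorrelates
#'   modules responding to disjoint condition sets; up-only responses
#'   (`p_down = 0`) leave disjoint modules strongly anti-correlated through
#'   their shared baseline samples.
#' @param seed Integer seed; a fixed seed makes [generate_compendium()]
#'   bit-reproducible.
#' @return A validated object of class `compendium_spec`.
#' @export
compendium_spec <- function(n_genes, n_conditions, replicates_per_condition,
                            modules, background_correlation = 0,
                            hub_spec = list(), noise_sd = 1,
                            baseline_expression = 10,
                            fold_change_range = c(2, 6), p_down = 0.5,
                            seed = 1L) {
  spec <- structure(
    list(n_genes = as.integer(n_genes),
         n_conditions = as.integer(n_conditions),
         replicates_per_condition = as.integer(replicates_per_condition),
         modules = modules,
         background_correlation = background_correlation,
         hub_spec = hub_spec,
         noise_sd = noise_sd,
         baseline_expression = baseline_expression,
         fold_change_range = as.numeric(fold_change_range),
         p_down = p_down,
         seed = as.integer(seed)),
    class = "compendium_spec"
  )
  validate_compendium_spec(spec)
  spec
}

validate_compendium_spec <- function(spec) {
  fail <- function(...) stop("invalid compendium spec: ", ..., call. = FALSE)
  if (spec$n_genes < 1) fail("n_genes must be >= 1")
  if (spec$n_conditions < 1) fail("n_conditions must be >= 1")
  if (spec$replicates_per_condition < 1) {
    fail("replicates_per_condition must be >= 1")
  }
  if (length(spec$modules) == 0) fail("at least one module is required")
  ids <- vapply(spec$modules, function(m) as.character(m$module_id), "")
  if (anyDuplicated(ids)) fail("duplicated module ids")
  n_mod_genes <- sum(vapply(spec$modules, function(m) as.integer(m$gene_count),
                            1L))
  if (n_mod_genes + length(spec$hub_spec) > spec$n_genes) {
    fail("module gene counts plus hub genes exceed n_genes (",
         n_mod_genes + length(spec$hub_spec), " > ", spec$n_genes, ")")
  }
  for (m in spec$modules) {
    rho <- m$within_correlation
    if (!is.numeric(rho) || rho <= 0 || rho > 1) {
      fail("within_correlation of module ", m$module_id,
           " must be in (0, 1]")
    }
    if (rho <= spec$background_correlation) {
      fail("within_correlation of module ", m$module_id,
           " must exceed background_correlation")
    }
  }
  if (spec$background_correlation < 0 || spec$background_correlation >= 1) {
    fail("background_correlation must be in [0, 1)")
  }
  for (h in spec$hub_spec) {
    unknown <- setdiff(h$modules, ids)
    if (length(unknown) > 0) {
      fail("hub ", h$gene, " bridges unknown modules: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (spec$noise_sd < 0) fail("noise_sd must be >= 0")
  if (spec$baseline_expression <= 0) fail("baseline_expression must be > 0")
  fr <- spec$fold_change_range
  if (length(fr) != 2 || any(fr < 1) || fr[1] > fr[2]) {
    fail("fold_change_range must be an ascending pair of values >= 1")
  }
  if (spec$p_down < 0 || spec$p_down > 1) fail("p_down must be in [0, 1]")
  invisible(spec)
}

# Round-robin assignment of condition indices to modules (disjoint sets when
# n_conditions >= n_modules).
default_module_conditions <- function(n_conditions, n_modules) {
  assign <- rep(seq_len(n_modules), length.out = n_conditions)
  lapply(seq_len(n_modules), function(i) which(assign == i))
}

#' Generate a synthetic expression compendium
#'
#' Simulates a non-negative gene-by-sample matrix with the structure declared
#' in a [compendium_spec()]: genes in a module share a condition-response
#' signal (responsive conditions change expression by a fold change drawn
#' from `fold_change_range`) plus gene-specific Gaussian noise calibrated so
#' pairwise correlation matches `within_correlation`; hub genes average the
#' signals of the modules they bridge; background genes fluctuate around
#' baseline with pairwise correlation `background_correlation`. Values are
#' floored at zero. Output is bit-reproducible for a fixed spec.
#'
#' @param spec A [compendium_spec()].
#' @param species Optional species tag stored on the result.
#' @return An [expression_compendium()] whose `truth` element records the
#'   planted structure: per-module gene ids, responsive conditions and fold
#'   changes, hub gene ids, and the differentially expressed gene set.
#' @export
generate_compendium <- function(spec, species = NA_character_) {
  validate_compendium_spec(spec)
  with_seed(spec$seed, {
    n_mod <- length(spec$modules)
    reps <- spec$replicates_per_condition
    conds <- sprintf("cond%02d", seq_len(spec$n_conditions))
    all_conds <- c("control", conds)
    sample_cond <- rep(all_conds, each = reps)
    sample_ids <- paste0(sample_cond, "_r", rep(seq_len(reps),
                                                times = length(all_conds)))
    n_samp <- length(sample_ids)

    mod_conditions <- lapply(seq_along(spec$modules), function(i) {
      spec$modules[[i]]$conditions %||%
        default_module_conditions(spec$n_conditions, n_mod)[[i]]
    })

    # condition-level mean expression per module
    base <- spec$baseline_expression
    signals <- matrix(base, nrow = n_mod, ncol = length(all_conds),
                      dimnames = list(NULL, all_conds))
    fold_changes <- vector("list", n_mod)
    for (i in seq_len(n_mod)) {
      ci <- mod_conditions[[i]]
      fc <- stats::runif(length(ci), spec$fold_change_range[1],
                         spec$fold_change_range[2])
      down <- stats::runif(length(ci)) < spec$p_down
      mu <- ifelse(down, base / fc, base * fc)
      signals[i, conds[ci]] <- mu
      fold_changes[[i]] <- data.frame(condition = conds[ci], fold_change = fc,
                                      direction = ifelse(down, "down", "up"),
                                      stringsAsFactors = FALSE)
    }
    signal_samples <- signals[, sample_cond, drop = FALSE]

    gene_pool <- sprintf("g%05d", seq_len(spec$n_genes))
    values <- matrix(0, nrow = spec$n_genes, ncol = n_samp,
                     dimnames = list(gene_pool, sample_ids))
    next_gene <- 1L
    take_genes <- function(k) {
      ids <- gene_pool[next_gene:(next_gene + k - 1L)]
      next_gene <<- next_gene + k
      ids
    }

    module_genes <- list()
    for (i in seq_len(n_mod)) {
      m <- spec$modules[[i]]
      ids <- take_genes(as.integer(m$gene_count))
      module_genes[[as.character(m$module_id)]] <- ids
      s <- signal_samples[i, ]
      sig_var <- stats::var(s)
      rho <- m$within_correlation
      sd_e <- if (rho >= 1 || sig_var == 0) 0 else
        sqrt(sig_var * (1 - rho) / rho)
      for (g in ids) {
        scale_g <- stats::runif(1, 0.5, 2)
        values[g, ] <- scale_g * (s + stats::rnorm(n_samp, 0, sd_e))
      }
    }

    hub_genes <- character(0)
    if (length(spec$hub_spec) > 0) {
      mod_ids <- vapply(spec$modules, function(m) as.character(m$module_id), "")
      for (h in spec$hub_spec) {
        g <- as.character(h$gene)
        # hub ids live outside the sequential pool; claim a pool slot and rename
        slot <- take_genes(1L)
        rownames(values)[rownames(values) == slot] <- g
        idx <- match(h$modules, mod_ids)
        s <- colMeans(signal_samples[idx, , drop = FALSE])
        rho <- mean(vapply(spec$modules[idx],
                           function(m) m$within_correlation, 1.0))
        sig_var <- stats::var(s)
        sd_e <- if (rho >= 1 || sig_var == 0) 0 else
          sqrt(sig_var * (1 - rho) / rho)
        scale_g <- stats::runif(1, 0.5, 2)
        values[g, ] <- scale_g * (s + stats::rnorm(n_samp, 0, sd_e))
        hub_genes <- c(hub_genes, g)
      }
    }

    n_bg <- spec$n_genes - (next_gene - 1L)
    background_genes <- character(0)
    if (n_bg > 0) {
      background_genes <- take_genes(n_bg)
      bc <- spec$background_correlation
      z_common <- stats::rnorm(n_samp)
      for (g in background_genes) {
        z <- sqrt(bc) * z_common + sqrt(1 - bc) * stats::rnorm(n_samp)
        values[g, ] <- base + spec$noise_sd * z
      }
    }

    values[values < 0] <- 0

    metadata <- data.frame(
      sample_id = sample_ids,
      condition = sample_cond,
      control_condition = "control",
      is_control = sample_cond == "control",
      platform = "rnaseq",
      stringsAsFactors = FALSE
    )

    truth <- list(
      spec = spec,
      modules = module_genes,
      module_conditions = stats::setNames(mod_conditions,
                                          names(module_genes)),
      fold_changes = stats::setNames(fold_changes, names(module_genes)),
      hub_genes = hub_genes,
      hub_modules = stats::setNames(
        lapply(spec$hub_spec, function(h) as.character(h$modules)),
        hub_genes),
      background_genes = background_genes,
      differential_genes = c(unlist(module_genes, use.names = FALSE),
                             hub_genes)
    )
    expression_compendium(values, metadata, species = species, truth = truth)
  })
}

#' Generate GO-style annotations for a synthetic compendium
#'
#' Module genes (and hub genes, for every module they bridge) receive their
#' module's annotation terms; background genes receive random terms from the
#' term pool, each term independently with probability
#' `terms_per_gene_noise`.
#'
#' @param compendium A synthetic [expression_compendium()] carrying `truth`.
#' @param terms_per_gene_noise Per-term annotation probability for background
#'   genes, in `[0, 1]`.
#' @param term_pool Character vector of terms background noise draws from;
#'   defaults to the union of all module terms.
#' @param seed Seed for the noise draws; defaults to the compendium's own
#'   generation seed + 1.
#' @return A [go_annotation()] whose universe is all compendium genes.
#' @export
generate_annotations <- function(compendium, terms_per_gene_noise = 0,
                                 term_pool = NULL, seed = NULL) {
  truth <- compendium$truth
  if (is.null(truth)) {
    stop("generate_annotations needs a synthetic compendium with `truth`",
         call. = FALSE)
  }
  if (terms_per_gene_noise < 0 || terms_per_gene_noise > 1) {
    stop("terms_per_gene_noise must be in [0, 1]", call. = FALSE)
  }
  spec <- truth$spec
  mod_terms <- lapply(spec$modules, function(m) as.character(m$annotation_terms))
  names(mod_terms) <- vapply(spec$modules, function(m)
    as.character(m$module_id), "")
  pool <- term_pool %||% unique(unlist(mod_terms, use.names = FALSE))
  seed <- seed %||% (spec$seed + 1L)

  pairs <- list()
  for (mid in names(truth$modules)) {
    terms <- mod_terms[[mid]]
    if (length(terms) == 0) next
    pairs[[mid]] <- expand.grid(gene = truth$modules[[mid]], term = terms,
                                stringsAsFactors = FALSE)
  }
  for (h in truth$hub_genes) {
    terms <- unique(unlist(mod_terms[truth$hub_modules[[h]]]))
    if (length(terms) == 0) next
    pairs[[paste0("hub_", h)]] <- data.frame(gene = h, term = terms,
                                             stringsAsFactors = FALSE)
  }
  noise <- with_seed(seed, {
    if (terms_per_gene_noise > 0 && length(truth$background_genes) > 0 &&
        length(pool) > 0) {
      hit <- matrix(stats::runif(length(truth$background_genes) *
                                   length(pool)) < terms_per_gene_noise,
                    nrow = length(truth$background_genes))
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        data.frame(gene = truth$background_genes[idx[, 1]],
                   term = pool[idx[, 2]], stringsAsFactors = FALSE)
      }
    }
  })
  mapping <- do.call(rbind, c(pairs, list(noise)))
  if (is.null(mapping)) {
    mapping <- data.frame(gene = character(0), term = character(0))
  }
  rownames(mapping) <- NULL
  go_annotation(mapping, universe = genes(compendium))
}

#' Generate promoter sequences with planted motif sites
#'
#' Promoters are i.i.d. uniform A/C/G/T backgrounds. Each target gene's
#' promoter receives one planted instance of the motif with probability
#' `rate_target` (background genes with `rate_background`), at a uniform
#' random position and strand. Chance matches in the background sequence are
#' possible and deliberately not removed.
#'
#' @param genes Character vector of gene ids.
#' @param target_genes Subset of `genes` treated as motif targets.
#' @param motif IUPAC motif string (see [motif_pattern()]).
#' @param length Promoter length in bp (default 1000).
#' @param rate_target,rate_background Planting probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet] of promoters.
#' @export
generate_promoters <- function(genes, target_genes, motif, length = 1000,
                               rate_target = 1, rate_background = 0,
                               seed = 1L) {
  pat <- motif_pattern(motif)
  if (nchar(pat$pattern) > length) {
    stop("motif is longer than the promoter length", call. = FALSE)
  }
  if (rate_target < 0 || rate_target > 1 ||
      rate_background < 0 || rate_background > 1) {
    stop("planting rates must be in [0, 1]", call. = FALSE)
  }
  stray <- setdiff(target_genes, genes)
  if (length(stray) > 0) {
    stop("target genes not in `genes`: ", paste(stray, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(genes, function(g) {
      s <- sample(bases, length, replace = TRUE)
      rate <- if (g %in% target_genes) rate_target else rate_background
      if (stats::runif(1) < rate) {
        inst <- sample_iupac_instance(pat$pattern)
        if (stats::runif(1) < 0.5) inst <- reverse_complement(inst)
        pos <- sample.int(length - nchar(inst) + 1L, 1)
        s[pos:(pos + nchar(inst) - 1L)] <- strsplit(inst, "")[[1]]
      }
      paste(s, collapse = "")
    }, "")
    Biostrings::DNAStringSet(stats::setNames(seqs, genes))
  })
}

# one concrete realisation of an IUPAC pattern
sample_iupac_instance <- function(pattern) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(codes, function(cc) {
    opts <- IUPAC_CODES[[cc]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, ""), collapse = "")
}

#' Simulate amino-acid sequences along a phylogeny
#'
#' Evolves a root sequence down a tree under a 20-state symmetric
#' (Jukes-Cantor-like) substitution process: along a branch of length `t`
#' (expected substitutions per site, scaled by `rate`) each site changes with
#' probability `(19/20) * (1 - exp(-20/19 * rate * t))`, to a uniformly
#' chosen different residue. In the short-branch limit the expected
#' p-distance between two leaves approaches their path length.
#'
#' @param tree An [ape::phylo] tree with non-negative branch lengths.
#' @param seq_length Number of alignment columns.
#' @param rate Rate multiplier applied to branch lengths (default 1).
#' @param seed Integer seed.
#' @return Named character vector of equal-length leaf sequences (an
#'   alignment; the simulation introduces no gaps).
#' @export
evolve_alignment <- function(tree, seq_length, rate = 1, seed = 1L) {
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", max(tree$edge))
    seqs[[root]] <- sample(aa, seq_length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_len <- tree$edge.length[e] * rate
      p_change <- (19 / 20) * (1 - exp(-(20 / 19) * t_len))
      s <- seqs[[parent]]
      hit <- which(stats::runif(seq_length) < p_change)
      for (i in hit) s[i] <- sample(setdiff(aa, s[i]), 1)
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                  "")
    stats::setNames(out, tree$tip.label)
  })
}
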