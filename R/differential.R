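#' Log expression and its delta-method variance
#'
#' Computes `ln(mean + pseudocount)` of a replicate vector and the
#' delta-method approximation to the variance of the log,
#' `Var(ln X) ~ Var(X) / (mean + pseudocount)^2`, with `Var(X)` the sample
#' variance across replicates. With a single replicate the sample variance is
#' undefined; a Poisson-like fallback `Var(X) = mean(X)` is used (common for
#' unreplicated count-derived expression), or 0 when the fallback is
#' disabled.
#'
#' @param values Non-negative replicate expression values (length >= 1).
#' @param pseudocount Added to the mean before taking logs (guards `log(0)`).
#' @param single_replicate_fallback Use `Var = mean` when only one replicate
#'   is available.
#' @return List with `log_mean` and `variance`.
#' @export
log_mean_and_variance <- function(values, pseudocount = 1,
                                  single_replicate_fallback = TRUE) {
  if (length(values) == 0) stop("empty replicate vector", call. = FALSE)
  if (any(values < 0)) stop("expression values must be >= 0", call. = FALSE)
  m <- mean(values) + pseudocount
  if (m <= 0) stop("mean + pseudocount must be positive", call. = FALSE)
  v <- if (length(values) > 1) {
    stats::var(values)
  } else if (single_replicate_fallback) {
    mean(values)
  } else {
    0
  }
  list(log_mean = log(m), variance = v / m^2)
}

#' Select differentially expressed genes
#'
#' For every gene and every condition-vs-control contrast, the natural-log
#' expression ratio and its delta-method variance are computed; a gene is
#' selected when at least one contrast satisfies both the fold-change
#' criterion `|log ratio| >= ln(fold_threshold)` and the significance
#' criterion `|z| >= z_threshold` with
#' `z = log_ratio / sqrt(var_condition + var_control)`. When both variances
#' are zero (noise-free data) the z criterion is treated as passed provided
#' the ratio criterion holds. Both boundaries are inclusive.
#'
#' @param compendium An [expression_compendium()].
#' @param contrasts List of contrasts as produced by
#'   [contrasts_from_metadata()]; defaults to all condition-vs-control
#'   contrasts in the metadata.
#' @param fold_threshold Fold-change cutoff (default 2).
#' @param z_threshold z cutoff (default 2, roughly two-sided 95%).
#' @param pseudocount Passed to [log_mean_and_variance()].
#' @param single_replicate_fallback Passed to [log_mean_and_variance()].
#' @return An object of class `deg_result`: a list with `table` (one row per
#'   gene: `gene`, `best_contrast`, `log2fc`, `z`, `selected`) and `detail`
#'   (per-contrast long data frame).
#' @export
select_differential <- function(compendium, contrasts = NULL,
                                fold_threshold = 2, z_threshold = 2,
                                pseudocount = 1,
                                single_replicate_fallback = TRUE) {
  contrasts <- contrasts %||% contrasts_from_metadata(compendium)
  if (length(contrasts) == 0) stop("no contrasts available", call. = FALSE)
  vals <- compendium$values
  missing_samples <- setdiff(
    unlist(lapply(contrasts, function(ct)
      c(ct$condition_samples, ct$control_samples))),
    colnames(vals))
  if (length(missing_samples) > 0) {
    stop("contrast samples absent from compendium: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  log_fold <- log(fold_threshold)
  eps <- 1e-12  # inclusive boundaries up to floating-point noise

  detail <- do.call(rbind, lapply(contrasts, function(ct) {
    cond <- vals[, ct$condition_samples, drop = FALSE]
    ctrl <- vals[, ct$control_samples, drop = FALSE]
    stat_side <- function(m) {
      mu <- rowMeans(m) + pseudocount
      v <- if (ncol(m) > 1) {
        apply(m, 1, stats::var)
      } else if (single_replicate_fallback) {
        rowMeans(m)
      } else {
        rep(0, nrow(m))
      }
      list(log_mean = log(mu), variance = v / mu^2)
    }
    a <- stat_side(cond); b <- stat_side(ctrl)
    log_ratio <- a$log_mean - b$log_mean
    var_sum <- a$variance + b$variance
    z <- ifelse(var_sum > 0, log_ratio / sqrt(var_sum), NA_real_)
    pass_fold <- abs(log_ratio) >= log_fold - eps
    pass_z <- ifelse(var_sum > 0, abs(z) >= z_threshold - eps, pass_fold)
    data.frame(gene = rownames(vals), contrast = ct$condition,
               log_ratio = log_ratio, variance = var_sum, z = z,
               pass = pass_fold & pass_z, stringsAsFactors = FALSE,
               row.names = NULL)
  }))

  # best contrast per gene: largest |log ratio|
  sel <- tapply(detail$pass, detail$gene, any)
  best_idx <- tapply(seq_len(nrow(detail)), detail$gene, function(ii) {
    ii[which.max(abs(detail$log_ratio[ii]))]
  })
  gene_order <- rownames(vals)
  best_idx <- best_idx[gene_order]
  table <- data.frame(
    gene = gene_order,
    best_contrast = detail$contrast[best_idx],
    log2fc = detail$log_ratio[best_idx] / log(2),
    z = detail$z[best_idx],
    selected = unname(sel[gene_order]),
    stringsAsFactors = FALSE
  )
  structure(list(table = table, detail = detail,
                 fold_threshold = fold_threshold, z_threshold = z_threshold,
                 pseudocount = pseudocount),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("deg_result: %d / %d genes selected (fold >= %g, |z| >= %g)\n",
              sum(x$table$selected), nrow(x$table), x$fold_threshold,
              x$z_threshold))
  invisible(x)
}

#' Selected gene ids of a `deg_result`
#' @param x A `deg_result`.
#' @return Character vector of selected gene ids.
#' @export
deg_genes <- function(x) {
  stopifnot(inherits(x, "deg_result"))
  x$table$gene[x$table$selected]
}
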