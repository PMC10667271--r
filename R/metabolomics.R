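#' Metabolite fold changes versus the hydrated reference
#'
#' Per metabolite x tissue x state: fold change = mean abundance in the
#' state / mean abundance in the same tissue's hydrated samples (raw
#' scale), with a Welch two-sample test on log2 abundances and BH
#' adjustment within each tissue x state contrast — the same testing
#' machinery as the expression stage, for internal consistency.
#' `significant_up` marks fold change > 1 with (adjusted or raw, see
#' `adjust`) p below `alpha`. Zero abundances are replaced by half the
#' metabolite's smallest positive value before the log transform (a
#' standard detection-limit surrogate), with a warning.
#'
#' @param mat Metabolites x samples matrix of nonnegative raw abundances.
#' @param samples Sample sheet.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"BH"` (default) or `"none"` (raw p, as the published
#'   table legend states only "p value < 0.05").
#' @param ref_state Reference state.
#' @return Data frame `metabolite`, `tissue`, `state`, `fold_change`,
#'   `log2fc`, `p_raw`, `p_adj`, `significant_up`.
#' @export
metabolite_fold_changes <- function(mat, samples, alpha = 0.05,
                                    adjust = c("BH", "none"),
                                    ref_state = "hydrated") {
  adjust <- match.arg(adjust)
  if (any(mat < 0)) stop("abundances must be nonnegative", call. = FALSE)
  if (any(mat == 0)) {
    warning(sum(mat == 0), " zero abundance(s) replaced by half the ",
            "metabolite's minimum positive value", call. = FALSE)
    for (i in which(rowSums(mat == 0) > 0)) {
      pos <- mat[i, mat[i, ] > 0]
      if (!length(pos))
        stop("metabolite '", rownames(mat)[i], "' is all-zero",
             call. = FALSE)
      mat[i, mat[i, ] == 0] <- min(pos) / 2
    }
  }
  lmat <- log2(mat)
  tissues <- unique(samples$tissue)
  states <- setdiff(unique(samples$state), ref_state)
  cols <- function(ti, st) {
    ids <- intersect(samples$sample_id[samples$tissue == ti &
                                         samples$state == st],
                     colnames(mat))
    if (length(ids) < 2)
      stop(sprintf("need >= 2 replicates for tissue '%s', state '%s'",
                   ti, st), call. = FALSE)
    ids
  }
  do.call(rbind, lapply(tissues, function(ti) {
    ref_ids <- cols(ti, ref_state)
    do.call(rbind, lapply(states, function(st) {
      ids <- cols(ti, st)
      fc <- rowMeans(mat[, ids, drop = FALSE]) /
        rowMeans(mat[, ref_ids, drop = FALSE])
      w <- welch_by_row(lmat[, ids, drop = FALSE],
                        lmat[, ref_ids, drop = FALSE])
      p_adj <- adjust_bh(w$p_raw)
      p_use <- if (adjust == "BH") p_adj else w$p_raw
      data.frame(metabolite = rownames(mat), tissue = ti, state = st,
                 fold_change = fc, log2fc = w$log2fc, p_raw = w$p_raw,
                 p_adj = p_adj,
                 significant_up = fc > 1 & !is.na(p_use) & p_use < alpha,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }))
}

#' Hierarchical-clustering orders for a metabolite heatmap
#'
#' Leaf orders for rows (metabolites) and columns (samples) from
#' agglomerative clustering — Euclidean distance on row-z-scored values,
#' average linkage by default, the common choice for mixed-magnitude
#' metabolite panels. Deterministic: no randomness is involved.
#'
#' @param mat Metabolites x samples matrix (>= 2 rows and columns).
#' @param scale_rows Z-score each metabolite before clustering.
#' @param method Distance method for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with integer `rows` and `cols` leaf orders and the two
#'   `hclust` trees (`NULL` when degenerate).
#' @export
heatmap_order <- function(mat, scale_rows = TRUE, method = "euclidean",
                          linkage = "average") {
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  m <- mat
  if (scale_rows) {
    sds <- apply(m, 1, sd)
    m <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  }
  if (all(abs(m - mean(m)) < .Machine$double.eps^0.5)) {
    warning("degenerate (constant) matrix; returning input order",
            call. = FALSE)
    return(list(rows = seq_len(nrow(mat)), cols = seq_len(ncol(mat)),
                row_hclust = NULL, col_hclust = NULL))
  }
  rh <- hclust(dist(m, method = method), method = linkage)
  ch <- hclust(dist(t(m), method = method), method = linkage)
  list(rows = rh$order, cols = ch$order, row_hclust = rh, col_hclust = ch)
}

#' PCA of a metabolite panel
#'
#' Principal components of the sample x metabolite table after centering
#' and (by default) unit-variance scaling per metabolite — the standard
#' pretreatment for GC-MS panels spanning orders of magnitude.
#'
#' @param mat Metabolites x samples matrix.
#' @param n_components Number of components to return; must not exceed
#'   min(n_samples, n_metabolites).
#' @param scale. Scale each metabolite to unit variance (default TRUE);
#'   set FALSE for center-only PCA.
#' @return A `metab_pca`: `scores` (samples x components), `loadings`
#'   (metabolites x components), `variance_explained` (fraction of total
#'   variance per returned component, non-increasing).
#' @export
run_pca <- function(mat, n_components = 2, scale. = TRUE) {
  x <- t(mat)  # samples x metabolites
  if (nrow(x) < 2) stop("need >= 2 samples", call. = FALSE)
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(samples, metabolites)", call. = FALSE)
  if (scale.) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      warning("constant metabolite(s) left unscaled", call. = FALSE)
      x <- scale(x, center = TRUE, scale = ifelse(sds == 0, 1, sds))
    } else x <- scale(x, center = TRUE, scale = TRUE)
    p <- prcomp(x, center = FALSE, scale. = FALSE)
  } else {
    p <- prcomp(x, center = TRUE, scale. = FALSE)
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(n_components)
  structure(list(scores = p$x[, k, drop = FALSE],
                 loadings = p$rotation[, k, drop = FALSE],
                 variance_explained = ve[k]),
            class = "metab_pca")
}

#' @export
print.metab_pca <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components; variance explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}

#' @param x A `metab_pca`.
#' @param groups Optional factor (length = samples) to color points by,
#'   e.g. tissue or dehydration state.
#' @param ... Passed to [graphics::plot()].
#' @rdname run_pca
#' @export
plot.metab_pca <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * x$variance_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * x$variance_explained[2]), ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 19)
  invisible(x)
}
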