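# Row-wise Welch two-sample t-test on log2 values. Returns the difference
# in means (log2 fold change), t, df and two-sided p per row. Degenerate
# rows: zero variance in both groups with equal means -> p = NA
# (non-testable, excluded from the BH m); zero variance with distinct
# means -> p = 0.
welch_by_row <- function(a, b) {
  nA <- ncol(a); nB <- ncol(b)
  mA <- rowMeans(a); mB <- rowMeans(b)
  vA <- rowSums((a - mA)^2) / (nA - 1)
  vB <- rowSums((b - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  diff <- mA - mB
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero & diff != 0] <- 0
  p[zero & diff == 0] <- NA_real_
  data.frame(log2fc = diff, t = tstat, df = df, p_raw = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a vector of raw p-values. `NA` entries
#' (non-testable features) are preserved and excluded from the number of
#' tests m, so they do not dilute the correction.
#'
#' @param p Numeric vector of p-values in \[0, 1\], possibly with `NA`.
#' @return Adjusted p-values, same length and order, capped at 1.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03))  # all 0.03
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Differential expression of one dehydration state against hydrated
#'
#' Per-gene Welch two-sample t-test on log2 expression between the given
#' (tissue, state) group and the same tissue's hydrated reference;
#' `log2fc = mean(state) - mean(hydrated)`. BH adjustment is applied within
#' this single contrast (one adjustment per tissue x state data set), and
#' the enrichment rule (|fold change| >= `fc_threshold`, adjusted
#' p < `alpha`) sets `passes` and `direction`.
#'
#' Genes with zero variance and identical means in both groups are flagged
#' non-testable (`p_raw = NA`) and excluded from the BH m.
#'
#' @param expr Genes x samples matrix of log2 expression.
#' @param samples Sample sheet (`sample_id`, `tissue`, `state`, ...).
#' @param tissue,state The contrasted cell.
#' @param ref_state Reference state, default `"hydrated"`.
#' @param fc_threshold,alpha Enrichment rule parameters (see
#'   [filter_degs()]).
#' @return A DEG table: one row per gene with `gene`, `tissue`, `state`,
#'   `log2fc`, `p_raw`, `p_adj`, `direction`, `passes`.
#' @export
test_state_vs_hydrated <- function(expr, samples, tissue, state,
                                   ref_state = "hydrated",
                                   fc_threshold = 2, alpha = 0.05) {
  grp <- function(st) {
    ids <- samples$sample_id[samples$tissue == tissue & samples$state == st]
    ids <- intersect(ids, colnames(expr))
    if (length(ids) < 2)
      stop(sprintf("need >= 2 replicates for tissue '%s', state '%s'",
                   tissue, st), call. = FALSE)
    expr[, ids, drop = FALSE]
  }
  w <- welch_by_row(grp(state), grp(ref_state))
  tab <- data.frame(gene = rownames(expr), tissue = tissue, state = state,
                    log2fc = w$log2fc, p_raw = w$p_raw,
                    p_adj = adjust_bh(w$p_raw),
                    stringsAsFactors = FALSE, row.names = NULL)
  filter_degs(tab, fc_threshold = fc_threshold, alpha = alpha)
}

#' Apply the DEG enrichment rule
#'
#' Sets `passes` and `direction` on a DEG table using the published
#' boundary semantics verbatim: absolute fold change >= `fc_threshold`
#' (inclusive, i.e. |log2fc| >= log2(fc_threshold)) AND adjusted
#' p strictly < `alpha`. Non-testable genes (`p_adj` NA) never pass.
#'
#' @param deg_table Data frame with at least `log2fc` and `p_adj`.
#' @param fc_threshold Fold-change threshold on the raw scale (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return The table with `passes` (logical) and `direction`
#'   (`"up"`/`"down"`/`"none"`) recomputed.
#' @export
#' @examples
#' filter_degs(data.frame(log2fc = c(1, 3), p_adj = c(0.049, 0.05)))$passes
filter_degs <- function(deg_table, fc_threshold = 2, alpha = 0.05) {
  stopifnot(fc_threshold > 0, alpha > 0, alpha < 1)
  lfc <- abs(deg_table$log2fc) >= log2(fc_threshold)
  sig <- !is.na(deg_table$p_adj) & deg_table$p_adj < alpha
  deg_table$passes <- lfc & sig
  deg_table$direction <- ifelse(!deg_table$passes, "none",
                                ifelse(deg_table$log2fc > 0, "up", "down"))
  deg_table
}

#' All per-state DEG contrasts for the design
#'
#' Runs [test_state_vs_hydrated()] for every tissue and every non-reference
#' state present in the sample sheet and stacks the tables. BH adjustment
#' stays within each contrast.
#'
#' @inheritParams test_state_vs_hydrated
#' @return Combined DEG table.
#' @export
deg_all_contrasts <- function(expr, samples, ref_state = "hydrated",
                              fc_threshold = 2, alpha = 0.05) {
  tissues <- unique(samples$tissue)
  states <- setdiff(unique(samples$state), ref_state)
  do.call(rbind, lapply(tissues, function(ti)
    do.call(rbind, lapply(states, function(st)
      test_state_vs_hydrated(expr, samples, ti, st, ref_state,
                             fc_threshold, alpha)))))
}

#' Functional category vocabulary for DEG tagging
#' @export
CATEGORY_VOCABULARY <- c("MYB", "NAC", "WRKY", "bZIP", "DREB", "LEA",
                         "antioxidant", "trehalose/T6P", "autophagy",
                         "energy-metabolism", "signalling", "other")

#' Tag genes with functional categories
#'
#' Left-joins an annotation (gene -> set of labels from the declared
#' vocabulary: transcription-factor families, drought-protection and
#' energy/signalling classes) onto a gene list; unannotated genes are
#' labeled `"other"`.
#'
#' @param genes Character vector of gene IDs.
#' @param annotation Named list: gene -> character vector of labels.
#' @return Data frame with `gene` and a list-column `labels`.
#' @export
tag_categories <- function(genes, annotation = list()) {
  bad <- setdiff(unlist(annotation), CATEGORY_VOCABULARY)
  if (length(bad))
    stop("labels outside the category vocabulary: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  labels <- lapply(genes, function(g) {
    l <- annotation[[g]]
    if (is.null(l) || !length(l)) "other" else unique(l)
  })
  data.frame(gene = genes, labels = I(labels), stringsAsFactors = FALSE)
}
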