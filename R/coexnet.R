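#' Rank a tissue's genes by coefficient of variation
#'
#' Computes CV = sample SD / |sample mean| per gene across all of one
#' tissue's samples (all dehydration states pooled, which is what makes CV
#' pick out dynamic-range genes) and ranks genes by descending CV. Ties are
#' broken lexicographically by gene ID so the ranking is deterministic and
#' seed-free. Genes whose |mean| falls below `eps` are excluded with a
#' warning: CV is numerically unstable there (the matrix is on a log2 scale
#' where values near zero carry no special meaning).
#'
#' @param expr Genes x samples matrix.
#' @param samples Sample sheet; `tissue` selects the columns used.
#' @param tissue Which tissue to rank.
#' @param eps Exclusion threshold on |mean|.
#' @return Data frame `gene`, `mean`, `sd`, `cv`, `rank` (1..n, sorted by
#'   CV descending).
#' @export
rank_by_cv <- function(expr, samples, tissue, eps = 1e-8) {
  ids <- intersect(samples$sample_id[samples$tissue == tissue],
                   colnames(expr))
  if (length(ids) < 3)
    stop(sprintf("tissue '%s' has %d samples; need >= 3 for CV ranking",
                 tissue, length(ids)), call. = FALSE)
  m <- expr[, ids, drop = FALSE]
  mu <- rowMeans(m)
  sdev <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  keep <- abs(mu) >= eps
  if (any(!keep))
    warning(sum(!keep), " gene(s) with |mean| < ", eps,
            " excluded from CV ranking", call. = FALSE)
  out <- data.frame(gene = rownames(m)[keep], mean = mu[keep],
                    sd = sdev[keep], cv = sdev[keep] / abs(mu[keep]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$cv, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-k genes of a CV ranking
#'
#' @param ranking Output of [rank_by_cv()].
#' @param k Number of genes to keep (study default 10000). If fewer genes
#'   exist, all are returned with a warning. Ties at the boundary are
#'   already resolved lexicographically by the ranking.
#' @return Character vector of gene IDs.
#' @export
select_top_k <- function(ranking, k = 10000) {
  stopifnot(k >= 1)
  if (k >= nrow(ranking)) {
    if (k > nrow(ranking))
      warning("only ", nrow(ranking), " genes available for top-", k,
              " selection; returning all", call. = FALSE)
    return(ranking$gene)
  }
  ranking$gene[seq_len(k)]
}

#' All-pairs Pearson correlation of a gene subset
#'
#' @param expr_subset Genes x samples matrix (the selected top-CV genes);
#'   needs >= 3 samples and no constant-valued gene (drop those first —
#'   their correlation is undefined).
#' @return Symmetric genes x genes correlation matrix.
#' @export
pearson_all_pairs <- function(expr_subset) {
  if (ncol(expr_subset) < 3)
    stop("need >= 3 samples for correlation", call. = FALSE)
  constant <- apply(expr_subset, 1, function(x) var(x) == 0)
  if (any(constant))
    stop("constant gene(s) reached correlation: ",
         paste(head(rownames(expr_subset)[constant], 5), collapse = ", "),
         call. = FALSE)
  cor(t(expr_subset))
}

#' Drop constant genes before correlation
#'
#' @param expr_subset Genes x samples matrix.
#' @return The matrix without zero-variance rows; a message reports drops.
#' @export
drop_constant_genes <- function(expr_subset) {
  constant <- apply(expr_subset, 1, function(x) var(x) == 0)
  if (any(constant))
    message("dropping ", sum(constant),
            " constant gene(s) with undefined correlation")
  expr_subset[!constant, , drop = FALSE]
}

#' Build a thresholded co-expression network
#'
#' Edges are exactly the unordered gene pairs with |Pearson r| strictly
#' above the threshold (study default 0.964). Genes with no passing edge
#' are excluded from the node set — the network is what an edge-list import
#' into a graph viewer produces.
#'
#' @param corr Correlation matrix from [pearson_all_pairs()].
#' @param threshold Absolute-correlation cutoff, in (0, 1\].
#' @param tissue Tissue label attached to the network.
#' @return A `coex_network`: list with `tissue`, `nodes`, `edges` (data
#'   frame `gene_a`, `gene_b`, `r`; `gene_a` < `gene_b`), `threshold`.
#' @export
build_network <- function(corr, threshold = 0.964, tissue = "unspecified") {
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]", call. = FALSE)
  ut <- upper.tri(corr)
  hit <- which(ut & abs(corr) > threshold, arr.ind = TRUE)
  edges <- if (nrow(hit)) {
    data.frame(gene_a = rownames(corr)[hit[, 1]],
               gene_b = colnames(corr)[hit[, 2]],
               r = corr[hit], stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(), gene_b = character(), r = numeric(),
               stringsAsFactors = FALSE)
  }
  # canonical order: gene_a < gene_b lexicographically, rows sorted
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(tissue = tissue,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges, threshold = threshold),
            class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("Co-expression network (%s): %d nodes, %d edges at |r| > %g\n",
              x$tissue, length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

as_igraph <- function(network, overlay = NULL) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes),
                            name = network$nodes)
  if (nrow(network$edges))
    g <- igraph::add_edges(
      g, rbind(match(network$edges$gene_a, network$nodes),
               match(network$edges$gene_b, network$nodes)),
      r = network$edges$r)
  g <- igraph::set_graph_attr(g, "tissue", network$tissue)
  g <- igraph::set_graph_attr(g, "threshold", network$threshold)
  if (!is.null(overlay))
    for (st in names(overlay))
      g <- igraph::set_vertex_attr(g, paste0("status_", st),
                                   value = unname(overlay[[st]][network$nodes]))
  g
}

#' Overlay per-state DEG status on a network
#'
#' Colors each node, per dehydration state, by its DEG call in that state:
#' `"up"`/`"down"` for genes passing the enrichment rule, `"unchanged"`
#' otherwise (including genes absent from the DEG table).
#'
#' @param network A `coex_network`.
#' @param degs DEG table (from [deg_all_contrasts()] or stacked
#'   [test_state_vs_hydrated()] calls) for the same tissue.
#' @return A `state_overlay`: named list state -> named character vector
#'   (node -> status).
#' @export
overlay_deg_states <- function(network, degs) {
  if (nrow(degs) && !all(degs$tissue == network$tissue))
    stop("DEG table tissue does not match network tissue '",
         network$tissue, "'", call. = FALSE)
  states <- unique(degs$state)
  overlay <- lapply(states, function(st) {
    status <- setNames(rep("unchanged", length(network$nodes)),
                       network$nodes)
    d <- degs[degs$state == st & degs$passes, , drop = FALSE]
    d <- d[d$gene %in% network$nodes, , drop = FALSE]
    status[d$gene] <- d$direction
    status
  })
  structure(setNames(overlay, states), class = "state_overlay",
            tissue = network$tissue)
}

#' Summarize a network across dehydration states
#'
#' Per state: counts of up/down nodes, active edges (both endpoints sharing
#' a non-unchanged status), and connected components of the state-active
#' subgraph (the "distinct sections" a state lights up). Across states:
#' Jaccard similarity of the active node sets, quantifying how much the
#' network's engaged portion turns over between dehydration states.
#'
#' @param network A `coex_network`.
#' @param overlay A `state_overlay` for the same network.
#' @return A `state_network_summary`: list with `per_state` (data frame)
#'   and `jaccard` (state x state matrix).
#' @export
summarize_states <- function(network, overlay) {
  if (length(overlay) < 1) stop("overlay covers no state", call. = FALSE)
  states <- names(overlay)
  active_sets <- list()
  per_state <- do.call(rbind, lapply(states, function(st) {
    status <- overlay[[st]]
    active <- names(status)[status != "unchanged"]
    active_sets[[st]] <<- active
    e <- network$edges
    active_e <- e[status[e$gene_a] != "unchanged" &
                    status[e$gene_a] == status[e$gene_b], , drop = FALSE]
    n_comp <- if (length(active)) {
      sub <- build_subgraph(active, active_e)
      as.integer(igraph::count_components(sub))
    } else 0L
    data.frame(tissue = network$tissue, state = st,
               n_up = sum(status == "up"), n_down = sum(status == "down"),
               n_active_edges = nrow(active_e),
               n_components_active = n_comp, stringsAsFactors = FALSE)
  }))
  jac <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
  for (i in seq_along(states)) for (j in seq_along(states)) {
    a <- active_sets[[states[i]]]; b <- active_sets[[states[j]]]
    u <- length(union(a, b))
    jac[i, j] <- if (u == 0) 0 else length(intersect(a, b)) / u
  }
  structure(list(per_state = per_state, jaccard = jac),
            class = "state_network_summary")
}

build_subgraph <- function(nodes, edges) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$gene_a, nodes),
                                    match(edges$gene_b, nodes)))
  g
}

#' @export
print.state_network_summary <- function(x, ...) {
  cat("Per-state network activity:\n")
  print(x$per_state, row.names = FALSE)
  cat("\nJaccard similarity of active node sets:\n")
  print(round(x$jaccard, 3))
  invisible(x)
}

#' @export
plot.state_network_summary <- function(x, ...) {
  m <- t(as.matrix(x$per_state[, c("n_up", "n_down")]))
  colnames(m) <- x$per_state$state
  graphics::barplot(m, beside = TRUE, col = c("forestgreen", "firebrick"),
                    legend.text = c("up", "down"),
                    ylab = "DEG nodes in network",
                    main = paste(x$per_state$tissue[1], "network"), ...)
  invisible(x)
}

#' Export a network as an edge list and GraphML
#'
#' Writes `<prefix>_edges.tsv` (gene_a, gene_b, r) and `<prefix>.graphml`
#' with per-state node status attributes and the correlation as edge
#' attribute, openable in Cytoscape and other graph viewers.
#'
#' @param network A `coex_network`.
#' @param overlay Optional `state_overlay` providing node attributes.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(network, overlay = NULL, prefix) {
  edge_file <- paste0(prefix, "_edges.tsv")
  graphml_file <- paste0(prefix, ".graphml")
  write.table(network$edges, edge_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  igraph::write_graph(as_igraph(network, overlay), graphml_file,
                      format = "graphml")
  invisible(c(edges = edge_file, graphml = graphml_file))
}

#' Read a GraphML network back into a `coex_network`
#'
#' Inverse of [export_network()]: node set, edge set and correlation
#' weights round-trip losslessly (weights to GraphML's double precision).
#'
#' @param graphml_file Path written by [export_network()].
#' @return A `coex_network`.
#' @export
read_network <- function(graphml_file) {
  g <- igraph::read_graph(graphml_file, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                      r = if (igraph::ecount(g))
                        igraph::edge_attr(g, "r") else numeric(0),
                      stringsAsFactors = FALSE)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(tissue = igraph::graph_attr(g, "tissue"),
                 nodes = sort(nodes), edges = edges,
                 threshold = igraph::graph_attr(g, "threshold")),
            class = "coex_network")
}

#' One-call network construction for a tissue
#'
#' Convenience wrapper: CV ranking, top-k selection, constant-gene
#' filtering, all-pairs Pearson correlation and thresholding.
#'
#' @inheritParams rank_by_cv
#' @param top_k Number of top-CV genes (default 10000).
#' @param threshold Absolute-correlation cutoff (default 0.964).
#' @return A `coex_network`.
#' @export
tissue_network <- function(expr, samples, tissue, top_k = 10000,
                           threshold = 0.964) {
  ranking <- rank_by_cv(expr, samples, tissue)
  genes <- select_top_k(ranking, top_k)
  ids <- intersect(samples$sample_id[samples$tissue == tissue],
                   colnames(expr))
  sub <- drop_constant_genes(expr[genes, ids, drop = FALSE])
  build_network(pearson_all_pairs(sub), threshold, tissue)
}
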