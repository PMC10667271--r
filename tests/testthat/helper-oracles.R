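# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: raw-formula Pearson, brute-force BH step-up,
# and direct eigendecomposition.

# Pearson r from raw sums (no stats::cor).
pearson_raw <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# All-pairs thresholded edge set by brute force: data frame gene_a < gene_b.
brute_edge_set <- function(mat, threshold) {
  genes <- rownames(mat)
  out <- list()
  for (i in seq_len(nrow(mat) - 1)) for (j in (i + 1):nrow(mat)) {
    r <- pearson_raw(mat[i, ], mat[j, ])
    if (abs(r) > threshold) {
      a <- genes[i]; b <- genes[j]
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      out[[length(out) + 1]] <- data.frame(gene_a = a, gene_b = b, r = r,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  e <- do.call(rbind, out)
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

# BH step-up adjusted p-values, straight from the definition:
# q_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- pmin(1, rev(cummin(rev(m * ranked / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

# Small seeded expression fixture: independent Gaussian genes.
noise_matrix <- function(n_genes, n_samples, seed, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, sd = sd), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Sample sheet for a single-tissue design laid out state-major.
toy_sheet <- function(states, replicates, tissue = "root") {
  grid <- expand.grid(replicate = seq_len(replicates), state = states,
                      stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_r%d", tissue, grid$state,
                                 grid$replicate),
             tissue = tissue, state = grid$state,
             replicate = grid$replicate, stringsAsFactors = FALSE)
}

# Assert that a compact letter display matches the non-significance
# relation of its own pairwise p-value matrix, pair by pair.
expect_letters_consistent <- function(ld, alpha = 0.05) {
  pm <- attr(ld, "p_matrix")
  states <- names(unclass(ld))
  for (i in seq_along(states)[-1]) for (j in seq_len(i - 1)) {
    a <- states[i]; b <- states[j]
    share <- length(intersect(strsplit(ld[[a]], "")[[1]],
                              strsplit(ld[[b]], "")[[1]])) > 0
    expect_identical(share, pm[a, b] >= alpha,
                     label = sprintf("letter sharing for %s vs %s", a, b))
  }
}
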