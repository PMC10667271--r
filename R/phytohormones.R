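# All observations numerically identical (to the spread that matters on
# the measurement scale): the ANOVA F is a 0/0 ratio there.
.no_variation <- function(x) {
  diff(range(x)) <= .Machine$double.eps^0.5 * max(1, abs(mean(x)))
}

.hormone_subset <- function(meas, hormone) {
  req <- c("hormone", "state", "conc_pmol_per_mg")
  if (!all(req %in% names(meas)))
    stop("measurements need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  d <- meas[meas$hormone == hormone, , drop = FALSE]
  if (!nrow(d)) stop("no measurements for hormone '", hormone, "'",
                     call. = FALSE)
  counts <- table(d$state)
  if (length(counts) < 2)
    stop("need >= 2 states for hormone '", hormone, "'", call. = FALSE)
  if (any(counts < 2))
    stop("need >= 2 replicates per state for hormone '", hormone, "'",
         call. = FALSE)
  d$state <- factor(d$state)
  d
}

#' One-way ANOVA of a hormone across dehydration states
#'
#' Classical fixed-effects one-way ANOVA of concentration on dehydration
#' state. The degenerate all-equal case (zero between- and within-group
#' sums of squares) is reported as F = 0, p = 1.
#'
#' @param meas Long-format measurements (`hormone`, `state`, `replicate`,
#'   `conc_pmol_per_mg`).
#' @param hormone Which hormone to test.
#' @return List with `statistic` (F), `p_value`, `df` (c(between, within))
#'   and the underlying `aov` fit.
#' @export
anova_oneway <- function(meas, hormone) {
  d <- .hormone_subset(meas, hormone)
  fit <- aov(conc_pmol_per_mg ~ state, data = d)
  k <- nlevels(d$state)
  if (.no_variation(d$conc_pmol_per_mg)) {
    # an essentially perfect fit: F is a 0/0 ratio
    return(list(statistic = 0, p_value = 1,
                df = c(between = k - 1L, within = nrow(d) - k), fit = fit))
  }
  tab <- anova(fit)
  list(statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
       df = c(between = tab$Df[1], within = tab$Df[2]), fit = fit)
}

# Insert-and-absorb letter assignment from a symmetric logical matrix of
# significant pairs. Start from one column holding every group; for each
# significant pair split every column containing both (insert), then drop
# columns that are subsets of others (absorb). By construction two groups
# end up sharing a column iff their comparison is non-significant.
insert_absorb <- function(signif_mat) {
  groups <- rownames(signif_mat)
  cols <- list(groups)
  pairs <- which(signif_mat & upper.tri(signif_mat), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- groups[pairs[k, 1]]; b <- groups[pairs[k, 2]]
    new_cols <- list()
    for (cl in cols) {
      if (all(c(a, b) %in% cl)) {
        new_cols <- c(new_cols, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else new_cols <- c(new_cols, list(cl))
    }
    # absorb: remove columns contained in another column
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
      if (i != j && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j))
        keep[i] <- FALSE
    }
    cols <- new_cols[keep]
  }
  # letters ordered by the first (highest-mean) group each column contains
  first <- vapply(cols, function(cl) min(match(cl, groups)), numeric(1))
  cols <- cols[order(first)]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols))
    for (g in cols[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  letters_out
}

#' Compact letter display for a hormone's pairwise comparisons
#'
#' All pairwise comparisons at level `alpha` — Tukey HSD by default, or
#' pairwise Welch tests with BH adjustment — summarized by the
#' insert-and-absorb letter algorithm over states ordered by descending
#' mean. Two states share a letter exactly when their comparison is
#' non-significant.
#'
#' @inheritParams anova_oneway
#' @param alpha Significance level for the pairwise comparisons.
#' @param method `"tukey"` (default) or `"welch-bh"`.
#' @return A `letter_display`: named character vector state -> letters,
#'   with the pairwise p-value matrix in attribute `p_matrix`.
#' @export
#' @examples
#' h <- simulate_hormones(sim_config(n_genes = 10, seed = 1))$hormones
#' compact_letters(h, "ABA")
compact_letters <- function(meas, hormone, alpha = 0.05,
                            method = c("tukey", "welch-bh")) {
  method <- match.arg(method)
  d <- .hormone_subset(meas, hormone)
  means <- tapply(d$conc_pmol_per_mg, d$state, mean)
  states <- names(sort(means, decreasing = TRUE))
  pmat <- matrix(NA_real_, length(states), length(states),
                 dimnames = list(states, states))
  if (method == "tukey") {
    if (.no_variation(d$conc_pmol_per_mg)) {
      pmat[] <- 1  # no variation anywhere: nothing can differ
    } else {
      tk <- TukeyHSD(aov(conc_pmol_per_mg ~ state, data = d))$state
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      for (k in seq_along(nm)) {
        a <- nm[[k]][1]; b <- nm[[k]][2]
        pmat[a, b] <- pmat[b, a] <- tk[k, "p adj"]
      }
    }
  } else {
    combs <- utils::combn(states, 2)
    praw <- apply(combs, 2, function(ab) {
      x <- d$conc_pmol_per_mg[d$state == ab[1]]
      y <- d$conc_pmol_per_mg[d$state == ab[2]]
      if (var(x) == 0 && var(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
      stats::t.test(x, y)$p.value
    })
    padj <- adjust_bh(praw)
    for (k in seq_len(ncol(combs)))
      pmat[combs[1, k], combs[2, k]] <-
        pmat[combs[2, k], combs[1, k]] <- padj[k]
  }
  diag(pmat) <- 1
  signif_mat <- pmat < alpha
  out <- insert_absorb(signif_mat)
  structure(out, class = "letter_display", p_matrix = pmat,
            hormone = hormone, alpha = alpha, means = means[states])
}

#' @export
print.letter_display <- function(x, ...) {
  cat(sprintf("Compact letter display (%s, alpha = %g):\n",
              attr(x, "hormone"), attr(x, "alpha")))
  means <- attr(x, "means")
  for (st in names(unclass(x)))
    cat(sprintf("  %-12s %8.2f  %s\n", st, means[[st]], x[[st]]))
  invisible(x)
}
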