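## Gene-set scoring engines. All four scorers are implemented from scratch
## on the contracts below; rank-based scorers (ssGSEA, AUCell) are invariant
## to strictly monotone transforms of the expression values.

## descending-rank running-sum enrichment score for one observation
ssgsea_one <- function(expr_col, set_idx, alpha) {
  n <- length(expr_col)
  r <- rank_desc(expr_col)
  ord <- order(r)
  inset <- logical(n)
  inset[set_idx] <- TRUE
  inset <- inset[ord]
  w <- r[ord]^alpha * inset
  p_g <- cumsum(w) / sum(w)
  p_ng <- cumsum(!inset) / (n - sum(inset))
  sum(p_g - p_ng)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per observation, genes are ranked by decreasing expression (average
#' ranks for ties) and the enrichment score is the sum over rank positions
#' of the difference between the weighted in-set cumulative fraction
#' (weights `rank^alpha`) and the uniform out-of-set cumulative fraction.
#' With `normalize = TRUE` all scores are divided by the global max - min
#' across observations and sets.
#'
#' @param expr expression matrix (any layer; only ranks are used).
#' @param sets gene-set collection; sets with fewer than 2 expressed genes
#'   are dropped with a warning.
#' @param alpha rank weighting exponent.
#' @param normalize rescale by the global score range.
#' @return observations x sets score matrix with attributes `method` and
#'   `parameters`.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  genes <- rownames(expr)
  idx <- lapply(sets$sets, function(g) which(genes %in% g))
  keep <- lengths(idx) >= 2
  if (any(!keep))
    warning(sprintf("dropping %d gene set(s) with fewer than 2 expressed genes",
                    sum(!keep)))
  if (!any(keep)) stop("all gene sets dropped: no usable overlap")
  idx <- idx[keep]
  out <- matrix(0, ncol(expr), length(idx),
                dimnames = list(colnames(expr), names(idx)))
  for (o in seq_len(ncol(expr))) {
    col <- expr[, o]
    for (s in seq_along(idx)) out[o, s] <- ssgsea_one(col, idx[[s]], alpha)
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  attr(out, "method") <- "ssgsea"
  attr(out, "parameters") <- list(alpha = alpha, normalize = normalize)
  out
}

#' Gene-set variation analysis score (GSVA-like)
#'
#' Per gene, a Gaussian-kernel cumulative density across observations
#' (bandwidth `sd/4`) gives an expression statistic; statistics are
#' converted per observation to ranks symmetrized about the midpoint, and
#' a Kolmogorov-Smirnov-like random walk with weight `|rank|^tau` yields
#' the score: largest positive plus largest negative deviation when
#' `mx_diff`, otherwise the maximum absolute deviation.
#'
#' @param expr expression matrix with at least 3 observations.
#' @param sets gene-set collection.
#' @param tau rank weight exponent.
#' @param mx_diff score definition, see above.
#' @param bw_factor kernel bandwidth as a fraction of the per-gene sd.
#' @return observations x sets score matrix.
#' @export
gsva <- function(expr, sets, tau = 1.0, mx_diff = TRUE, bw_factor = 0.25) {
  if (ncol(expr) < 3) stop("gsva requires at least 3 observations")
  genes <- rownames(expr)
  n <- ncol(expr)
  ng <- nrow(expr)
  ## kernel CDF statistic per gene across observations
  z <- matrix(0, ng, n, dimnames = dimnames(expr))
  const_rows <- 0
  for (g in seq_len(ng)) {
    x <- expr[g, ]
    s <- stats::sd(x)
    if (s < 1e-12) {
      z[g, ] <- 0.5
      const_rows <- const_rows + 1
      next
    }
    h <- bw_factor * s
    z[g, ] <- colMeans(stats::pnorm(outer(x, x, "-") / h))
  }
  if (const_rows > 0)
    warning(sprintf("%d constant gene row(s) assigned the midpoint statistic",
                    const_rows))
  idx <- lapply(sets$sets, function(g) which(genes %in% g))
  keep <- lengths(idx) >= 1
  if (!any(keep)) stop("no gene set overlaps the expression matrix")
  idx <- idx[keep]
  out <- matrix(0, n, length(idx),
                dimnames = list(colnames(expr), names(idx)))
  for (o in seq_len(n)) {
    r <- rank_desc(z[, o])                    # 1 = largest statistic
    sym <- (ng + 1) / 2 - r                   # symmetric about the midpoint
    ord <- order(r)
    w <- abs(sym)^tau
    for (s in seq_along(idx)) {
      inset <- logical(ng)
      inset[idx[[s]]] <- TRUE
      ins <- inset[ord]
      nu <- cumsum(w[ord] * ins) / sum(w[ord][ins]) -
        cumsum(!ins) / (ng - sum(ins))
      out[o, s] <- if (mx_diff) max(c(nu, 0)) + min(c(nu, 0))
                   else nu[which.max(abs(nu))]
    }
  }
  attr(out, "method") <- "gsva"
  attr(out, "parameters") <- list(tau = tau, mx_diff = mx_diff,
                                  bw_factor = bw_factor)
  out
}

#' AUCell recovery-curve activity scores
#'
#' Per cell, genes are ranked by decreasing expression with ties broken
#' uniformly at random under `seed`; the score is the area under the step
#' recovery curve of set genes within the top `ceil(max_rank_frac * N)`
#' positions, normalized to the maximum achievable area.
#'
#' @param lognorm expression matrix (cells as observations).
#' @param sets gene-set collection; sets must fit in the gene universe.
#' @param max_rank_frac fraction of the ranking considered.
#' @param seed RNG seed for tie breaking.
#' @return cells x sets AUC matrix in [0, 1].
#' @export
aucell <- function(lognorm, sets, max_rank_frac = 0.05, seed = 1) {
  n <- nrow(lognorm)
  max_rank <- max(2L, as.integer(ceiling(max_rank_frac * n)))
  genes <- rownames(lognorm)
  idx <- lapply(sets$sets, function(g) {
    if (length(g) > n) stop("gene set larger than the gene universe")
    which(genes %in% g)
  })
  set.seed(seed)
  out <- matrix(0, ncol(lognorm), length(idx),
                dimnames = list(colnames(lognorm), names(idx)))
  for (o in seq_len(ncol(lognorm))) {
    r <- rank(-lognorm[, o], ties.method = "random")
    for (s in seq_along(idx)) {
      rk <- sort(r[idx[[s]]])
      rk <- rk[rk <= max_rank]
      ## recovery curve height at positions 1..max_rank, summed
      hits <- findInterval(seq_len(max_rank), rk)
      auc_max <- sum(pmin(seq_len(max_rank), length(idx[[s]])))
      out[o, s] <- sum(hits) / auc_max
    }
  }
  attr(out, "method") <- "aucell"
  attr(out, "parameters") <- list(max_rank_frac = max_rank_frac,
                                  max_rank = max_rank, seed = seed)
  out
}

#' Binned-control module score
#'
#' Genes are binned by mean expression across cells into `n_bins`
#' expression bins; for every set gene, `n_ctrl` control genes are sampled
#' from its bin (with replacement when the bin is small). The score per
#' cell is mean set expression minus mean control expression.
#'
#' @param lognorm expression matrix.
#' @param set character vector of set genes.
#' @param n_bins number of expression bins.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed RNG seed for the control draw.
#' @return named numeric score per cell.
#' @export
module_score <- function(lognorm, set, n_bins = 24, n_ctrl = 100, seed = 1) {
  genes <- rownames(lognorm)
  set <- intersect(set, genes)
  if (!length(set)) stop("gene set does not intersect the expression matrix")
  avg <- rowMeans(lognorm)
  bins <- ceiling(rank(avg, ties.method = "first") / (length(avg) / n_bins))
  set.seed(seed)
  ctrl <- unlist(lapply(set, function(g) {
    pool <- which(bins == bins[match(g, genes)])
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  score <- colMeans(lognorm[set, , drop = FALSE]) -
    colMeans(lognorm[ctrl, , drop = FALSE])
  stats::setNames(score, colnames(lognorm))
}

#' Median dichotomization
#'
#' Values strictly above the median are labeled high; at or below, low.
#'
#' @param scores numeric vector, length at least 2.
#' @param labels two labels, `c(high, low)`.
#' @return character vector of labels (named when `scores` is named).
#' @export
classify_by_median <- function(scores, labels = c("high", "low")) {
  if (length(scores) < 2) stop("need at least 2 observations")
  if (max(scores) == min(scores)) {
    warning("all values identical; everything labeled low")
    out <- rep(labels[2], length(scores))
  } else {
    out <- ifelse(scores > stats::median(scores), labels[1], labels[2])
  }
  stats::setNames(out, names(scores))
}

#' Two-group proportion comparison (Fisher exact)
#'
#' @param tab 2x2 table of non-negative integer counts.
#' @return list with `odds_ratio` (conditional MLE; `NA` when a margin is
#'   zero) and `p_value` (two-sided exact; 1 when a margin is zero).
#' @export
compare_proportions <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == floor(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Differential gene-set analysis between two groups of observations
#'
#' Per set: log2 ratio of group mean scores (pseudo-count 1e-9), two-sided
#' Wilcoxon rank-sum p, Bonferroni adjustment across sets. Rows sorted by
#' decreasing log2 difference.
#'
#' @param scores observations x sets score matrix (e.g. [aucell()]).
#' @param group_labels vector with two levels aligned to score rows; the
#'   first level (sorted) is the reference "group1".
#' @return data.frame `gene_set`, `log2_diff`, `p_value`, `adj_p_value`.
#' @export
diff_genesets <- function(scores, group_labels) {
  lv <- sort(unique(as.character(group_labels)))
  if (length(lv) != 2) stop("exactly two groups required")
  g1 <- group_labels == lv[1]
  if (sum(g1) < 3 || sum(!g1) < 3)
    stop("each group needs at least 3 observations")
  m <- ncol(scores)
  lfc <- log2((colMeans(scores[g1, , drop = FALSE]) + .EPS) /
                (colMeans(scores[!g1, , drop = FALSE]) + .EPS))
  p <- vapply(seq_len(m), function(s) {
    wilcox_rank_sum(scores[g1, s], scores[!g1, s])$p_value
  }, numeric(1))
  out <- data.frame(gene_set = colnames(scores), log2_diff = lfc,
                    p_value = p, adj_p_value = pmin(1, p * m))
  out <- out[order(-out$log2_diff), ]
  rownames(out) <- NULL
  out
}

#' Correlate a mean program score with individual gene expression
#'
#' Averages the given score columns per observation and reports the
#' Pearson correlation (and p) of that mean with each listed gene's
#' expression, sorted by decreasing correlation. The top-scoring gene is
#' the one whose expression best tracks the program.
#'
#' @param scores observations x sets matrix restricted to the sets of
#'   interest (e.g. the top enriched ones).
#' @param expr expression matrix over the same observations.
#' @param top_genes genes to correlate (e.g. most highly expressed).
#' @return data.frame `gene`, `r`, `p_value` (constant genes get `NA`).
#' @export
functional_alignment <- function(scores, expr, top_genes) {
  mean_score <- rowMeans(scores)
  obs <- rownames(scores)
  stopifnot(all(obs %in% colnames(expr)))
  res <- lapply(top_genes, function(g) {
    if (!g %in% rownames(expr))
      return(data.frame(gene = g, r = NA_real_, p_value = NA_real_))
    x <- expr[g, obs]
    if (stats::sd(x) < 1e-12)
      return(data.frame(gene = g, r = NA_real_, p_value = NA_real_))
    ct <- stats::cor.test(mean_score, x, method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, res)
  out <- out[order(-ifelse(is.na(out$r), -Inf, out$r)), ]
  rownames(out) <- NULL
  out
}
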