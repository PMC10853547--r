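## shared fixture builders; everything is generated in code

## small named counts matrix
toy_counts <- function(values, genes = NULL, cells = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 4 else length(genes))
  rownames(m) <- if (is.null(genes)) paste0("G", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(cells)) paste0("C", seq_len(ncol(m))) else cells
  expression_matrix(m, "counts")
}

## random lognorm matrix with named axes
rand_lognorm <- function(ng, nc, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(ng * nc, 3), ng, nc,
              dimnames = list(paste0("G", seq_len(ng)),
                              paste0("C", seq_len(nc))))
  lognormalize(expression_matrix(m, "counts"))
}

## default 3-population single-cell config (planted pair + independent)
default_sc_config <- function(seed = 1, n_samples = 8, n_cells = 60,
                              n_genes = 120, coenrich = NULL) {
  pops <- data.frame(name = c("tumorA", "tregB", "otherC"),
                     baseline_fraction = c(1 / 3, 1 / 3, 1 / 3),
                     marker_genes = c(10, 10, 10),
                     marker_log2fc = c(2, 2, 2))
  sc_sim_config(n_samples, n_cells, n_genes, pops,
                coenrich_pairs = coenrich, seed = seed)
}

## survival table from vectors
surv_tab <- function(time, event) {
  data.frame(sample_id = paste0("S", seq_along(time)), time = time,
             event = event)
}

## exhaustive two-sided Wilcoxon p by enumeration of all group assignments
exact_wilcox_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

## brute-force per-event-time log-rank tabulation (independent of the
## package's cumulative-count implementation)
logrank_oracle <- function(time, event, g1) {
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)                     # degenerate split, no information
  (o - e)^2 / v
}

## drop scorer metadata attributes so matrices compare by value
strip_attrs <- function(x) {
  attr(x, "method") <- NULL
  attr(x, "parameters") <- NULL
  unname(x)
}

## direct running-sum ssGSEA evaluation (naive double loop)
ssgsea_oracle <- function(expr_col, set_genes, alpha) {
  genes <- names(expr_col)
  r <- rank(-expr_col)                      # descending, average ties
  ord <- genes[order(r)]
  inset <- ord %in% set_genes
  denom_w <- sum((r[ord])[inset]^alpha)
  es <- 0
  for (i in seq_along(ord)) {
    p_g <- sum((r[ord])[seq_len(i)][inset[seq_len(i)]]^alpha) / denom_w
    p_ng <- sum(!inset[seq_len(i)]) / sum(!inset)
    es <- es + p_g - p_ng
  }
  es
}
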