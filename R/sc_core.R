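#' Quality-control filtering of single-cell counts
#'
#' Cells are retained when they have strictly more than `min_genes` genes
#' detected, a total transcript count strictly above `min_counts` and at
#' most `max_counts`, and a mitochondrial transcript fraction of at most
#' `max_mito_frac`. Genes listed in `exclusion_lists` (e.g. mitochondrial,
#' heat-shock, ribosomal and dissociation genes) are removed after the cell
#' filter. Doublet removal is not performed; the report says so.
#'
#' @param counts expression matrix, counts layer.
#' @param exclusion_lists optional gene-set collection of genes to drop.
#' @param min_genes,min_counts,max_counts,max_mito_frac thresholds.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes,
#'   used unless `mito_genes` is given.
#' @param mito_genes explicit mitochondrial gene list (overrides prefix).
#' @return list with `counts` (filtered matrix) and `report` (cells removed
#'   per rule, genes excluded, doublet note).
#' @export
qc_filter <- function(counts, exclusion_lists = NULL, min_genes = 200,
                      min_counts = 1000, max_counts = 30000,
                      max_mito_frac = 0.20, mito_prefix = "MT-",
                      mito_genes = NULL) {
  stopifnot(identical(expr_layer(counts), "counts"))
  if (is.null(mito_genes))
    mito_genes <- rownames(counts)[startsWith(rownames(counts), mito_prefix)]
  total <- colSums(counts)
  n_genes_det <- colSums(counts > 0)
  mito_frac <- if (length(mito_genes)) {
    colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE]) /
      pmax(total, 1)
  } else rep(0, ncol(counts))

  fail_genes <- n_genes_det <= min_genes
  fail_low <- total <= min_counts
  fail_high <- total > max_counts
  fail_mito <- mito_frac > max_mito_frac
  keep <- !(fail_genes | fail_low | fail_high | fail_mito)
  if (!any(keep)) stop("no cells pass quality control")

  out <- counts[, keep, drop = FALSE]
  excluded <- character(0)
  if (!is.null(exclusion_lists)) {
    excluded <- intersect(rownames(out),
                          unique(unlist(exclusion_lists$sets)))
    out <- out[!rownames(out) %in% excluded, , drop = FALSE]
    if (nrow(out) == 0) stop("no genes left after exclusion-list removal")
  }
  report <- list(n_input_cells = ncol(counts), n_kept_cells = sum(keep),
                 removed_low_genes = sum(fail_genes),
                 removed_low_counts = sum(fail_low & !fail_genes),
                 removed_high_counts = sum(fail_high),
                 removed_high_mito = sum(fail_mito),
                 genes_excluded = length(excluded),
                 doublet_removal = "not applied")
  list(counts = expression_matrix(out, "counts"), report = report)
}

#' Library-size log-normalization
#'
#' Scales each cell to 10,000 total counts and applies natural log1p:
#' `ln(1 + 10000 * c / total)`.
#'
#' @param counts expression matrix, counts layer.
#' @param scale_factor target library size.
#' @return expression matrix, lognorm layer.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  stopifnot(identical(expr_layer(counts), "counts"))
  total <- colSums(counts)
  if (any(total == 0))
    stop("zero-count cell encountered; run qc_filter first")
  out <- log1p(sweep(unclass(counts), 2, scale_factor / total, "*"))
  expression_matrix(out, "lognorm")
}

## exact-or-approximate Wilcoxon on pre-computed ranks for one gene,
## vectorized over genes via rank sums; ranks computed once per gene
marker_wilcox_p <- function(expr_row, in_group) {
  wilcox_rank_sum(expr_row[in_group], expr_row[!in_group])$p_value
}

#' One-vs-rest marker discovery per cluster
#'
#' For each cluster and gene: a two-sided Wilcoxon rank-sum test of the
#' cluster's cells against all other cells, log2 fold-change of the
#' expm1-mean expression (with a 1e-9 pseudo-count), and
#' Benjamini-Hochberg adjustment across genes within each cluster. Genes
#' expressed in fewer than `min_pct` of cells in both groups are dropped.
#'
#' @param lognorm expression matrix, lognorm layer.
#' @param annotation data.frame with `cell_id` and `cluster` covering the
#'   matrix columns.
#' @param min_log2fc report only genes with log2 fold-change above this.
#' @param min_pct minimum expression fraction in at least one group.
#' @return marker table: `cluster`, `gene`, `log2fc`, `p_value`,
#'   `adj_p_value`, `pct_in`, `pct_out`, sorted by cluster then
#'   decreasing log2fc.
#' @export
find_markers <- function(lognorm, annotation, min_log2fc = 0, min_pct = 0.1) {
  stopifnot(identical(expr_layer(lognorm), "lognorm"))
  cl <- annotation$cluster[match(colnames(lognorm), annotation$cell_id)]
  if (anyNA(cl)) stop("annotation does not cover all cells")
  clusters <- unique(cl)
  if (length(clusters) < 2) stop("need at least 2 clusters")
  ex <- expm1(unclass(lognorm))
  res <- list()
  for (k in clusters) {
    in_g <- cl == k
    if (sum(in_g) < 3) {
      warning(sprintf("cluster '%s' has fewer than 3 cells; skipped", k))
      next
    }
    pct_in <- rowMeans(lognorm[, in_g, drop = FALSE] > 0)
    pct_out <- rowMeans(lognorm[, !in_g, drop = FALSE] > 0)
    keep <- pct_in >= min_pct | pct_out >= min_pct
    if (!any(keep)) next
    m_in <- rowMeans(ex[keep, in_g, drop = FALSE])
    m_out <- rowMeans(ex[keep, !in_g, drop = FALSE])
    lfc <- log2((m_in + .EPS) / (m_out + .EPS))
    p <- apply(lognorm[keep, , drop = FALSE], 1, marker_wilcox_p, in_group = in_g)
    adj <- stats::p.adjust(p, method = "BH")
    tab <- data.frame(cluster = k, gene = rownames(lognorm)[keep],
                      log2fc = lfc, p_value = p, adj_p_value = adj,
                      pct_in = pct_in[keep], pct_out = pct_out[keep])
    tab <- tab[tab$log2fc > min_log2fc, , drop = FALSE]
    res[[as.character(k)]] <- tab[order(-tab$log2fc), ]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Marker gene sets from a marker table
#'
#' Applies the significance rule used to define population signatures
#' (log2 fold-change above `min_log2fc` and adjusted p below `max_adj_p`).
#'
#' @param markers output of [find_markers()].
#' @param min_log2fc,max_adj_p selection thresholds.
#' @return a gene-set collection, one set per cluster passing the filter.
#' @export
marker_gene_sets <- function(markers, min_log2fc = 1, max_adj_p = 0.05) {
  sel <- markers[markers$log2fc > min_log2fc &
                   markers$adj_p_value < max_adj_p, ]
  sets <- split(sel$gene, sel$cluster)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop("no cluster passes the marker significance rule")
  gene_set_collection(sets)
}

#' Copy-number inference from smoothed reference-subtracted expression
#'
#' Per gene, the mean over reference cells is subtracted; values are
#' clipped, genes ordered along the genome, and a centered moving average
#' of length `window` applied within each chromosome (truncated at the
#' ends). Profiles are median-recentered per cell. The CNV score is the
#' mean of squared smoothed values; malignancy is called by 1-D k-means
#' (k = 2) on the scores, the higher-mean class being malignant.
#'
#' @param lognorm expression matrix, lognorm layer.
#' @param annotation data.frame with `cell_id`, `cluster`.
#' @param coords gene coordinate table ([read_gene_coords()] format).
#' @param reference_clusters cluster labels to use as the diploid
#'   reference.
#' @param window moving-average length (genes).
#' @param clip symmetric bound applied to reference-subtracted values.
#' @return list with `profile` (cells x ordered genes smoothed matrix),
#'   `scores` (named per-cell CNV score), `malignant` (named logical),
#'   `gene_order` (genes as ordered along the genome).
#' @export
infer_cnv <- function(lognorm, annotation, coords, reference_clusters,
                      window = 101, clip = 3.0) {
  stopifnot(identical(expr_layer(lognorm), "lognorm"))
  cl <- annotation$cluster[match(colnames(lognorm), annotation$cell_id)]
  ref <- cl %in% reference_clusters
  if (!any(ref)) stop("no reference cells found")

  co <- coords[coords$gene %in% rownames(lognorm), ]
  co <- co[order(co$chromosome, co$start), ]
  ## drop chromosomes with too few genes to smooth meaningfully
  n_per_chrom <- table(co$chromosome)
  small <- names(n_per_chrom)[n_per_chrom < 3]
  if (length(small)) {
    warning(sprintf("excluding %d chromosome(s) with fewer than 3 genes",
                    length(small)))
    co <- co[!co$chromosome %in% small, ]
  }
  x <- unclass(lognorm)[co$gene, , drop = FALSE]
  centered <- x - rowMeans(x[, ref, drop = FALSE])
  centered <- pmin(pmax(centered, -clip), clip)

  smoothed <- matrix(0, nrow(centered), ncol(centered),
                     dimnames = dimnames(centered))
  for (ch in unique(co$chromosome)) {
    idx <- which(co$chromosome == ch)
    block <- centered[idx, , drop = FALSE]
    ## truncated centered moving average via cumulative sums
    n <- nrow(block)
    half <- (window - 1) %/% 2
    cs <- rbind(0, apply(block, 2, cumsum))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    smoothed[idx, ] <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  }
  ## per-cell median re-centering
  smoothed <- sweep(smoothed, 2, apply(smoothed, 2, stats::median), "-")
  scores <- colMeans(smoothed^2)

  malignant <- rep(FALSE, length(scores))
  if (length(unique(round(scores, 12))) > 1) {
    km <- stats::kmeans(scores, centers = range(scores))
    hi_class <- which.max(km$centers)
    malignant <- km$cluster == hi_class
  }
  names(malignant) <- names(scores)
  list(profile = t(smoothed), scores = scores, malignant = malignant,
       gene_order = co$gene)
}

#' Per-sample cell-population frequency table
#'
#' @param annotation data.frame with `sample_id` and `population`.
#' @param level `"all_cells"` (fractions of all cells per sample, rows sum
#'   to 1) or `"within_parent"` (fractions within a `parent` column
#'   grouping).
#' @param min_samples optional: drop populations present in fewer than this
#'   many samples.
#' @return samples x populations numeric matrix; absent populations are 0.
#' @export
population_frequencies <- function(annotation,
                                   level = c("all_cells", "within_parent"),
                                   min_samples = NULL) {
  level <- match.arg(level)
  stopifnot(all(c("sample_id", "population") %in% names(annotation)))
  tab <- table(annotation$sample_id, annotation$population)
  freq <- if (level == "all_cells") {
    sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
  } else {
    stopifnot("parent" %in% names(annotation))
    parent_of <- tapply(annotation$parent, annotation$population,
                        function(p) p[1])
    parent_tot <- table(annotation$sample_id, annotation$parent)
    denom <- unclass(parent_tot)[, parent_of[colnames(tab)], drop = FALSE]
    unclass(tab) / pmax(denom, 1)
  }
  freq <- as.matrix(freq)
  if (!is.null(min_samples)) {
    present <- colSums(freq > 0)
    freq <- freq[, present >= min_samples, drop = FALSE]
  }
  freq
}
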