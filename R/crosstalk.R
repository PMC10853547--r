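#' Co-enrichment of cell-population frequencies across samples
#'
#' Pairwise Pearson correlation of population frequencies across samples;
#' pairs with correlation strictly above `threshold` are flagged
#' significant (off-diagonal only). Zero-variance populations yield `NA`
#' correlations for their pairs.
#'
#' @param freq samples x populations frequency matrix
#'   (see [population_frequencies()]).
#' @param threshold significance threshold on r.
#' @return list with `r` (correlation matrix, diagonal 1) and
#'   `significant` (logical mask).
#' @export
coenrichment <- function(freq, threshold = 0.3) {
  if (nrow(freq) < 3) stop("co-enrichment needs at least 3 samples")
  sds <- apply(freq, 2, stats::sd)
  r <- suppressWarnings(stats::cor(freq, method = "pearson"))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  sig <- !is.na(r) & r > threshold
  diag(sig) <- FALSE
  list(r = r, significant = sig)
}

#' Ligand-receptor interaction test by cluster-label permutation
#'
#' For each sender/receiver cluster pair and each ligand-receptor gene
#' pair: the interaction statistic is the mean of (mean ligand expression
#' in the sender cluster, mean receptor expression in the receiver
#' cluster). Pairs where the ligand (receptor) is expressed in fewer than
#' `min_frac` of sender (receiver) cells are skipped. The null permutes
#' cluster labels within the union of the two clusters; the one-sided p is
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param lognorm expression matrix.
#' @param annotation data.frame with `cell_id`, `cluster`.
#' @param pairs ligand-receptor table (`pair_id`, `ligand`, `receptor`).
#' @param cluster_pairs list of `c(sender, receiver)` cluster label pairs.
#' @param n_perm number of permutations.
#' @param min_frac expression-fraction threshold.
#' @param seed RNG seed.
#' @param bh add a BH-adjusted p column (adjustment is across all reported
#'   rows; the primary readout is the raw p).
#' @return data.frame: sender, receiver, ligand, receptor, interaction
#'   mean, expression fractions, `p_value` (and `adj_p_value` when `bh`).
#' @export
lr_permutation_test <- function(lognorm, annotation, pairs, cluster_pairs,
                                n_perm = 1000, min_frac = 0.1, seed = 1,
                                bh = FALSE) {
  cl <- annotation$cluster[match(colnames(lognorm), annotation$cell_id)]
  set.seed(seed)
  rows <- list()
  for (cp in cluster_pairs) {
    a_cells <- which(cl == cp[1])
    b_cells <- which(cl == cp[2])
    if (length(a_cells) < 10 || length(b_cells) < 10)
      stop(sprintf("clusters '%s'/'%s' need at least 10 cells each",
                   cp[1], cp[2]))
    pool <- c(a_cells, b_cells)
    na <- length(a_cells)
    np <- length(pool)
    ## shared permutations for all LR pairs of this cluster pair:
    ## indicator matrix of which pooled cells land in the sender cluster
    perm_a <- matrix(FALSE, np, n_perm)
    for (p in seq_len(n_perm)) perm_a[sample.int(np, na), p] <- TRUE
    nb <- np - na
    for (i in seq_len(nrow(pairs))) {
      lg <- pairs$ligand[i]; rc <- pairs$receptor[i]
      if (!lg %in% rownames(lognorm) || !rc %in% rownames(lognorm)) {
        warning(sprintf("pair %s: gene absent from matrix; skipped",
                        pairs$pair_id[i]))
        next
      }
      frac_l <- mean(lognorm[lg, a_cells] > 0)
      frac_r <- mean(lognorm[rc, b_cells] > 0)
      if (frac_l < min_frac || frac_r < min_frac) next
      obs <- (mean(lognorm[lg, a_cells]) + mean(lognorm[rc, b_cells])) / 2
      xl <- lognorm[lg, pool]; xr <- lognorm[rc, pool]
      mean_a <- crossprod(xl, perm_a)[1, ] / na
      mean_b <- (sum(xr) - crossprod(xr, perm_a)[1, ]) / nb
      null_stat <- (mean_a + mean_b) / 2
      pval <- (1 + sum(null_stat >= obs)) / (n_perm + 1)
      rows[[length(rows) + 1]] <- data.frame(
        sender = cp[1], receiver = cp[2], ligand = lg, receptor = rc,
        interaction_mean = obs, frac_ligand = frac_l, frac_receptor = frac_r,
        p_value = pval)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (bh) out$adj_p_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

## exact nearest-neighbor distances from each source point to the target set
nn_dist <- function(src_xy, tgt_xy) {
  d2 <- outer(src_xy[, 1], tgt_xy[, 1], "-")^2 +
    outer(src_xy[, 2], tgt_xy[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Spatial proximity of phenotyped cells within regions of interest
#'
#' Per ROI, the Euclidean distance from each source-phenotype cell to its
#' nearest target-phenotype cell is computed (within the ROI only);
#' distances above `radius_um` are excluded and counted. The two source
#' phenotypes' pooled distance distributions are compared by a two-sided
#' Wilcoxon test; per-ROI mean distances are also reported.
#'
#' @param cells data.frame `roi_id`, `x_um`, `y_um`, `phenotype`.
#' @param source_phenotypes two phenotype names to compare.
#' @param target_phenotype the phenotype distances are measured to.
#' @param radius_um capture radius in micrometers.
#' @return list with `distances` (roi_id, phenotype, distance),
#'   `roi_means`, `n_excluded` (per source phenotype, beyond the radius),
#'   `p_value`.
#' @export
spatial_proximity <- function(cells, source_phenotypes, target_phenotype,
                              radius_um = 200) {
  stopifnot(length(source_phenotypes) == 2)
  rows <- list()
  excl <- stats::setNames(c(0L, 0L), source_phenotypes)
  for (roi in unique(cells$roi_id)) {
    sub <- cells[cells$roi_id == roi, ]
    tgt <- sub[sub$phenotype == target_phenotype, c("x_um", "y_um")]
    if (nrow(tgt) == 0) {
      warning(sprintf("ROI %s lacks target phenotype; skipped", roi))
      next
    }
    for (ph in source_phenotypes) {
      src <- sub[sub$phenotype == ph, c("x_um", "y_um")]
      if (nrow(src) == 0) next
      d <- nn_dist(as.matrix(src), as.matrix(tgt))
      excl[ph] <- excl[ph] + sum(d > radius_um)
      d <- d[d <= radius_um]
      if (length(d))
        rows[[length(rows) + 1]] <- data.frame(roi_id = roi, phenotype = ph,
                                               distance = d)
    }
  }
  dist_df <- do.call(rbind, rows)
  if (is.null(dist_df)) stop("no ROI contained both a source and the target phenotype")
  roi_means <- stats::aggregate(distance ~ roi_id + phenotype, dist_df, mean)
  d1 <- dist_df$distance[dist_df$phenotype == source_phenotypes[1]]
  d2 <- dist_df$distance[dist_df$phenotype == source_phenotypes[2]]
  p <- if (length(d1) && length(d2)) wilcox_rank_sum(d1, d2)$p_value
       else NA_real_
  list(distances = dist_df, roi_means = roi_means, n_excluded = excl,
       p_value = p)
}
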