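## Synthetic-data generators. Every dataset the pipeline consumes can be
## produced here with planted ground truth, so each analysis stage can be
## validated by parameter recovery rather than by fixtures.

#' Configuration for the single-cell count generator
#'
#' @param n_samples number of tumor samples.
#' @param n_cells_per_sample cells drawn per sample.
#' @param n_genes gene universe size.
#' @param populations data.frame with columns `name`, `baseline_fraction`
#'   (summing to 1), `marker_genes` (count of planted markers) and
#'   `marker_log2fc` (log2 fold-change of markers in their population).
#' @param malignant_population name of the population carrying CNV blocks,
#'   or `NULL`.
#' @param cnv_blocks data.frame with columns `chromosome`,
#'   `start_gene_index`, `end_gene_index`, `log2_shift`; indices are global
#'   gene indices and must fall inside the named chromosome.
#' @param coenrich_pairs list of `list(pair = c(popA, popB), r = target)`
#'   giving target Pearson correlations of per-sample population fractions.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param latent_sd standard deviation of the logistic-normal latent field
#'   controlling per-sample composition variability.
#' @param n_chromosomes chromosomes the gene universe is split into, in
#'   index order.
#' @param seed RNG seed.
#' @return validated config list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_samples, n_cells_per_sample, n_genes, populations,
                          malignant_population = NULL, cnv_blocks = NULL,
                          coenrich_pairs = NULL, nb_dispersion = 0.4,
                          latent_sd = 0.8, n_chromosomes = 10, seed = 1) {
  stopifnot(is.data.frame(populations),
            all(c("name", "baseline_fraction", "marker_genes",
                  "marker_log2fc") %in% names(populations)))
  if (abs(sum(populations$baseline_fraction) - 1) > 1e-9)
    stop("population baseline fractions must sum to 1")
  if (!is.null(malignant_population) &&
      !malignant_population %in% populations$name)
    stop("malignant_population not among population names")
  if (!is.null(cnv_blocks)) {
    if (any(cnv_blocks$start_gene_index < 1) ||
        any(cnv_blocks$end_gene_index > n_genes) ||
        any(cnv_blocks$start_gene_index > cnv_blocks$end_gene_index))
      stop("cnv_blocks lie outside the gene index range")
  }
  if (!is.null(coenrich_pairs)) {
    for (cp in coenrich_pairs) {
      if (abs(cp$r) > 1) stop("target_correlation must be in [-1, 1]")
      if (!all(cp$pair %in% populations$name))
        stop("coenrich pair names unknown")
    }
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  structure(list(n_samples = check_count(n_samples, "n_samples"),
                 n_cells_per_sample = check_count(n_cells_per_sample,
                                                  "n_cells_per_sample"),
                 n_genes = check_count(n_genes, "n_genes"),
                 populations = populations,
                 malignant_population = malignant_population,
                 cnv_blocks = cnv_blocks, coenrich_pairs = coenrich_pairs,
                 nb_dispersion = nb_dispersion, latent_sd = latent_sd,
                 n_chromosomes = n_chromosomes, seed = as.integer(seed)),
            class = "sc_sim_config")
}

## latent covariance realizing the coenrichment targets on the logistic
## scale. The softmax closure centers the latent field, which attenuates a
## pairwise latent correlation rho to roughly
##   (rho + A) / (1 + A),  A = -(K + 2(K-1) rho) / K^2
## for K populations; we invert that map so the *centered* latent
## correlation matches the target, then eigenvalue-clip to the nearest
## positive semi-definite matrix.
coenrich_sigma <- function(pop_names, coenrich_pairs, latent_sd) {
  k <- length(pop_names)
  C <- diag(k)
  dimnames(C) <- list(pop_names, pop_names)
  for (cp in coenrich_pairs) {
    t <- cp$r
    rho <- (t + (1 - t) / k) / (1 - 2 * (1 - t) * (k - 1) / k^2)
    rho <- max(min(rho, 0.99), -0.99)
    C[cp$pair[1], cp$pair[2]] <- rho
    C[cp$pair[2], cp$pair[1]] <- rho
  }
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    C <- ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors)
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
    dimnames(C) <- list(pop_names, pop_names)
  }
  latent_sd^2 * C
}

## draw per-sample population fractions from the logistic-normal model
draw_fractions <- function(n, baseline, sigma) {
  k <- length(baseline)
  L <- chol(sigma)
  z <- matrix(stats::rnorm(n * k), n, k) %*% L
  eta <- sweep(z, 2, log(baseline), "+")
  f <- exp(eta - apply(eta, 1, max))
  f <- f / rowSums(f)
  colnames(f) <- names(baseline)
  f
}

#' Generate a multi-sample single-cell count dataset with planted structure
#'
#' Counts are negative binomial around population-specific mean profiles
#' with log-normal library-size variation per cell. Each population's
#' planted marker genes are up-shifted by `marker_log2fc`; malignant cells
#' additionally carry multiplicative chromosome-block shifts emulating
#' copy-number alterations. Per-sample composition follows a
#' logistic-normal model whose latent correlations realize the requested
#' co-enrichment targets.
#'
#' @param config a [sc_sim_config()].
#' @return list with `counts` (expression matrix, counts layer),
#'   `annotation` (cell_id, sample_id, cluster, population, malignant),
#'   `coords` (gene coordinate table) and `truth` (all planted values).
#' @export
gen_sc_dataset <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  pops <- config$populations
  k <- nrow(pops)
  genes <- sprintf("G%05d", seq_len(ng))

  ## chromosomes assigned in index order, equal contiguous blocks
  chrom_of <- paste0("chr", ceiling(seq_len(ng) / ceiling(ng / config$n_chromosomes)))
  pos_in_chrom <- stats::ave(seq_len(ng), chrom_of, FUN = seq_along)
  coords <- data.frame(gene = genes, chromosome = chrom_of,
                       start = (pos_in_chrom - 1) * 1000L,
                       end = pos_in_chrom * 1000L)

  ## baseline mean counts per gene, population-specific marker shifts
  lambda <- stats::rlnorm(ng, meanlog = log(2), sdlog = 1)
  mult <- matrix(1, ng, k, dimnames = list(genes, pops$name))
  marker_pool <- sample.int(ng)
  marker_genes <- list()
  offset <- 0
  for (j in seq_len(k)) {
    idx <- marker_pool[offset + seq_len(pops$marker_genes[j])]
    offset <- offset + pops$marker_genes[j]
    mult[idx, j] <- 2^pops$marker_log2fc[j]
    marker_genes[[pops$name[j]]] <- genes[sort(idx)]
  }

  cnv_gene_idx <- integer(0)
  if (!is.null(config$cnv_blocks) && !is.null(config$malignant_population)) {
    jm <- match(config$malignant_population, pops$name)
    for (b in seq_len(nrow(config$cnv_blocks))) {
      idx <- config$cnv_blocks$start_gene_index[b]:config$cnv_blocks$end_gene_index[b]
      mult[idx, jm] <- mult[idx, jm] * 2^config$cnv_blocks$log2_shift[b]
      cnv_gene_idx <- union(cnv_gene_idx, idx)
    }
  }

  baseline <- stats::setNames(pops$baseline_fraction, pops$name)
  sigma <- coenrich_sigma(pops$name, config$coenrich_pairs, config$latent_sd)
  fractions <- draw_fractions(config$n_samples, baseline, sigma)
  rownames(fractions) <- sprintf("S%03d", seq_len(config$n_samples))

  n_cells <- config$n_samples * config$n_cells_per_sample
  sample_id <- rep(rownames(fractions), each = config$n_cells_per_sample)
  population <- character(n_cells)
  for (s in seq_len(config$n_samples)) {
    i <- (s - 1) * config$n_cells_per_sample + seq_len(config$n_cells_per_sample)
    population[i] <- sample(pops$name, config$n_cells_per_sample,
                            replace = TRUE, prob = fractions[s, ])
  }
  libf <- stats::rlnorm(n_cells, meanlog = 0, sdlog = 0.3)

  counts <- matrix(0L, ng, n_cells)
  size <- 1 / config$nb_dispersion
  for (i in seq_len(n_cells)) {
    mu <- lambda * mult[, population[i]] * libf[i]
    counts[, i] <- stats::rnbinom(ng, size = size, mu = mu)
  }
  rownames(counts) <- genes
  colnames(counts) <- sprintf("C%06d", seq_len(n_cells))

  annotation <- data.frame(cell_id = colnames(counts), sample_id = sample_id,
                           cluster = population, population = population,
                           malignant = if (is.null(config$malignant_population))
                             rep(FALSE, n_cells)
                           else population == config$malignant_population)
  truth <- list(config = config, marker_genes = marker_genes,
                fractions = fractions, lambda = lambda, multipliers = mult,
                profiles = lambda * mult, normal_profile = lambda,
                cnv_genes = genes[sort(cnv_gene_idx)],
                baseline = baseline, sigma = sigma)
  list(counts = expression_matrix(counts, "counts"),
       annotation = annotation, coords = coords, truth = truth)
}

#' Configuration for the bulk-cohort generator
#'
#' @param n_patients cohort size.
#' @param purity_mean,purity_sd normal parameters of tumor purity, draws
#'   clipped to (0.05, 1].
#' @param hazard_coefficients named numeric vector, log-hazard per unit
#'   population abundance; names must be population names.
#' @param censoring_rate expected fraction of censored patients, in [0, 1].
#' @param baseline_hazard exponential baseline event rate (per time unit).
#' @param noise_sd Gaussian noise added to log2 bulk expression.
#' @param seed RNG seed.
#' @return config list of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_patients, purity_mean = 0.7, purity_sd = 0.1,
                            hazard_coefficients = numeric(0),
                            censoring_rate = 0.3, baseline_hazard = 0.02,
                            noise_sd = 0.2, seed = 1) {
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  structure(list(n_patients = check_count(n_patients, "n_patients"),
                 purity_mean = purity_mean, purity_sd = purity_sd,
                 hazard_coefficients = hazard_coefficients,
                 censoring_rate = censoring_rate,
                 baseline_hazard = baseline_hazard, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Generate a bulk cohort as purity-weighted mixtures with planted survival
#'
#' Patient expression is `purity x (abundance-weighted mixture of
#' population profiles) + (1 - purity) x normal profile`, log2-transformed,
#' plus Gaussian noise. Survival times are exponential with log-hazard
#' linear in the planted population abundances; censoring is independent.
#'
#' @param sc_truth the `truth` element of [gen_sc_dataset()] output
#'   (supplies population mean profiles and the composition model).
#' @param config a [bulk_sim_config()].
#' @return list with `bulk` (expression matrix, bulk layer), `survival`
#'   (sample_id, time, event), `purity` (named vector) and `truth`
#'   (abundances, hazards, planted coefficients).
#' @export
gen_bulk_cohort <- function(sc_truth, config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  hc <- config$hazard_coefficients
  if (length(hc) && !all(names(hc) %in% names(sc_truth$baseline)))
    stop("hazard_coefficients name unknown populations")
  set.seed(config$seed)
  n <- config$n_patients
  abund <- draw_fractions(n, sc_truth$baseline, sc_truth$sigma)
  patients <- sprintf("P%04d", seq_len(n))
  rownames(abund) <- patients

  purity <- stats::rnorm(n, config$purity_mean, config$purity_sd)
  purity <- pmin(pmax(purity, 0.05), 1)
  names(purity) <- patients

  tumor <- sc_truth$profiles %*% t(abund)          # genes x patients
  mix <- sweep(tumor, 2, purity, "*") +
    outer(sc_truth$normal_profile, 1 - purity)
  expr <- log2(1 + mix) +
    matrix(stats::rnorm(length(mix), 0, config$noise_sd), nrow(mix))
  rownames(expr) <- rownames(sc_truth$profiles)
  colnames(expr) <- patients

  loghaz <- as.numeric(abund[, names(hc), drop = FALSE] %*% hc)
  haz <- config$baseline_hazard * exp(loghaz)
  t_event <- stats::rexp(n, rate = haz)
  censored <- stats::runif(n) < config$censoring_rate
  time <- ifelse(censored, stats::runif(n, 0, t_event), t_event)
  surv <- data.frame(sample_id = patients, time = time,
                     event = as.integer(!censored))
  truth <- list(config = config, abundance = abund, purity = purity,
                log_hazard = loghaz)
  list(bulk = expression_matrix(expr, "bulk"), survival = surv,
       purity = purity, truth = truth)
}

#' Configuration for the pharmacogenomic generator
#'
#' @param n_cell_lines,n_drugs,n_genes table dimensions (per dataset).
#' @param planted_drugs data.frame with columns `drug` and `coefficient`
#'   giving the log-IC50 coefficient on the UPP1-proxy gene.
#' @param response_noise_sd Gaussian noise on log-IC50.
#' @param seed RNG seed.
#' @return config list of class `pharmaco_sim_config`.
#' @export
pharmaco_sim_config <- function(n_cell_lines = 100, n_drugs = 20,
                                n_genes = 300, planted_drugs = NULL,
                                response_noise_sd = 0.5, seed = 1) {
  drugs <- sprintf("D%03d", seq_len(n_drugs))
  if (!is.null(planted_drugs) && !all(planted_drugs$drug %in% drugs))
    stop("planted drugs not in the drug list")
  if (response_noise_sd < 0) stop("response_noise_sd must be non-negative")
  structure(list(n_cell_lines = check_count(n_cell_lines, "n_cell_lines"),
                 n_drugs = check_count(n_drugs, "n_drugs"),
                 n_genes = check_count(n_genes, "n_genes"),
                 drugs = drugs, planted_drugs = planted_drugs,
                 response_noise_sd = response_noise_sd,
                 seed = as.integer(seed)),
            class = "pharmaco_sim_config")
}

#' Generate three pharmacogenomic datasets with planted drug-gene links
#'
#' Emulates CTRP/GDSC/PRISM-style panels: three datasets share the gene
#' space (gene 1 is the UPP1 proxy, named `UPP1`) but have dataset-specific
#' response offsets and independent cell lines. log-IC50 is a sparse linear
#' function of expression; planted drugs carry the configured coefficient
#' on the UPP1 proxy.
#'
#' @param config a [pharmaco_sim_config()].
#' @return list with `datasets` (named list of three, each with `expr`
#'   genes x lines, `response` lines x drugs, `tag`) and `truth`
#'   (coefficient matrix, offsets, planted drugs).
#' @export
gen_pharmaco_dataset <- function(config) {
  stopifnot(inherits(config, "pharmaco_sim_config"))
  set.seed(config$seed)
  genes <- c("UPP1", sprintf("PG%04d", seq_len(config$n_genes - 1)))
  drugs <- config$drugs

  ## sparse coefficients shared across datasets
  beta <- matrix(0, config$n_genes, config$n_drugs,
                 dimnames = list(genes, drugs))
  for (d in seq_len(config$n_drugs)) {
    idx <- sample(2:config$n_genes, 5)
    beta[idx, d] <- stats::rnorm(5, 0, 0.3)
  }
  if (!is.null(config$planted_drugs)) {
    beta["UPP1", config$planted_drugs$drug] <- config$planted_drugs$coefficient
  }
  offsets <- stats::setNames(stats::rnorm(3, 0, 1), c("CTRP", "GDSC", "PRISM"))

  datasets <- lapply(names(offsets), function(tag) {
    x <- matrix(stats::rnorm(config$n_genes * config$n_cell_lines), config$n_genes,
                dimnames = list(genes, sprintf("%s_CL%03d", tag,
                                               seq_len(config$n_cell_lines))))
    y <- t(x) %*% beta + offsets[tag] +
      matrix(stats::rnorm(config$n_cell_lines * config$n_drugs, 0,
                          config$response_noise_sd), config$n_cell_lines)
    list(expr = x, response = y, tag = tag)
  })
  names(datasets) <- names(offsets)
  list(datasets = datasets,
       truth = list(config = config, beta = beta, offsets = offsets,
                    planted_drugs = config$planted_drugs, genes = genes))
}

#' Draw patient expression from the pharmacogenomic gene space
#'
#' Convenience companion to [gen_pharmaco_dataset()] for end-to-end drug
#' screens: patients share the training feature distribution so planted
#' drug-gene links carry over to imputed responses.
#'
#' @param n_patients number of patients.
#' @param pharmaco_truth `truth` element of [gen_pharmaco_dataset()].
#' @param seed RNG seed.
#' @return genes x patients expression matrix (bulk layer).
#' @export
gen_patient_expression <- function(n_patients, pharmaco_truth, seed = 1) {
  set.seed(seed)
  genes <- pharmaco_truth$genes
  x <- matrix(stats::rnorm(length(genes) * n_patients), length(genes),
              dimnames = list(genes, sprintf("PT%04d", seq_len(n_patients))))
  expression_matrix(x, "bulk")
}

#' Configuration for the spatial point-pattern generator
#'
#' @param n_rois number of regions of interest.
#' @param roi_width_um,roi_height_um ROI extent in micrometers.
#' @param phenotypes data.frame with columns `name`, `count`, `attract_to`
#'   (target phenotype name or `NA`), `length_scale_um` (Gaussian
#'   displacement scale for attracted phenotypes; `NA` when uniform).
#' @param seed RNG seed.
#' @return config list of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(n_rois, roi_width_um = 500,
                               roi_height_um = 500, phenotypes, seed = 1) {
  stopifnot(is.data.frame(phenotypes),
            all(c("name", "count") %in% names(phenotypes)))
  if (any(phenotypes$count <= 0)) stop("phenotype counts must be positive")
  if (!is.null(phenotypes$length_scale_um) &&
      any(stats::na.omit(phenotypes$length_scale_um) <= 0))
    stop("length scales must be positive")
  structure(list(n_rois = check_count(n_rois, "n_rois"),
                 roi_width_um = roi_width_um, roi_height_um = roi_height_um,
                 phenotypes = phenotypes, seed = as.integer(seed)),
            class = "spatial_sim_config")
}

#' Generate phenotyped cell coordinates over regions of interest
#'
#' Per ROI, phenotypes without attraction are placed uniformly; attracted
#' phenotypes are placed by Gaussian displacement (the configured length
#' scale) from uniformly chosen parent cells of their target phenotype,
#' reflected back into the ROI.
#'
#' @param config a [spatial_sim_config()].
#' @return data.frame with columns `roi_id`, `x_um`, `y_um`, `phenotype`.
#' @export
gen_spatial_rois <- function(config) {
  stopifnot(inherits(config, "spatial_sim_config"))
  set.seed(config$seed)
  ph <- config$phenotypes
  w <- config$roi_width_um; h <- config$roi_height_um
  out <- list()
  for (r in seq_len(config$n_rois)) {
    roi <- sprintf("ROI%02d", r)
    placed <- list()
    attract <- if (is.null(ph$attract_to)) rep(NA_character_, nrow(ph)) else ph$attract_to
    for (pass in 1:2) {                      # parents first, attracted second
      for (j in seq_len(nrow(ph))) {
        is_attracted <- !is.na(attract[j])
        if ((pass == 1) == is_attracted) next
        n <- ph$count[j]
        if (!is_attracted) {
          xy <- cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
        } else {
          parents <- placed[[attract[j]]]
          if (is.null(parents))
            stop(sprintf("attraction target '%s' not placed before '%s'",
                         attract[j], ph$name[j]))
          pi <- parents[sample.int(nrow(parents), n, replace = TRUE), , drop = FALSE]
          ls <- ph$length_scale_um[j]
          xy <- pi + matrix(stats::rnorm(2 * n, 0, ls), n)
          ## reflect back into the ROI
          xy[, 1] <- abs(xy[, 1]); xy[, 1] <- w - abs(w - xy[, 1])
          xy[, 2] <- abs(xy[, 2]); xy[, 2] <- h - abs(h - xy[, 2])
        }
        placed[[ph$name[j]]] <- xy
        out[[length(out) + 1]] <- data.frame(roi_id = roi, x_um = xy[, 1],
                                             y_um = xy[, 2],
                                             phenotype = ph$name[j])
      }
    }
  }
  do.call(rbind, out)
}

#' Generate a random ligand-receptor pair table
#'
#' Draws `n_pairs` distinct ordered (ligand, receptor) pairs with ligand
#' different from receptor.
#'
#' @param n_pairs number of pairs.
#' @param genes gene universe (non-empty character vector).
#' @param seed RNG seed.
#' @return data.frame with columns `pair_id`, `ligand`, `receptor`.
#' @export
gen_lr_table <- function(n_pairs, genes, seed = 1) {
  if (length(genes) == 0) stop("gene list must be non-empty")
  g <- length(genes)
  capacity <- g * (g - 1)
  if (n_pairs > capacity)
    stop(sprintf("requested %d pairs but only %d distinct ordered pairs exist",
                 n_pairs, capacity))
  set.seed(seed)
  if (n_pairs == 0)
    return(data.frame(pair_id = character(0), ligand = character(0),
                      receptor = character(0)))
  idx <- sample.int(capacity, n_pairs) - 1L
  li <- idx %/% (g - 1L) + 1L
  rj <- idx %% (g - 1L) + 1L
  rj <- ifelse(rj >= li, rj + 1L, rj)      # skip the diagonal
  data.frame(pair_id = sprintf("LR%04d", seq_len(n_pairs)),
             ligand = genes[li], receptor = genes[rj])
}
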