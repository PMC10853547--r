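#' Tumor purity from stromal and immune enrichment
#'
#' Stromal and immune signature scores are computed by unnormalized
#' [ssgsea()]; their sum is the combined score, and purity is
#' `cos(a + b * score)`, the fixed cosine transform of the ESTIMATE
#' approach, clipped to (0.01, 1].
#'
#' @param bulk bulk expression matrix.
#' @param stromal_set,immune_set character vectors of signature genes.
#' @param constants `c(a, b)` of the cosine transform.
#' @return list of class `purity_model` with `purity` (named vector),
#'   `stromal`, `immune`, `combined_score`, `source`.
#' @export
estimate_purity <- function(bulk, stromal_set, immune_set,
                            constants = c(a = 0.6049872018, b = 0.0001467884)) {
  sets <- gene_set_collection(list(stromal = stromal_set,
                                   immune = immune_set))
  sc <- ssgsea(bulk, sets, alpha = 0.25, normalize = FALSE)
  combined <- sc[, "stromal"] + sc[, "immune"]
  arg <- constants[["a"]] + constants[["b"]] * combined
  if (any(arg < 0) || any(arg > pi / 2)) {
    warning("cosine argument outside [0, pi/2]; clipped")
    arg <- pmin(pmax(arg, 0), pi / 2)
  }
  purity <- pmin(pmax(cos(arg), 0.01), 1)
  structure(list(purity = purity, stromal = sc[, "stromal"],
                 immune = sc[, "immune"], combined_score = combined,
                 source = "estimate_formula"),
            class = "purity_model")
}

#' Wrap user-supplied purity values
#' @param purity named numeric vector in (0, 1].
#' @return a `purity_model` with source tag `user_supplied`.
#' @export
purity_model <- function(purity) {
  if (any(purity <= 0) || any(purity > 1)) stop("purity must lie in (0, 1]")
  structure(list(purity = purity, source = "user_supplied"),
            class = "purity_model")
}

#' Residualize bulk expression on tumor purity
#'
#' Per gene, ordinary least squares of expression on (intercept, purity);
#' the output is the residual matrix, mean-zero and orthogonal to purity
#' gene by gene.
#'
#' @param bulk bulk expression matrix (genes x samples).
#' @param purity a `purity_model` or named numeric vector covering the
#'   samples.
#' @return residual expression matrix (bulk layer).
#' @export
purity_residualize <- function(bulk, purity) {
  if (inherits(purity, "purity_model")) purity <- purity$purity
  p <- purity[colnames(bulk)]
  if (anyNA(p)) stop("purity missing for some samples")
  if (stats::sd(p) <= 1e-8)
    stop("purity is constant; skip the purity adjustment instead")
  x <- cbind(1, p)
  beta <- solve(crossprod(x), crossprod(x, t(unclass(bulk))))
  res <- unclass(bulk) - t(x %*% beta)
  expression_matrix(res, "bulk")
}

## Kaplan-Meier product-limit estimator with Greenwood variance
km_curve <- function(time, event) {
  dt <- sort(unique(time[event == 1]))
  s <- 1
  gw <- 0
  out <- data.frame(time = dt, n_risk = NA_real_, n_event = NA_real_,
                    surv = NA_real_, se = NA_real_)
  for (i in seq_along(dt)) {
    n <- sum(time >= dt[i])
    d <- sum(time == dt[i] & event == 1)
    s <- s * (1 - d / n)
    gw <- gw + if (n > d) d / (n * (n - d)) else 0
    out$n_risk[i] <- n; out$n_event[i] <- d
    out$surv[i] <- s; out$se[i] <- s * sqrt(gw)
  }
  out
}

#' Log-rank test and Kaplan-Meier curves for a binary split
#'
#' At each distinct event time the observed deaths in group 1 are compared
#' with the hypergeometric expectation; the statistic is
#' `(sum O - sum E)^2 / sum V`, chi-square with 1 df.
#'
#' @param surv survival table (`sample_id`, `time`, `event`).
#' @param groups logical or two-level vector aligned to `surv` rows;
#'   `TRUE` / the alphabetically first level is group 1 (so labels
#'   `"high"` / `"low"` place `"high"` in group 1).
#' @return list with `statistic`, `p_value`, `o_minus_e`, `var`, and
#'   `curves` (per-group KM tables).
#' @export
km_logrank <- function(surv, groups) {
  g1 <- to_group1(groups, nrow(surv))
  if (sum(g1) == 0 || sum(!g1) == 0) stop("both groups must be non-empty")
  if (sum(surv$event[g1]) == 0 || sum(surv$event[!g1]) == 0)
    stop("each group needs at least one event")
  lr <- logrank_core(surv$time, surv$event, g1)
  curves <- list(group1 = km_curve(surv$time[g1], surv$event[g1]),
                 group0 = km_curve(surv$time[!g1], surv$event[!g1]))
  list(statistic = lr$statistic, p_value = lr$p_value,
       o_minus_e = lr$o_minus_e, var = lr$var, curves = curves)
}

to_group1 <- function(groups, n) {
  stopifnot(length(groups) == n)
  if (is.logical(groups)) return(groups)
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2) stop("groups must have exactly two levels")
  as.character(groups) == lv[1]
}

#' Univariate Cox hazard ratio for a binary split
#'
#' Maximizes the Breslow partial likelihood for a single binary covariate
#' by Newton-Raphson (convergence `|delta beta| < 1e-8`). Complete
#' separation is reported as an infinite (or zero) hazard ratio with a
#' warning.
#'
#' @inheritParams km_logrank
#' @return list with `hr`, `ci` (95% Wald), `beta`, `se`, `p_value`.
#' @export
cox_hr <- function(surv, groups) {
  g1 <- to_group1(groups, nrow(surv))
  if (sum(surv$event[g1]) == 0 || sum(surv$event[!g1]) == 0)
    stop("each group needs at least one event")
  st <- surv_tables(surv$time, surv$event, g1)
  d <- st$d; s <- st$d1; n1 <- st$n_risk1; n0 <- st$n_risk - st$n_risk1
  beta <- 0
  for (it in 1:100) {
    eb <- exp(beta)
    prob <- n1 * eb / (n0 + n1 * eb)
    u <- sum(s - d * prob)
    info <- sum(d * prob * (1 - prob))
    if (info < 1e-12 || abs(beta) > 15) {
      warning("complete separation in Cox fit; hazard ratio reported as a sentinel")
      hr <- if (beta > 0 || (info < 1e-12 && u > 0)) Inf else 0
      return(list(hr = hr, ci = c(NA_real_, NA_real_), beta = sign(hr - 1) * Inf,
                  se = NA_real_, p_value = NA_real_))
    }
    delta <- u / info
    beta <- beta + delta
    if (abs(delta) < 1e-8) break
  }
  se <- 1 / sqrt(info)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * 1.96 * se),
       beta = beta, se = se,
       p_value = 2 * stats::pnorm(-abs(beta / se)))
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every unique score value whose induced high/low split leaves at
#' least `minprop` of the samples on each side, computes the standardized
#' log-rank statistic for each, and returns the cutpoint maximizing its
#' absolute value (ties resolved toward the smaller cutpoint).
#'
#' @param scores numeric vector aligned to `surv` rows.
#' @param surv survival table.
#' @param minprop minimum group proportion.
#' @return list with `cutpoint`, `high` (logical: score > cutpoint),
#'   `statistic` (standardized log-rank z at the cutpoint).
#' @export
optimal_cutpoint <- function(scores, surv, minprop = 0.1) {
  n <- length(scores)
  stopifnot(n == nrow(surv))
  if (sum(surv$event) == 0) stop("no events in the survival table")
  cand <- sort(unique(scores))
  nmin <- minprop * n
  valid <- vapply(cand, function(c) {
    nh <- sum(scores > c); nh >= nmin && (n - nh) >= nmin
  }, logical(1))
  cand <- cand[valid]
  if (!length(cand)) stop("no valid cutpoint candidate under minprop")
  z <- vapply(cand, function(c) {
    lr <- logrank_core(surv$time, surv$event, scores > c)
    lr$z
  }, numeric(1))
  best <- which.max(abs(z))           # first max = smaller cutpoint on ties
  list(cutpoint = cand[best], high = scores > cand[best],
       statistic = z[best])
}

#' Cross-cohort prognostic scan of cell-population signatures
#'
#' For every cohort and population signature: residualize the bulk matrix
#' on purity, score the signature by [ssgsea()], dichotomize at the
#' maximally selected log-rank cutpoint, and report the log-rank p and the
#' Cox hazard ratio of high vs low. A population is called adverse
#' (favorable) when HR > 1 (< 1) with p < `alpha` in every cohort, and
#' inconsistent otherwise; `consistency = "direction"` drops the per-cohort
#' significance requirement.
#'
#' @param cohorts named list, each element a list with `bulk` (expression
#'   matrix) and `survival` (survival table).
#' @param marker_sets gene-set collection, one set per population.
#' @param purity named list of `purity_model`s / purity vectors per cohort,
#'   or `NULL` to skip the adjustment.
#' @param alpha per-cohort significance threshold.
#' @param minprop cutpoint constraint, see [optimal_cutpoint()].
#' @param normalize passed to [ssgsea()].
#' @param consistency `"strict"` (default) or `"direction"`.
#' @return list with `grid` (one row per population x cohort: cutpoint,
#'   HR, CI, log-rank p) and `calls` (named vector: adverse / favorable /
#'   inconsistent).
#' @export
prognostic_scan <- function(cohorts, marker_sets, purity = NULL,
                            alpha = 0.05, minprop = 0.1, normalize = TRUE,
                            consistency = c("strict", "direction")) {
  consistency <- match.arg(consistency)
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  rows <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    bulk <- co$bulk
    if (!is.null(purity) && !is.null(purity[[cn]]))
      bulk <- purity_residualize(bulk, purity[[cn]])
    sc <- tryCatch(ssgsea(bulk, marker_sets, normalize = normalize),
                   error = function(e) stop(e))
    surv <- co$survival
    sc <- sc[surv$sample_id, , drop = FALSE]
    for (pop in names(marker_sets$sets)) {
      if (!pop %in% colnames(sc)) {
        rows[[length(rows) + 1]] <- data.frame(
          population = pop, cohort = cn, cutpoint = NA_real_, hr = NA_real_,
          ci_lo = NA_real_, ci_hi = NA_real_, logrank_p = NA_real_)
        next
      }
      res <- tryCatch({
        cut <- optimal_cutpoint(sc[, pop], surv, minprop = minprop)
        lr <- km_logrank(surv, cut$high)
        cx <- cox_hr(surv, cut$high)
        data.frame(population = pop, cohort = cn, cutpoint = cut$cutpoint,
                   hr = cx$hr, ci_lo = cx$ci[1], ci_hi = cx$ci[2],
                   logrank_p = lr$p_value)
      }, error = function(e) data.frame(
        population = pop, cohort = cn, cutpoint = NA_real_, hr = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, logrank_p = NA_real_))
      rows[[length(rows) + 1]] <- res
    }
  }
  grid <- do.call(rbind, rows)
  calls <- vapply(names(marker_sets$sets), function(pop) {
    g <- grid[grid$population == pop, ]
    if (anyNA(g$hr)) return("inconsistent")
    sig <- if (consistency == "strict") all(g$logrank_p < alpha) else TRUE
    if (all(g$hr > 1) && sig) "adverse"
    else if (all(g$hr < 1) && sig) "favorable"
    else "inconsistent"
  }, character(1))
  list(grid = grid, calls = calls)
}

#' Combined-signature microenvironment module analysis
#'
#' Unions the marker sets of the given populations into one module gene
#' set, scores it per patient with [gsva()], splits at the maximally
#' selected cutpoint, and reports log-rank / Cox results per cohort plus a
#' high-vs-low comparison of every microenvironment feature set (GSVA
#' scores, two-sided Wilcoxon, BH-adjusted).
#'
#' @param population_sets gene-set collection of the populations to merge.
#' @param cohorts named list of `list(bulk, survival)`.
#' @param tme_feature_sets gene-set collection of feature signatures, or
#'   `NULL` to skip the comparison.
#' @param minprop cutpoint constraint.
#' @return list per cohort: `module_genes`, `scores`, `cutpoint`,
#'   `logrank_p`, `hr`, `feature_diff` (feature, delta, p, adj_p).
#' @export
tme_module <- function(population_sets, cohorts, tme_feature_sets = NULL,
                       minprop = 0.1) {
  module <- unique(unlist(population_sets$sets))
  modset <- gene_set_collection(list(tme_module = module))
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  out <- lapply(names(cohorts), function(cn) {
    co <- cohorts[[cn]]
    sc <- gsva(co$bulk, modset)[co$survival$sample_id, 1]
    cut <- optimal_cutpoint(sc, co$survival, minprop = minprop)
    lr <- km_logrank(co$survival, cut$high)
    cx <- cox_hr(co$survival, cut$high)
    fdiff <- NULL
    if (!is.null(tme_feature_sets)) {
      fs <- gsva(co$bulk, tme_feature_sets)[co$survival$sample_id, ,
                                            drop = FALSE]
      p <- vapply(colnames(fs), function(f)
        wilcox_rank_sum(fs[cut$high, f], fs[!cut$high, f])$p_value,
        numeric(1))
      fdiff <- data.frame(feature = colnames(fs),
                          delta = colMeans(fs[cut$high, , drop = FALSE]) -
                            colMeans(fs[!cut$high, , drop = FALSE]),
                          p_value = p,
                          adj_p_value = stats::p.adjust(p, "BH"))
      rownames(fdiff) <- NULL
    }
    list(module_genes = module, scores = sc, cutpoint = cut$cutpoint,
         logrank_p = lr$p_value, hr = cx$hr, feature_diff = fdiff)
  })
  names(out) <- names(cohorts)
  out
}
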