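#' Fit a ridge-regression drug-response imputer
#'
#' Trains on cell-line expression (genes x lines) and one drug's response
#' vector (log-IC50 convention: lower = more sensitive). Features are the
#' `top_var_genes` most variable genes, standardized on the training data;
#' the intercept (the response mean) is unpenalized. The penalty is chosen
#' by generalized cross-validation over a log-spaced grid, or fixed.
#'
#' @param expr genes x cell-lines expression matrix.
#' @param response cell-lines x drugs response matrix (NAs allowed).
#' @param drug drug column to model; needs >= 10 non-missing responses.
#' @param lambda_rule `"gcv"` or `"fixed"`.
#' @param lambda penalty when `lambda_rule = "fixed"`.
#' @param top_var_genes number of features retained by training variance.
#' @return object of class `ridge_imputer`: coefficients on the
#'   standardized scale, training means/sds, intercept, lambda, fitted
#'   values.
#' @export
fit_ridge_imputer <- function(expr, response, drug,
                              lambda_rule = c("gcv", "fixed"), lambda = 1,
                              top_var_genes = 1000) {
  lambda_rule <- match.arg(lambda_rule)
  if (!drug %in% colnames(response)) stop("unknown drug")
  y <- response[, drug]
  ok <- !is.na(y)
  if (sum(ok) < 10) stop("drug needs at least 10 non-missing responses")
  lines <- intersect(rownames(response)[ok], colnames(expr))
  y <- y[lines]
  x <- t(expr[, lines, drop = FALSE])
  v <- apply(x, 2, stats::var)
  keep <- order(-v)[seq_len(min(top_var_genes, sum(v > 0)))]
  x <- x[, keep, drop = FALSE]
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  z <- sweep(sweep(x, 2, center), 2, scale_, "/")
  intercept <- mean(y)
  yc <- y - intercept

  sv <- svd(z)
  uty <- crossprod(sv$u, yc)
  n <- nrow(z)
  beta_for <- function(l) sv$v %*% (sv$d / (sv$d^2 + l) * uty)
  if (lambda_rule == "gcv") {
    grid <- 10^seq(-3, 3, length.out = 25)
    gcv <- vapply(grid, function(l) {
      df <- sum(sv$d^2 / (sv$d^2 + l)) + 1
      fit <- sv$u %*% (sv$d^2 / (sv$d^2 + l) * uty)
      rss <- sum((yc - fit)^2)
      n * rss / (n - df)^2
    }, numeric(1))
    lambda <- grid[which.min(gcv)]
  } else {
    if (lambda <= 0) {
      warning("lambda floor 1e-8 applied")
      lambda <- 1e-8
    }
  }
  beta <- drop(beta_for(lambda))
  names(beta) <- colnames(z)
  structure(list(drug = drug, genes = colnames(z), beta = beta,
                 center = center, scale = scale_, intercept = intercept,
                 lambda = lambda,
                 fitted = stats::setNames(drop(intercept + z %*% beta), lines)),
            class = "ridge_imputer")
}

#' Predict drug response for new expression profiles
#'
#' Aligns patient genes to the model's feature set (genes missing from the
#' patients enter at the training mean, i.e. standardized 0) and applies
#' the linear model. With `harmonize = "standardize"` (default) patient
#' genes are z-scored within the patient matrix itself — a deliberate
#' simplification of cross-platform batch correction; `"train"` applies
#' the training means/sds directly (no harmonization).
#'
#' @param model a `ridge_imputer`.
#' @param patient_expr genes x patients expression matrix; at least 50% of
#'   the model genes must be present.
#' @param harmonize `"standardize"` or `"train"`.
#' @return named numeric predicted response per patient.
#' @export
predict_response <- function(model, patient_expr,
                             harmonize = c("standardize", "train")) {
  harmonize <- match.arg(harmonize)
  present <- intersect(model$genes, rownames(patient_expr))
  if (length(present) < 0.5 * length(model$genes))
    stop("fewer than 50% of model genes present in the patient matrix")
  z <- matrix(0, ncol(patient_expr), length(model$genes),
              dimnames = list(colnames(patient_expr), model$genes))
  x <- t(patient_expr[present, , drop = FALSE])
  if (harmonize == "standardize") {
    mu <- colMeans(x)
    sd_ <- apply(x, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    z[, present] <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  } else {
    z[, present] <- sweep(sweep(x, 2, model$center[present]), 2,
                          model$scale[present], "/")
  }
  drop(model$intercept + z %*% model$beta)
}

#' Stratified differential drug sensitivity
#'
#' Patients (or cell lines) are split at the median of the stratum gene's
#' expression; per drug, the difference of median predicted response (high
#' minus low) and a two-sided Wilcoxon p are reported. A drug is a
#' candidate when the high stratum is more sensitive (`delta < 0`, lower
#' log-IC50) at `p < alpha`.
#'
#' @param predicted patients x drugs response matrix.
#' @param stratum_gene_expr named expression vector of the stratum gene
#'   over the same patients.
#' @param alpha significance threshold.
#' @return data.frame `drug`, `delta`, `p_value`, `candidate`.
#' @export
stratified_sensitivity <- function(predicted, stratum_gene_expr,
                                   alpha = 0.05) {
  x <- stratum_gene_expr[rownames(predicted)]
  if (anyNA(x)) stop("stratum gene expression missing for some patients")
  grp <- classify_by_median(x)
  hi <- grp == "high"
  if (sum(hi) < 10 || sum(!hi) < 10)
    stop("each stratum needs at least 10 patients")
  res <- lapply(colnames(predicted), function(d) {
    yh <- predicted[hi, d]; yl <- predicted[!hi, d]
    if (max(c(yh, yl)) == min(c(yh, yl))) {
      p <- 1
    } else {
      p <- wilcox_rank_sum(yh, yl)$p_value
    }
    delta <- stats::median(yh) - stats::median(yl)
    data.frame(drug = d, delta = delta, p_value = p,
               candidate = delta < 0 & p < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Integrate drug candidates across datasets and evidence levels
#'
#' Stage 1 combines the patient-level candidate lists of the datasets
#' (`intersection`: candidate in every dataset; `any_dataset`: in at least
#' one). Stage 2 intersects the stage-1 list with the cell-line-level
#' candidates (combined the same way). Provenance per surviving drug is
#' recorded.
#'
#' @param patient_results named list of [stratified_sensitivity()] tables
#'   (one per dataset).
#' @param cellline_results named list of [stratified_sensitivity()] tables
#'   from measured cell-line responses.
#' @param mode stage-1 combination rule.
#' @return list with `candidates` (character vector) and `provenance`
#'   (data.frame drug, patient_datasets, cellline_datasets).
#' @export
integrate_candidates <- function(patient_results, cellline_results,
                                 mode = c("intersection", "any_dataset")) {
  mode <- match.arg(mode)
  all_drugs <- Reduce(intersect, lapply(c(patient_results, cellline_results),
                                        function(r) r$drug))
  if (!length(all_drugs)) stop("result tables share no drug namespace")
  cand_of <- function(r) r$drug[r$candidate]
  combine <- function(lists) {
    if (mode == "intersection") Reduce(intersect, lists)
    else unique(unlist(lists))
  }
  stage1 <- combine(lapply(patient_results, cand_of))
  cl <- combine(lapply(cellline_results, cand_of))
  final <- intersect(stage1, cl)
  prov <- data.frame(
    drug = final,
    patient_datasets = vapply(final, function(d) paste(
      names(patient_results)[vapply(patient_results,
                                    function(r) d %in% cand_of(r), logical(1))],
      collapse = ","), character(1)),
    cellline_datasets = vapply(final, function(d) paste(
      names(cellline_results)[vapply(cellline_results,
                                     function(r) d %in% cand_of(r), logical(1))],
      collapse = ","), character(1)))
  rownames(prov) <- NULL
  list(candidates = final, provenance = prov)
}
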