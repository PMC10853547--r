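test_that("estimate_purity behaves monotonically and deterministically", {
  set.seed(30)
  m <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:4)))
  m[, 2] <- m[, 1]                          # identical samples
  stromal <- paste0("g", 1:10); immune <- paste0("g", 11:20)
  pm <- estimate_purity(expression_matrix(m, "bulk"), stromal, immune)
  expect_equal(pm$purity[["s1"]], pm$purity[["s2"]])
  expect_identical(pm$source, "estimate_formula")
  expect_true(all(pm$purity > 0 & pm$purity <= 1))

  ## pushing signature genes to the top of a sample lowers its purity
  m2 <- m
  m2[c(stromal, immune), 3] <- max(m) + seq_len(20)
  pm2 <- estimate_purity(expression_matrix(m2, "bulk"), stromal, immune)
  expect_lt(pm2$purity[["s3"]], pm$purity[["s3"]])

  up <- purity_model(c(s1 = 0.5, s2 = 0.9))
  expect_identical(up$source, "user_supplied")
  expect_error(purity_model(c(s1 = 0)), "\\(0, 1\\]")
})

test_that("purity_residualize matches closed-form least squares", {
  set.seed(31)
  n <- 25
  p <- runif(n, 0.3, 0.9)
  names(p) <- paste0("s", 1:n)
  m <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(paste0("g", 1:20), names(p)))
  m["g1", ] <- 2 * p + 1                     # exact linear gene
  em <- expression_matrix(m, "bulk")
  res <- purity_residualize(em, p)
  expect_lt(max(abs(res["g1", ])), 1e-10)
  ## closed-form (X'X)^-1 X'y per gene
  x <- cbind(1, p)
  for (g in c("g3", "g9", "g17")) {
    beta <- solve(t(x) %*% x) %*% t(x) %*% m[g, ]
    expect_equal(unname(res[g, ]), unname(m[g, ] - drop(x %*% beta)),
                 tolerance = 1e-10)
  }
  ## orthogonality and zero mean, every gene
  expect_lt(max(abs(rowMeans(res))), 1e-10)
  ## orthogonality, excluding exact-fit rows whose residual is numerical dust
  varying <- apply(res, 1, sd) > 1e-8
  expect_lt(max(abs(apply(res[varying, ], 1, function(r) cor(r, p)))), 1e-8)
  expect_error(purity_residualize(em, setNames(rep(0.5, n), names(p))),
               "constant")
})

test_that("km_logrank: identical groups give statistic 0, KM equals the ecdf", {
  s <- surv_tab(c(1, 2, 3, 4, 1, 2, 3, 4), rep(1, 8))
  r <- km_logrank(s, rep(c(TRUE, FALSE), each = 4))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  ## no censoring: survival curve equals the empirical survival function
  km <- r$curves$group1
  expect_equal(km$surv, 1 - ecdf(c(1, 2, 3, 4))(km$time))
  expect_error(km_logrank(surv_tab(1:4, c(0, 0, 1, 1)),
                          c(TRUE, TRUE, FALSE, FALSE)),
               "at least one event")
})

test_that("log-rank matches the brute-force tabulation and survdiff", {
  skip_if_not_installed("survival")
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(6:30, 1)
    time <- sample(1:10, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5) == 1
    if (sum(event) == 0 || sum(g) == 0 || sum(!g) == 0) next
    mine <- tmelink:::logrank_core(time, event, g)
    expect_equal(mine$statistic, logrank_oracle(time, event, g),
                 tolerance = 1e-10)
    ref <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
  }
})

test_that("cox_hr solves the partial likelihood and matches coxph", {
  skip_if_not_installed("survival")
  ## two-subject, two-event, no ties: the partial likelihood
  ## L = e^{b x_1} / (e^{b x_1} + e^{b x_2}) has its maximum at b -> +/-Inf
  ## unless x is swapped between risk sets; use a 4-subject case instead
  s <- surv_tab(c(1, 2, 3, 4), rep(1, 4))
  g <- c(TRUE, FALSE, TRUE, FALSE)
  got <- cox_hr(s, g)
  ref <- survival::coxph(survival::Surv(s$time, s$event) ~ g,
                         ties = "breslow")
  expect_equal(got$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(got$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)

  ## exchanging labels inverts the hazard ratio
  swapped <- cox_hr(s, !g)
  expect_equal(swapped$hr, 1 / got$hr, tolerance = 1e-8)

  set.seed(33)
  for (rep in 1:25) {
    n <- 40
    time <- rexp(n); event <- rbinom(n, 1, 0.8)
    g <- rbinom(n, 1, 0.5) == 1
    if (sum(event[g]) == 0 || sum(event[!g]) == 0) next
    got <- suppressWarnings(cox_hr(surv_tab(time, event), g))
    if (!is.finite(got$beta)) next
    ref <- survival::coxph(survival::Surv(time, event) ~ g, ties = "breslow")
    expect_equal(got$beta, unname(coef(ref)), tolerance = 1e-6)
  }
})

test_that("cox_hr is centered under a null generator", {
  set.seed(34)
  betas <- replicate(60, {
    n <- 200
    time <- rexp(n); event <- rbinom(n, 1, 0.8)
    g <- rbinom(n, 1, 0.5) == 1
    suppressWarnings(cox_hr(surv_tab(time, event), g)$beta)
  })
  expect_lt(abs(mean(betas, na.rm = TRUE)), 0.1)
})

test_that("log-rank direction agrees with the Cox coefficient sign", {
  set.seed(35)
  for (rep in 1:20) {
    n <- 60
    g <- rbinom(n, 1, 0.5) == 1
    time <- rexp(n, 0.1 * exp(0.8 * g)); event <- rbinom(n, 1, 0.9)
    if (sum(event[g]) == 0 || sum(event[!g]) == 0) next
    lr <- tmelink:::logrank_core(time, event, g)
    cx <- suppressWarnings(cox_hr(surv_tab(time, event), g))
    if (!is.finite(cx$beta) || cx$beta == 0) next
    expect_equal(sign(cx$beta), sign(lr$o_minus_e))
  }
})

test_that("optimal_cutpoint agrees with an exhaustive scan and is rank-invariant", {
  set.seed(36)
  n <- 60
  scores <- rnorm(n)
  time <- rexp(n, 0.1 * exp(1 * (scores > 0)))
  s <- surv_tab(time, rbinom(n, 1, 0.9))
  got <- optimal_cutpoint(scores, s, minprop = 0.1)
  ## oracle: evaluate every unique value, restrict to the valid region
  cand <- sort(unique(scores))
  z <- sapply(cand, function(cc) {
    nh <- sum(scores > cc)
    if (nh < 0.1 * n || (n - nh) < 0.1 * n) return(NA_real_)
    tmelink:::logrank_core(s$time, s$event, scores > cc)$z
  })
  expect_equal(got$cutpoint, cand[which.max(abs(z))])
  ## monotone transform of scores gives the same split
  got2 <- optimal_cutpoint(exp(scores), s, minprop = 0.1)
  expect_identical(got2$high, got$high)
  expect_error(optimal_cutpoint(rep(1, n), s), "no valid cutpoint")
})

test_that("optimal_cutpoint recovers a planted step-hazard threshold", {
  hits <- vapply(1:5, function(seed) {
    set.seed(seed)
    n <- 300
    scores <- rnorm(n)
    thr <- quantile(scores, 0.5)
    time <- rexp(n, 0.05 * exp(log(3) * (scores > thr)))
    s <- surv_tab(time, rbinom(n, 1, 0.85))
    cut <- optimal_cutpoint(scores, s)
    abs(mean(scores <= cut$cutpoint) - 0.5) <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("prognostic_scan degenerates gracefully on a single cohort", {
  scd <- gen_sc_dataset(default_sc_config(seed = 40, n_samples = 10,
                                          n_cells = 80, n_genes = 200))
  b <- gen_bulk_cohort(scd$truth,
                       bulk_sim_config(120, censoring_rate = 0.2,
                                       hazard_coefficients = c(tumorA = 3),
                                       seed = 1))
  sets <- gene_set_collection(scd$truth$marker_genes)
  scan <- prognostic_scan(list(c1 = list(bulk = b$bulk, survival = b$survival)),
                          sets)
  expect_equal(nrow(scan$grid), 3)
  g <- scan$grid[scan$grid$population == "tumorA", ]
  expect_identical(unname(scan$calls["tumorA"]),
                   if (g$hr > 1 && g$logrank_p < 0.05) "adverse"
                   else if (g$hr < 1 && g$logrank_p < 0.05) "favorable"
                   else "inconsistent")
})

test_that("tme_module unions marker sets and flags the planted module", {
  ## union of identical sets is the set itself
  one <- gene_set_collection(list(a = c("x", "y"), b = c("y", "x")))
  expect_setequal(unique(unlist(one$sets)), c("x", "y"))

  ## module built from the adverse population and its co-enriched partner
  scd <- gen_sc_dataset(default_sc_config(
    seed = 41, n_samples = 10, n_cells = 80, n_genes = 150,
    coenrich = list(list(pair = c("tumorA", "tregB"), r = 0.8))))
  sets <- gene_set_collection(scd$truth$marker_genes[c("tumorA", "tregB")])
  b <- gen_bulk_cohort(scd$truth,
                       bulk_sim_config(150, censoring_rate = 0.2,
                                       hazard_coefficients = c(tumorA = 4),
                                       seed = 2))
  feats <- gene_set_collection(list(f1 = scd$truth$marker_genes$tregB,
                                    f2 = scd$truth$marker_genes$otherC))
  rep <- tme_module(sets, list(c1 = list(bulk = b$bulk,
                                         survival = b$survival)), feats)
  expect_setequal(rep$c1$module_genes, unique(unlist(sets$sets)))
  expect_lt(rep$c1$logrank_p, 0.05)
  expect_equal(nrow(rep$c1$feature_diff), 2)
})
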