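test_that("qc_filter applies the exact threshold semantics", {
  ## 5 cells: ok / 999 counts / 21% mito / 200 genes / 30001 counts
  genes <- c(paste0("G", 1:4), "MT-1")
  m <- matrix(0L, 5, 5, dimnames = list(genes, paste0("c", 1:5)))
  m[1:4, 1] <- c(500L, 400L, 200L, 1L)      # 1101 counts, fine
  m[1:4, 2] <- c(400L, 300L, 200L, 99L)     # 999 total -> out ("exceeding 1000")
  m[, 3] <- c(500L, 300L, 200L, 100L, 293L) # 1393 total, 21% mito -> out
  m[1:2, 4] <- c(800L, 400L)                # only 2 genes detected -> out
  m[1:4, 5] <- c(20000L, 10000L, 1L, 1000L) # 30002 -> out
  em <- expression_matrix(m, "counts")
  res <- qc_filter(em, min_genes = 2, min_counts = 1000, max_counts = 30000,
                   max_mito_frac = 0.20)
  expect_identical(colnames(res$counts), "c1")
  expect_equal(res$report$removed_low_counts, 1)
  expect_equal(res$report$removed_high_mito, 1)
  expect_equal(res$report$removed_low_genes, 1)
  expect_equal(res$report$removed_high_counts, 1)
  expect_identical(res$report$doublet_removal, "not applied")

  ## boundary: a cell with exactly 1000 counts is removed, 1001 is kept
  m2 <- matrix(c(1000L, 1001L), 1, 2,
               dimnames = list("GX", c("at", "above")))
  r2 <- qc_filter(expression_matrix(m2, "counts"), min_genes = 0,
                  min_counts = 1000)
  expect_identical(colnames(r2$counts), "above")

  ## mito fraction exactly 20% kept, 21% removed
  m3 <- rbind(`MT-1` = c(200L, 210L), GA = c(800L, 790L))
  colnames(m3) <- c("at20", "at21")
  r3 <- qc_filter(expression_matrix(m3, "counts"), min_genes = 0,
                  min_counts = 100)
  expect_identical(colnames(r3$counts), "at20")
})

test_that("qc_filter removes exclusion-list genes and is idempotent", {
  set.seed(2)
  m <- matrix(rpois(400, 20), 20, 20,
              dimnames = list(paste0("G", 1:20), paste0("c", 1:20)))
  excl <- gene_set_collection(list(junk = c("G1", "G5")))
  r1 <- qc_filter(expression_matrix(m, "counts"), exclusion_lists = excl,
                  min_genes = 2, min_counts = 10)
  expect_false(any(c("G1", "G5") %in% rownames(r1$counts)))
  r2 <- qc_filter(r1$counts, exclusion_lists = excl, min_genes = 2,
                  min_counts = 10)
  expect_identical(r2$counts, r1$counts)
  expect_equal(r2$report$n_input_cells, r2$report$n_kept_cells)
  expect_error(qc_filter(expression_matrix(m, "counts"),
                         min_counts = 10000), "no cells pass")
})

test_that("lognormalize matches its closed form", {
  m <- toy_counts(c(1L, 0L), genes = c("a", "b"), cells = "c1")
  ln <- lognormalize(m)
  expect_equal(unname(ln[, 1]), c(log(10001), 0))
  ## column sums of expm1 equal the scale factor
  r <- toy_counts(rpois(100, 5) + 1L, genes = paste0("g", 1:10),
                  cells = paste0("c", 1:10))
  ln2 <- lognormalize(r)
  expect_equal(unname(colSums(expm1(ln2))), rep(1e4, 10), tolerance = 1e-10)
  ## independent formula evaluation
  direct <- log1p(1e4 * sweep(unclass(r), 2, colSums(r), "/"))
  expect_lt(max(abs(ln2 - direct)), 1e-12)
  ## zero-count cell is an error
  z <- toy_counts(c(0L, 0L, 1L, 2L), genes = c("a", "b"))
  expect_error(lognormalize(z), "zero-count")
})

test_that("find_markers ranks exclusively expressed genes first with small p", {
  set.seed(10)
  m <- matrix(rpois(30 * 24, 2), 30, 24,
              dimnames = list(paste0("G", 1:30), paste0("c", 1:24)))
  m["G7", 1:12] <- m["G7", 1:12] + 20L
  m["G7", 13:24] <- 0L
  ann <- data.frame(cell_id = colnames(m), sample_id = "s1",
                    cluster = rep(c("A", "B"), each = 12))
  mk <- find_markers(lognormalize(expression_matrix(m, "counts")), ann)
  a <- mk[mk$cluster == "A", ]
  expect_identical(a$gene[1], "G7")
  expect_lt(a$p_value[a$gene == "G7"], 0.05)
})

test_that("find_markers p-values match exhaustive rank enumeration on small groups", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(4); y <- rnorm(4)
    got <- tmelink:::wilcox_rank_sum(x, y)
    expect_equal(got$p_value, exact_wilcox_oracle(x, y), tolerance = 1e-12)
  }
  ## 4+4 cell worked example embedded in a marker run
  m <- matrix(0, 2, 8, dimnames = list(c("Gz", "Gt"), paste0("c", 1:8)))
  m["Gt", ] <- c(5.2, 4.1, 6.3, 3.9, 1.2, 2.8, 0.7, 1.9)
  m["Gz", ] <- rep(c(1, 2), 4)
  em <- m; attr(em, "layer") <- "lognorm"
  ann <- data.frame(cell_id = colnames(m), sample_id = "s",
                    cluster = rep(c("A", "B"), each = 4))
  mk <- find_markers(em, ann, min_pct = 0)
  p_pkg <- mk$p_value[mk$cluster == "A" & mk$gene == "Gt"]
  expect_equal(p_pkg, exact_wilcox_oracle(m["Gt", 1:4], m["Gt", 5:8]),
               tolerance = 1e-12)
})

test_that("find_markers null p-values are roughly uniform", {
  set.seed(77)
  m <- matrix(rpois(200 * 60, 4), 200, 60,
              dimnames = list(paste0("G", 1:200), paste0("c", 1:60)))
  ann <- data.frame(cell_id = colnames(m), sample_id = "s",
                    cluster = sample(rep(c("A", "B"), 30)))
  mk <- find_markers(lognormalize(expression_matrix(m, "counts")), ann,
                     min_log2fc = -Inf)
  p <- mk$p_value[mk$cluster == "A"]
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("infer_cnv is null-calibrated, order-invariant and zero on constants", {
  pops <- data.frame(name = c("q", "ref"), baseline_fraction = c(0.5, 0.5),
                     marker_genes = c(0, 0) + 1, marker_log2fc = c(0, 0))
  d <- gen_sc_dataset(sc_sim_config(2, 80, 300, pops, seed = 21))
  ln <- lognormalize(d$counts)
  cnv <- infer_cnv(ln, d$annotation, d$coords, reference_clusters = "ref")
  q <- d$annotation$population == "q"
  ratio <- mean(cnv$scores[q]) / mean(cnv$scores[!q])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)

  ## permuting gene input order changes nothing
  perm <- sample(nrow(ln))
  ln2 <- ln[perm, ]; attr(ln2, "layer") <- "lognorm"
  cnv2 <- infer_cnv(ln2, d$annotation, d$coords, reference_clusters = "ref")
  expect_equal(cnv2$scores, cnv$scores)

  ## constant matrix -> all-zero profiles and scores
  cm <- matrix(2, 30, 10, dimnames = list(d$coords$gene[1:30],
                                          paste0("c", 1:10)))
  attr(cm, "layer") <- "lognorm"
  ann <- data.frame(cell_id = colnames(cm), sample_id = "s",
                    cluster = rep(c("q", "ref"), 5))
  cnv3 <- infer_cnv(cm, ann, d$coords, reference_clusters = "ref")
  expect_true(all(cnv3$scores == 0))
  expect_error(infer_cnv(ln, d$annotation, d$coords,
                         reference_clusters = "nope"), "no reference")
})

test_that("infer_cnv separates cells with a planted expression block", {
  pops <- data.frame(name = c("malig", "ref"), baseline_fraction = c(0.5, 0.5),
                     marker_genes = c(5, 5), marker_log2fc = c(1, 1))
  cfg <- sc_sim_config(2, 120, 800, pops, malignant_population = "malig",
                       cnv_blocks = data.frame(chromosome = "chr2",
                                               start_gene_index = 81,
                                               end_gene_index = 300,
                                               log2_shift = 0.5),
                       seed = 31)
  d <- gen_sc_dataset(cfg)
  cnv <- infer_cnv(lognormalize(d$counts), d$annotation, d$coords,
                   reference_clusters = "ref")
  truth <- d$annotation$malignant
  r <- rank(cnv$scores)
  auc <- (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
  expect_gt(auc, 0.9)
  ## the k-means call should beat chance clearly (score overlap keeps it
  ## below the ranking AUC)
  expect_gt(mean(cnv$malignant == truth), 0.65)
})

test_that("population_frequencies matches direct counting", {
  ann <- data.frame(cell_id = paste0("c", 1:5),
                    sample_id = c("s1", "s1", "s1", "s1", "s1"),
                    population = c("A", "A", "B", "B", "B"))
  f <- population_frequencies(ann)
  expect_equal(unname(f["s1", c("A", "B")]), c(0.4, 0.6))

  ann2 <- rbind(ann, data.frame(cell_id = "c6", sample_id = "s2",
                                population = "A"))
  f2 <- population_frequencies(ann2)
  expect_equal(unname(f2["s2", "B"]), 0)          # absent population is 0
  expect_equal(rowSums(f2), c(s1 = 1, s2 = 1))

  ## independent group-by count on random data
  set.seed(3)
  ann3 <- data.frame(cell_id = paste0("c", 1:200),
                     sample_id = sample(paste0("s", 1:4), 200, TRUE),
                     population = sample(c("A", "B", "C"), 200, TRUE))
  f3 <- population_frequencies(ann3)
  for (s in rownames(f3)) for (p in colnames(f3)) {
    expect_equal(f3[s, p],
                 sum(ann3$sample_id == s & ann3$population == p) /
                   sum(ann3$sample_id == s))
  }
})
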