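test_that("normalization scales cells to a common total before log1p", {
  cm <- matrix(c(10, 30, 5, 15), 2, 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- normalize_counts(cm)
  expect_equal(expm1(norm[, "c1"]), c(g1 = 2500, g2 = 7500))
  # proportional cells normalize identically
  expect_equal(norm[, "c1"], norm[, "c2"], ignore_attr = TRUE)
  # an all-zero gene stays all-zero
  cm2 <- rbind(cm, g3 = c(0, 0))
  expect_true(all(normalize_counts(cm2)["g3", ] == 0))
  cm3 <- cbind(cm, c3 = c(0, 0))
  expect_error(normalize_counts(cm3), "all-zero")
  expect_equal(colnames(filter_zero_cells(cm3)), c("c1", "c2"))
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1 & adj >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_norm <- function(a, b, n_genes = 1, gene_values = NULL) {
  na <- length(a); nb <- length(b)
  vals <- rbind(matrix(c(a, b), nrow = 1))
  if (n_genes > 1)
    vals <- do.call(rbind, c(list(vals), gene_values))
  dimnames(vals) <- list(sprintf("g%d", seq_len(nrow(vals))),
                         sprintf("c%d", seq_len(na + nb)))
  meta <- data.frame(cell_id = colnames(vals),
                     condition = rep(c("A", "B"), c(na, nb)),
                     cell_type = "t")
  list(norm = vals, meta = meta)
}

test_that("the rank-sum p matches exact enumeration on separated arms", {
  # {1,2,3} vs {4,5,6}: the most extreme of the C(6,3)=20 rank splits,
  # two-sided p = 2/20 = 0.1
  f <- make_norm(c(1, 2, 3), c(4, 5, 6))
  deg <- wilcoxon_deg(f$norm, f$meta, "t", c("A", "B"))
  expect_equal(deg$p, 0.1)
})

test_that("identical arms give p ~ 1, zero fold change, no calls", {
  f <- make_norm(c(1, 2, 3, 4), c(1, 2, 3, 4))
  deg <- wilcoxon_deg(f$norm, f$meta, "t", c("A", "B"))
  expect_gt(deg$p, 0.99)
  expect_equal(deg$log2fc, 0)
  expect_false(deg$significant)
})

test_that("exact and normal-approximation p-values agree for small arms", {
  set.seed(71)
  for (n in 8:10) {
    a <- rnorm(n); b <- rnorm(n) + 0.5
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    p_norm <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("the screen is invariant to gene and cell order", {
  sim <- simulate_counts(count_sim_config(
    n_genes = 60, cells_per_group = 10, conditions = c("x", "y"),
    cell_types = "t", de_fraction = 0.2, planted_log2fc = 2, seed = 72))
  norm <- normalize_counts(filter_zero_cells(sim$counts))
  deg <- wilcoxon_deg(norm, sim$meta, "t", c("y", "x"))
  gp <- sample(nrow(norm)); cp <- sample(ncol(norm))
  deg2 <- wilcoxon_deg(norm[gp, cp], sim$meta, "t", c("y", "x"))
  reord <- deg2[match(deg$gene, deg2$gene), ]
  expect_equal(reord$p, deg$p, ignore_attr = TRUE)
  expect_equal(reord$log2fc, deg$log2fc, ignore_attr = TRUE)
})

test_that("unknown labels and thin arms are contract errors", {
  f <- make_norm(c(1, 2, 3), c(4, 5, 6))
  expect_error(wilcoxon_deg(f$norm, f$meta, "nope", c("A", "B")),
               "unknown cell type.*t")
  expect_error(wilcoxon_deg(f$norm, f$meta, "t", c("A", "C")),
               "unknown condition")
  f2 <- make_norm(c(1, 2), c(4, 5, 6))
  expect_error(wilcoxon_deg(f2$norm, f2$meta, "t", c("A", "B")),
               ">= 3 cells")
})

test_that("planted genes are flagged and nulls are not", {
  sim <- simulate_counts(count_sim_config(
    n_genes = 600, cells_per_group = 100, conditions = c("ctrl", "trt"),
    cell_types = "t", de_fraction = 0.1, planted_log2fc = 2, seed = 73))
  norm <- normalize_counts(filter_zero_cells(sim$counts))
  meta <- sim$meta[sim$meta$cell_id %in% colnames(norm), ]
  deg <- wilcoxon_deg(norm, meta, "t", c("trt", "ctrl"))
  hits <- deg$gene[deg$significant]
  expect_gte(mean(sim$truth$gene %in% hits), 0.9)
  expect_lte(mean(!(hits %in% sim$truth$gene)), 0.1)
  expect_true(all(deg$p_adj >= deg$p))
})

test_that("cluster proportion chi-square matches the 2x2 hand computation", {
  # 40/100 vs 60/100: Pearson chi-square without correction = 8.0
  meta <- data.frame(
    cell_id = sprintf("c%03d", 1:200),
    condition = rep(c("A", "B"), each = 100),
    cell_type = c(rep("t1", 40), rep("t2", 60), rep("t1", 60), rep("t2", 40)))
  out <- cluster_proportion_test(meta)
  expect_equal(out$statistic, rep(8, 2), tolerance = 1e-12)
  identical_meta <- meta
  identical_meta$cell_type <- rep(c(rep("t1", 50), rep("t2", 50)), 2)
  out2 <- cluster_proportion_test(identical_meta)
  expect_true(all(out2$p_adj > 0.99))
})

test_that("the proportion test holds its level under the null", {
  set.seed(74)
  alarms <- vapply(1:1000, function(i) {
    meta <- data.frame(cell_id = sprintf("c%03d", 1:160),
                       condition = rep(c("A", "B"), each = 80),
                       cell_type = sample(c("t1", "t2"), 160, replace = TRUE))
    any(cluster_proportion_test(meta)$p < 0.05)
  }, logical(1))
  # one effective test per replicate (two mirrored rows)
  expect_gt(mean(alarms), 0.03)
  expect_lt(mean(alarms), 0.07)
})

test_that("counts round trip through the MTX triplet and metadata CSV", {
  sim <- simulate_counts(count_sim_config(n_genes = 40, cells_per_group = 3,
                                          seed = 75))
  dir <- withr::local_tempdir()
  write_counts_mtx(sim$counts, dir)
  back <- read_counts_mtx(dir)
  expect_identical(unname(back), unname(sim$counts))
  expect_identical(dimnames(back), dimnames(sim$counts))
  meta_path <- file.path(dir, "meta.csv")
  write_cell_meta(sim$meta, meta_path)
  expect_equal(read_cell_meta(meta_path), sim$meta, ignore_attr = TRUE)
  cc <- condition_cell_counts(sim$meta)
  expect_equal(sum(cc), ncol(sim$counts))
  expect_equal(unname(cc[["control"]]), 12L)
})
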