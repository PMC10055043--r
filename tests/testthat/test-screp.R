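# small handmade count container: 5 genes (3 ORs, 1 housekeeping, 1 mito)
make_counts <- function(mat, zones = c("1", "2", "4")) {
  genes <- c("OlfrA", "OlfrB", "OlfrC", "Hk1", "mt-1")
  cells <- sprintf("c%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  zonal_count_matrix(
    mat,
    data.frame(cell_id = cells, stage = "INP", segment = "whole",
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes, is_OR = c(TRUE, TRUE, TRUE, FALSE, FALSE),
               zone = c(zones, "unknown", "unknown"),
               is_mito = c(FALSE, FALSE, FALSE, FALSE, TRUE),
               stringsAsFactors = FALSE))
}

test_that("QC discards cells failing any criterion, inclusively", {
  m <- make_counts(cbind(c(3, 3, 0, 10, 0),    # 3 detected genes, no mito
                         c(3, 0, 0, 10, 0),    # only 2 detected genes
                         c(3, 3, 0, 2, 0),     # low UMIs
                         c(3, 3, 0, 10, 2)))   # 10% mito
  out <- qc_filter_cells(m, min_genes = 3, min_umis = 10,
                         max_mito_frac = 0.05)
  expect_equal(out$cell_meta$cell_id, "c01")
  expect_equal(unname(attr(out, "qc_removed")["total_removed"]), 3)
  # zero mito counts with passing sizes is retained
  expect_equal(ncol(out$counts), 1)
  no_mito <- make_counts(matrix(c(5, 5, 5, 5, 0), ncol = 1))
  expect_equal(ncol(qc_filter_cells(no_mito, 3, 10, 0.05)$counts), 1)
  bad <- no_mito; bad$gene_meta$is_mito <- NULL
  expect_error(qc_filter_cells(bad, 3, 10, 0.05), "is_mito")
})

test_that("QC survivors equal a brute-force row scan on random matrices", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 40
    mat <- matrix(rpois(5 * n, 4), 5, n)
    m <- make_counts(mat)
    out <- qc_filter_cells(m, min_genes = 3, min_umis = 15,
                           max_mito_frac = 0.1)
    keep <- vapply(seq_len(n), function(j) {
      genes <- sum(mat[, j] >= 3)
      umis <- sum(mat[, j])
      mito <- mat[5, j] / max(umis, 1)
      genes >= 3 && umis >= 15 && mito < 0.1
    }, TRUE)
    expect_equal(out$cell_meta$cell_id, sprintf("c%02d", which(keep)))
  }
  # idempotence
  m <- make_counts(matrix(rpois(5 * 20, 4), 5, 20))
  f1 <- qc_filter_cells(m, 2, 10, 0.2)
  f2 <- qc_filter_cells(f1, 2, 10, 0.2)
  expect_identical(f1$counts, f2$counts)
})

test_that("expressed-OR calling applies the 3-UMI rule", {
  m <- make_counts(cbind(c(3, 2, 0, 5, 0), c(0, 0, 0, 5, 0)))
  prof <- call_expressed_ors(m)
  expect_equal(prof$expressed$c01, "OlfrA")
  expect_equal(prof$expressed$c02, character(0))
  expect_equal(as.character(prof$cells$dominant_zone), c("1", "unknown"))
})

test_that("expressed-OR sets equal dense thresholding on random input", {
  set.seed(3)
  mat <- matrix(rpois(5 * 50, 2), 5, 50)
  m <- make_counts(mat)
  prof <- call_expressed_ors(m, umi_threshold = 3)
  for (j in 1:50) {
    expect_equal(prof$expressed[[j]],
                 c("OlfrA", "OlfrB", "OlfrC")[mat[1:3, j] >= 3])
  }
})

test_that("cell zone classification breaks ties towards dorsal", {
  m <- make_counts(cbind(c(4, 0, 4, 0, 0)), zones = c("4", "3", "2"))
  # OlfrA (zone 4) and OlfrC (zone 2) tie at 4 UMIs -> zone 2
  expect_equal(as.character(call_expressed_ors(m)$cells$dominant_zone),
               "2")
  m2 <- make_counts(cbind(c(0, 0, 9, 0, 0)), zones = c("1", "2", "5"))
  expect_equal(as.character(call_expressed_ors(m2)$cells$dominant_zone),
               "5")
})

test_that("repertoire crosstab counts cells per zone class they express", {
  mat <- cbind(c(3, 3, 0, 1, 0), c(0, 3, 3, 1, 0), c(0, 0, 0, 1, 0))
  m <- make_counts(mat, zones = c("1", "2", "4"))
  ct <- repertoire_crosstab(call_expressed_ors(m), by = "stage")
  expect_equal(ct$n_cells, 3)
  expect_equal(ct[["1"]], 1)
  expect_equal(ct[["2"]], 2)
  expect_equal(ct[["4"]], 1)
  expect_equal(ct[["5"]], 0)
})

test_that("zonal fold change is zero for identical input and exact for a
          doubled OR at equal library size", {
  ann <- test_ann(c("1", "2", "4", "5"), width = 1000)
  a <- matrix(100, 4, 2, dimnames = list(ann$gene_id, c("s1", "s2")))
  fc0 <- zonal_fold_change(a, a, ann, pseudocount = 1)
  expect_equal(fc0$log2fc, rep(0, 4))
  # double gene 1, absorb the excess in genes 3-4: library sizes equal
  b <- a; b[1, ] <- 200; b[3, ] <- 50; b[4, ] <- 50
  # cpm of gene1 doubles exactly; with pseudocount the log2 ratio shifts
  fc <- zonal_fold_change(b, a, ann, pseudocount = 0)
  expect_equal(fc$log2fc[1], 1)
  # invariance under common library scaling
  fc2 <- zonal_fold_change(b * 10, a * 10, ann, pseudocount = 0)
  expect_equal(fc$log2fc, fc2$log2fc)
})

test_that("rank-sum test is exact for small tie-free groups", {
  # fully separated groups of 5: two-sided p is 2/choose(10,5)
  x <- 1:5 + 0.5; y <- 6:10
  t <- rank_sum_test(x, y)
  expect_equal(t$statistic, 0)
  expect_equal(t$p.value, 2 / choose(10, 5))
  expect_equal(oracle_ranksum(x, y)$p.value, t$p.value)
  # symmetric swap mirrors the statistic around nx*ny/2
  t2 <- rank_sum_test(y, x)
  expect_equal(t2$statistic, 25)
  expect_equal(t2$p.value, t$p.value)
})

test_that("rank-sum matches exhaustive enumeration on random small groups", {
  set.seed(12)
  for (rep in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny, sample(c(0, 2), 1))
    got <- rank_sum_test(x, y)
    want <- oracle_ranksum(x, y)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
    # and agrees with the reference implementation
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                               correct = FALSE))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give p near 1 under the tie-corrected
          approximation", {
  x <- rep(c(1, 2, 3), 10)
  t <- rank_sum_test(x, x)
  expect_equal(t$method, "normal")
  expect_equal(t$p.value, 1)
})

test_that("zone shift test compares fold-change groups by zone label", {
  fc <- data.frame(zone = rep(c("2", "5"), each = 5),
                   log2fc = c(rnorm(5, 3), rnorm(5, -3)))
  t <- zone_shift_test(fc, "2", "5")
  expect_lt(t$p.value, 0.01)
})
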