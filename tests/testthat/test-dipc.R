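write_toy_3dg <- function(lines, path = withr::local_tempfile(
                            fileext = ".3dg",
                            .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

toy_struct <- function(xyz, chrom = NULL, pos = NULL) {
  n <- nrow(xyz)
  s <- list(cell_id = "toy",
            particles = data.frame(
              chrom = if (is.null(chrom)) rep("chr1(mat)", n) else chrom,
              pos = if (is.null(pos)) (seq_len(n) - 1) * 20000 else pos,
              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
            resolution = 20000)
  class(s) <- "structure_3d"
  s
}

test_that(".3dg files round-trip and malformed input is rejected by line", {
  p <- write_toy_3dg(c("chr1(mat)\t0\t1.5\t2\t3",
                       "chr1(pat)\t0\t-1\t0\t0.25",
                       "chr2(mat)\t20000\t0\t0\t0"))
  s <- read_3dg(p, cell_id = "c1")
  expect_equal(nrow(s$particles), 3)
  expect_equal(s$particles$x, c(1.5, -1, 0))
  p2 <- withr::local_tempfile()
  write_3dg(s, p2)
  expect_equal(read_3dg(p2)$particles, s$particles)
  bad <- write_toy_3dg(c("chr1(mat)\t0\t1\t2\t3", "chr1(mat)\t0\t1\t2"))
  expect_error(read_3dg(bad), "line 2")
  bad2 <- write_toy_3dg(c("chr1(mat)\t0\t1\t2\tNOPE"))
  expect_error(read_3dg(bad2), "non-numeric")
  dup <- write_toy_3dg(rep("chr1(mat)\t0\t1\t2\t3", 2))
  expect_error(read_3dg(dup), "duplicate")
})

test_that("OR loci map to the particle containing the gene midpoint", {
  s <- toy_struct(matrix(0, 4, 3),
                  chrom = c("chr1(mat)", "chr1(mat)", "chr1(pat)",
                            "chr2(mat)"),
                  pos = c(0, 20000, 0, 0))
  # midpoint exactly at a bin start maps to that bin
  ann <- test_ann(c("1", "2"), chrom = "chr1", start = c(19000, 39000),
                  width = 2000)
  loci <- map_or_loci(s, ann)
  expect_equal(loci$particle[loci$gene_id == "OlfrT01" &
                               grepl("mat", loci$chrom)], 2)
  # both haplotypes are distinct nodes; chr1 has mat+pat for gene 1 bin 0?
  expect_equal(sum(loci$gene_id == "OlfrT01"), 1)  # pat lacks bin 20000
  annX <- test_ann("3", chrom = "chrX", start = 0, width = 1000)
  lx <- map_or_loci(s, annX)
  expect_equal(nrow(lx), 0)
  expect_equal(attr(lx, "unmapped"), "OlfrT01")
})

test_that("locus mapping matches an interval oracle on random layouts", {
  set.seed(71)
  pos <- seq(0, 980000, by = 20000)
  s <- toy_struct(matrix(rnorm(3 * 2 * length(pos)), ncol = 3),
                  chrom = rep(c("chr1(mat)", "chr1(pat)"),
                              each = length(pos)),
                  pos = rep(pos, 2))
  starts <- sort(sample.int(9e5, 30))
  ann <- or_annotation(sprintf("G%02d", 1:30), "chr1", starts,
                       starts + 1500, zone_index = runif(30, 1, 5))
  loci <- map_or_loci(s, ann)
  expect_equal(nrow(loci), 60)
  for (k in seq_len(nrow(loci))) {
    g <- match(loci$gene_id[k], ann$gene_id)
    mid <- (ann$start[g] + ann$end[g]) %/% 2
    prow <- loci$particle[k]
    expect_true(s$particles$pos[prow] <= mid &&
                  mid < s$particles$pos[prow] + 20000)
  }
})

test_that("pairwise distances are Euclidean and match brute force", {
  s <- toy_struct(rbind(c(0, 0, 0), c(3, 4, 0)))
  ann <- test_ann(c("1", "2"), chrom = "chr1", start = c(0, 20000),
                  width = 1000)
  loci <- map_or_loci(s, ann)
  D <- pairwise_or_distances(s, loci)
  expect_equal(D[1, 2], 5)
  expect_equal(diag(D), rep(0, 2), ignore_attr = TRUE)
  set.seed(72)
  xyz <- matrix(rnorm(300), 100, 3)
  s2 <- toy_struct(xyz)
  ann2 <- or_annotation(sprintf("G%03d", 1:100), "chr1",
                        (0:99) * 20000, (0:99) * 20000 + 1000,
                        zone_index = runif(100, 1, 5))
  loci2 <- map_or_loci(s2, ann2)
  D2 <- pairwise_or_distances(s2, loci2)
  for (pair in list(c(1, 2), c(10, 99), c(37, 64))) {
    expect_equal(D2[pair[1], pair[2]],
                 sqrt(sum((xyz[pair[1], ] - xyz[pair[2], ])^2)))
  }
  # permutation invariance
  perm <- sample(100)
  loci_p <- loci2[perm, ]
  Dp <- pairwise_or_distances(s2, loci_p)
  expect_equal(unname(Dp), unname(D2[perm, perm]))
})

test_that("neighbor counts match the double-loop oracle", {
  # colinear points spaced 1 apart, r = 2.5: interior points see 4
  xyz <- cbind(0:9, 0, 0)
  s <- toy_struct(xyz)
  ann <- or_annotation(sprintf("G%02d", 1:10), "chr1", (0:9) * 20000,
                       (0:9) * 20000 + 100, zone_index = 1)
  g <- neighbors_within(s, map_or_loci(s, ann), 2.5)
  expect_equal(unname(g$counts), c(2, 3, 4, 4, 4, 4, 4, 4, 3, 2))
  # far-apart points have no neighbors
  g0 <- neighbors_within(toy_struct(cbind(seq(0, 900, 100), 0, 0)),
                         map_or_loci(toy_struct(cbind(seq(0, 900, 100),
                                                      0, 0)), ann), 2.5)
  expect_equal(unname(g0$counts), rep(0, 10))
  expect_equal(nrow(g0$edges), 0)
  set.seed(73)
  xyz2 <- matrix(runif(3 * 80, 0, 6), 80, 3)
  ann2 <- or_annotation(sprintf("H%02d", 1:80), "chr1", (0:79) * 20000,
                        (0:79) * 20000 + 99, zone_index = runif(80, 1, 5))
  g2 <- neighbors_within(toy_struct(xyz2), map_or_loci(toy_struct(xyz2),
                                                       ann2), 2)
  expect_equal(unname(g2$counts), oracle_neighbor_counts(xyz2, 2))
})

test_that("neighbor counts and aggregates are monotone in the radius", {
  set.seed(74)
  xyz <- matrix(runif(150, 0, 5), 50, 3)
  s <- toy_struct(xyz)
  ann <- or_annotation(sprintf("G%02d", 1:50), "chr1", (0:49) * 20000,
                       (0:49) * 20000 + 99, zone_index = runif(50, 1, 5))
  loci <- map_or_loci(s, ann)
  radii <- c(0.5, 1, 2, 4)
  gs <- lapply(radii, function(r) neighbors_within(s, loci, r))
  for (k in 2:4) {
    expect_true(all(gs[[k]]$counts >= gs[[k - 1]]$counts))
    # components only merge as r grows: membership at smaller r refines
    small <- oracle_components(50, gs[[k - 1]]$edges$i,
                               gs[[k - 1]]$edges$j)
    big <- oracle_components(50, gs[[k]]$edges$i, gs[[k]]$edges$j)
    expect_true(all(tapply(big, small, function(v) length(unique(v))) == 1))
  }
})

test_that("aggregate statistics equal union-find components", {
  # empty graph: all singletons
  xyz <- cbind(seq(0, 500, length.out = 6) * 10, 0, 0)
  ann <- or_annotation(sprintf("G%d", 1:6), "chr1", (0:5) * 20000,
                       (0:5) * 20000 + 99, zone_index = 1)
  s <- toy_struct(xyz)
  a0 <- aggregate_stats(neighbors_within(s, map_or_loci(s, ann), 1))
  expect_equal(a0$n_ors, rep(1, 6))
  # one clique: a single component spanning two chromosomes
  s1 <- toy_struct(matrix(rnorm(18, sd = 0.1), 6, 3),
                   chrom = rep(c("chr1(mat)", "chr2(mat)"), each = 3),
                   pos = rep(c(0, 20000, 40000), 2))
  ann1 <- or_annotation(sprintf("G%d", 1:6), rep(c("chr1", "chr2"),
                                                 each = 3),
                        rep(c(0, 20000, 40000), 2),
                        rep(c(0, 20000, 40000), 2) + 99, zone_index = 1)
  a1 <- aggregate_stats(neighbors_within(s1, map_or_loci(s1, ann1), 10))
  expect_equal(nrow(a1), 1)
  expect_equal(a1$n_ors, 6)
  expect_equal(a1$n_chromosomes, 2)
  set.seed(75)
  xyz2 <- matrix(runif(240, 0, 4), 80, 3)
  ann2 <- or_annotation(sprintf("H%02d", 1:80),
                        sample(c("chr1", "chr2", "chr3"), 80, TRUE),
                        1:80 * 1000, 1:80 * 1000 + 99,
                        zone_index = runif(80, 1, 5))
  ann2 <- or_annotation(ann2$gene_id, ann2$chrom,
                        stats::ave(ann2$start, ann2$chrom,
                                   FUN = function(v) seq_along(v) * 20000),
                        stats::ave(ann2$start, ann2$chrom,
                                   FUN = function(v) seq_along(v) * 20000)
                        + 99, zone_index = ann2$zone_index)
  s2 <- toy_struct(xyz2, chrom = paste0(ann2$chrom, "(mat)"),
                   pos = (ann2$start %/% 20000) * 20000)
  loci <- map_or_loci(s2, ann2)
  g2 <- neighbors_within(s2, loci, 1.5)
  a2 <- aggregate_stats(g2)
  comp <- oracle_components(nrow(loci), g2$edges$i, g2$edges$j)
  expect_equal(sort(a2$n_ors), sort(unname(table(comp))),
               ignore_attr = TRUE)
  expect_equal(sum(a2$n_ors), nrow(loci))
})

test_that("trans-proximity fractions count interchromosomal neighbors", {
  # all isolated: zero for every class
  xyz <- cbind(c(0, 100, 200, 300), 0, 0)
  ann <- or_annotation(c("A", "B", "C", "D"), c("chr1", "chr1", "chr2",
                                                "chr2"),
                       c(0, 20000, 0, 20000), c(99, 20099, 99, 20099),
                       zone_index = c(1, 1, 5, 5))
  s <- toy_struct(xyz, chrom = paste0(ann$chrom, "(mat)"),
                  pos = c(0, 20000, 0, 20000))
  fr0 <- zonal_trans_proximity_fraction(
    neighbors_within(s, map_or_loci(s, ann), 1))
  expect_equal(unname(fr0[c("1", "4-5")]), c(0, 0))
  # one trans pair: both involved classes positive
  xyz2 <- cbind(c(0, 100, 0.5, 300), 0, 0)
  s2 <- toy_struct(xyz2, chrom = paste0(ann$chrom, "(mat)"),
                   pos = c(0, 20000, 0, 20000))
  fr1 <- zonal_trans_proximity_fraction(
    neighbors_within(s2, map_or_loci(s2, ann), 1))
  expect_equal(unname(fr1["1"]), 0.5)
  expect_equal(unname(fr1["4-5"]), 0.5)
})

test_that("contact density comparison is tie-safe and scale invariant", {
  ann <- or_annotation(sprintf("G%02d", 1:20),
                       rep(c("chr1", "chr2"), each = 10),
                       rep((0:9) * 20000, 2), rep((0:9) * 20000, 2) + 99,
                       zone_index = seq(1, 5, length.out = 20))
  mk <- function(scale = 1) {
    xyz <- matrix(runif(60, 0, 6), 20, 3) * scale
    toy_struct(xyz, chrom = paste0(ann$chrom, "(mat)"),
               pos = rep((0:9) * 20000, 2))
  }
  set.seed(76)
  cells <- replicate(6, mk(), simplify = FALSE)
  same <- contact_density_compare(cells, cells, ann, r = 2)
  expect_gt(same$p.value, 0.99)
  # global scaling of coordinates and radius leaves densities unchanged
  set.seed(76)
  cells_big <- replicate(6, mk(scale = 10), simplify = FALSE)
  big <- contact_density_compare(cells_big, cells_big, ann, r = 20)
  expect_equal(big$density_a, same$density_a)
  # disjoint supports give the minimal exact p
  lo <- contact_density_compare(cells, cells, ann, r = 2)
  x <- c(0.9, 0.8, 0.85); y <- c(0.1, 0.2, 0.15)
  t <- rank_sum_test(x, y)
  expect_equal(t$p.value, oracle_ranksum(x, y)$p.value)
})

test_that("distance heatmaps order deterministically and mask by threshold", {
  # planted two blocks far apart: hierarchical order keeps blocks contiguous
  set.seed(77)
  xyz <- rbind(matrix(rnorm(30, 0, 0.3), 10, 3),
               matrix(rnorm(30, 50, 0.3), 10, 3))
  perm <- sample(20)
  D <- as.matrix(dist(xyz[perm, ]))
  h <- ordered_distance_heatmap(D, "hierarchical", threshold = 10)
  blocks <- (perm <= 10)[h$order]
  expect_equal(sum(diff(blocks) != 0), 1)   # one block boundary
  expect_true(all(is.na(h$matrix[1:10, 11:20])))   # cross-block masked
  expect_true(all(!is.na(h$matrix[1:10, 1:10])))
  # genomic order is the identity permutation; single element works
  g <- ordered_distance_heatmap(D, "genomic")
  expect_equal(g$order, 1:20)
  one <- ordered_distance_heatmap(matrix(0, 1, 1), "hierarchical")
  expect_equal(one$order, 1)
  # repeat runs give identical leaf order
  h2 <- ordered_distance_heatmap(D, "hierarchical", threshold = 10)
  expect_identical(h$order, h2$order)
})
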