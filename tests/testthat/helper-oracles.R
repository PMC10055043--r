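# Independent brute-force oracles. Deliberately naive implementations
# (explicit loops, transitive closures, exhaustive enumeration) kept free of
# any code path they are used to check.

# all-pairs transitive closure clustering: genes i,j linked iff same chrom
# and interval gap <= cluster_gap; returns membership vector
oracle_cluster_membership <- function(ann, cluster_gap) {
  n <- nrow(ann)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (ann$chrom[i] == ann$chrom[j]) {
      gap <- max(ann$start[i], ann$start[j]) -
        min(ann$end[i], ann$end[j])
      if (gap <= cluster_gap) linked[i, j] <- TRUE
    }
  }
  # transitive closure
  repeat {
    new <- linked | (linked %*% linked > 0)
    if (identical(new, linked)) break
    linked <- new
  }
  membership <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      next_id <- next_id + 1L
      membership[linked[i, ]] <- next_id
    }
  }
  membership
}

# per-bin zone by explicit overlap counting with dorsal-most tie-break
oracle_bin_zones <- function(bins, ann, resolution) {
  dorsal_order <- c("classI", "1", "2", "3", "4", "5")
  vapply(seq_len(nrow(bins)), function(b) {
    b0 <- bins$start[b]; b1 <- b0 + resolution
    hits <- which(ann$chrom == bins$chrom[b] &
                    ann$start < b1 & ann$end > b0)
    if (!length(hits)) return("unknown")
    tab <- table(as.character(ann$zone[hits]))
    winners <- names(tab)[tab == max(tab)]
    dorsal_order[min(match(winners, dorsal_order))]
  }, "")
}

# union-find connected components
oracle_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(edges_i)) {
    a <- find(edges_i[k]); b <- find(edges_j[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 1L)
}

# exhaustive two-sided rank-sum p by enumerating all group splits
oracle_ranksum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  v <- c(x, y)
  r <- rank(v)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  splits <- utils::combn(nx + ny, nx)
  Us <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  list(statistic = U_obs,
       p.value = mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9))
}

# mean trans contacts between zone classes by triple loop over a dense
# symmetric matrix
oracle_trans_heatmap <- function(M, chrom, zone, class_a, class_b) {
  ia <- which(zone %in% class_a); ib <- which(zone %in% class_b)
  tot <- 0; n <- 0
  for (i in ia) for (j in ib) {
    if (chrom[i] != chrom[j]) { tot <- tot + M[i, j]; n <- n + 1 }
  }
  if (n == 0) NA_real_ else tot / n
}

# neighbor counts within r by explicit double loop
oracle_neighbor_counts <- function(xyz, r) {
  n <- nrow(xyz)
  counts <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= r) {
      counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# exact marginal choice distribution of the polygenic-transcription +
# weighted-choice model, by enumerating ordered without-replacement draws:
# P(sequence) = prod w_k / remaining mass; K ~ Poisson(lambda) truncated at
# n genes (mass of K >= n lumped into K = n)
oracle_choice_distribution <- function(w, lambda) {
  n <- length(w)
  pK <- stats::dpois(0:(n - 1), lambda)
  pK <- c(pK, 1 - sum(pK))
  probs <- numeric(n)
  recurse <- function(chosen, p_seq) {
    k <- length(chosen)
    if (k > 0) {
      # sequence stops here with prob pK[k+1]; choice ~ w within the set
      ws <- w[chosen]
      probs[chosen] <<- probs[chosen] + pK[k + 1] * p_seq * ws / sum(ws)
    }
    if (k == n) return()
    rest <- setdiff(seq_len(n), chosen)
    rem_mass <- sum(w[rest])
    for (g in rest) recurse(c(chosen, g), p_seq * w[g] / rem_mass)
  }
  recurse(integer(), 1)
  probs / sum(pK[-1]) * 1  # K = 0 cells are resampled: condition on K >= 1
}

# tiny hand-rolled annotation for unit fixtures
test_ann <- function(zones = c("1", "2", "5"), chrom = "chrT",
                     start = NULL, width = 1000, gap = 5000) {
  n <- length(zones)
  if (is.null(start)) start <- seq(0, by = width + gap, length.out = n)
  or_annotation(gene_id = sprintf("OlfrT%02d", seq_len(n)),
                chrom = rep_len(chrom, n), start = start,
                end = start + width, strand = "+",
                zone_index = as.numeric(ifelse(zones == "classI", "1",
                                               zones)),
                is_class_I = zones == "classI")
}

# constant-depth coverage track over one contig
flat_track <- function(depth, len = 100000, contig = "chrT",
                       total = NULL) {
  coverage_track(stats::setNames(list(S4Vectors::Rle(depth, len)), contig),
                 total_reads = if (is.null(total)) depth * len else total)
}
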