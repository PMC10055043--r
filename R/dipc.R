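#' Single-cell 3D genome structure (.3dg) I/O
#'
#' The dip-c \code{.3dg} convention: five tab-separated columns — chromosome
#' with haplotype suffix (e.g. \code{chr1(mat)}), genomic position at fixed
#' resolution, and x, y, z coordinates in particle-radius units.
#'
#' @param path file path
#' @param cell_id identifier attached to the structure (defaults to the
#'   file name)
#' @param resolution particle resolution in bp (20 kb by convention)
#' @return a \code{structure_3d}: list with \code{cell_id},
#'   \code{particles} (chrom, pos, x, y, z) and \code{resolution}
#' @export
read_3dg <- function(path, cell_id = NULL, resolution = 20000) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5)
  if (length(bad)) stop("malformed .3dg line ", bad[1], " in ", path)
  m <- matrix(unlist(parts), ncol = 5, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:5, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 4)
  if (anyNA(num)) {
    stop("non-numeric coordinate at .3dg line ",
         which(rowSums(is.na(num)) > 0)[1], " in ", path)
  }
  p <- data.frame(chrom = m[, 1], pos = num[, 1], x = num[, 2],
                  y = num[, 3], z = num[, 4], stringsAsFactors = FALSE)
  dup <- duplicated(paste(p$chrom, p$pos))
  if (any(dup)) {
    stop("duplicate particle key at .3dg line ", which(dup)[1], " in ", path)
  }
  if (any(!is.finite(c(p$x, p$y, p$z)))) stop("non-finite coordinate")
  s <- list(cell_id = if (is.null(cell_id)) basename(path) else cell_id,
            particles = p, resolution = resolution)
  class(s) <- "structure_3d"
  s
}

#' @rdname read_3dg
#' @param struct a \code{structure_3d}
#' @export
write_3dg <- function(struct, path) {
  p <- struct$particles
  utils::write.table(
    data.frame(p$chrom, format(p$pos, trim = TRUE, scientific = FALSE),
               p$x, p$y, p$z),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.structure_3d <- function(x, ...) {
  cat(sprintf("structure_3d %s: %d particles @ %g bp\n",
              x$cell_id, nrow(x$particles), x$resolution))
  invisible(x)
}

# strip the haplotype suffix "(...)": "chr1(mat)" -> "chr1"
base_chrom <- function(chrom) sub("\\(.*\\)$", "", chrom)

#' Map OR genes to structure particles
#'
#' Each OR maps, per haplotype, to the particle whose bin contains the gene
#' midpoint.  Both haplotypes of an OR are distinct loci.
#'
#' @param struct a \code{structure_3d}
#' @param ann \code{or_annotation}
#' @return data.frame of mapped loci: locus (gene|haplotype), gene_id,
#'   zone, is_class_I, chrom (with haplotype), particle row index;
#'   attribute \code{unmapped} lists ORs without a matching particle
#' @export
map_or_loci <- function(struct, ann) {
  p <- struct$particles
  mid <- (ann$start + ann$end) %/% 2
  bin <- (mid %/% struct$resolution) * struct$resolution
  haps <- split(seq_len(nrow(p)), base_chrom(p$chrom))
  rows <- list(); unmapped <- character()
  for (i in seq_len(nrow(ann))) {
    idx <- haps[[ann$chrom[i]]]
    hit <- idx[p$pos[idx] == bin[i]]
    if (!length(hit)) { unmapped <- c(unmapped, ann$gene_id[i]); next }
    rows[[length(rows) + 1]] <- data.frame(
      locus = paste0(ann$gene_id[i], "|", p$chrom[hit]),
      gene_id = ann$gene_id[i], zone = as.character(ann$zone[i]),
      is_class_I = ann$is_class_I[i], chrom = p$chrom[hit],
      particle = hit, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), gene_id = character(),
               zone = character(), is_class_I = logical(),
               chrom = character(), particle = integer())
  out$zone <- zone_factor(out$zone)
  rownames(out) <- NULL
  attr(out, "unmapped") <- unique(unmapped)
  out
}

#' Pairwise Euclidean distances between mapped OR loci
#'
#' @param struct a \code{structure_3d}
#' @param loci output of [map_or_loci()]
#' @return symmetric distance matrix in particle-radius units, dimnames =
#'   locus ids
#' @export
pairwise_or_distances <- function(struct, loci) {
  xyz <- as.matrix(struct$particles[loci$particle, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  dimnames(D) <- list(loci$locus, loci$locus)
  D
}

#' Radius-neighborhood graph over OR loci
#'
#' Edges join locus pairs within Euclidean distance \code{r} (particle
#' radii); self-edges excluded, haplotypes are distinct nodes.
#'
#' @param struct a \code{structure_3d}
#' @param loci output of [map_or_loci()]
#' @param r neighborhood radius in particle radii (2.5, 5 and 10 are the
#'   conventional choices, roughly 150/300/600 nm)
#' @return a \code{proximity_graph}: list with \code{nodes} (the loci),
#'   \code{edges} (i, j row indices with i < j, dist), \code{counts}
#'   (per-locus neighbor count) and \code{r}
#' @export
neighbors_within <- function(struct, loci, r) {
  D <- pairwise_or_distances(struct, loci)
  A <- D <= r
  diag(A) <- FALSE
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  g <- list(nodes = loci,
            edges = data.frame(i = idx[, 1], j = idx[, 2],
                               dist = D[idx]),
            counts = stats::setNames(rowSums(A), loci$locus), r = r)
  class(g) <- "proximity_graph"
  g
}

#' @export
print.proximity_graph <- function(x, ...) {
  cat(sprintf("proximity_graph: %d loci, %d edges at r = %g radii\n",
              nrow(x$nodes), nrow(x$edges), x$r))
  invisible(x)
}

#' OR aggregate statistics from a proximity graph
#'
#' Aggregates are connected components of the radius-neighborhood graph;
#' singletons are kept (n_ors = 1).  Complexity is the number of distinct
#' chromosomes (haplotype-collapsed) contributing loci.
#'
#' @param graph a \code{proximity_graph}
#' @return data.frame: component, n_ors, n_chromosomes
#' @export
aggregate_stats <- function(graph) {
  n <- nrow(graph$nodes)
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$edges$i, to = graph$edges$j),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(i) {
    data.frame(n_ors = length(i),
               n_chromosomes = length(unique(base_chrom(
                 graph$nodes$chrom[i]))))
  }))
  out <- data.frame(component = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Fraction of OR loci with an interchromosomal neighbor, by zone class
#'
#' For each zone class, the fraction of its loci having at least one
#' neighbor on a different chromosome within the graph radius; zone classes
#' may be grouped (e.g. zones 4-5).
#'
#' @param graph a \code{proximity_graph}
#' @param zone_classes named list of zone label groups; default the
#'   conventional dorsal/dorsomedial/ventral grouping plus class I
#' @return named numeric vector of fractions (NA for empty classes)
#' @export
zonal_trans_proximity_fraction <- function(graph,
    zone_classes = list(classI = "classI", "1" = "1", "2-3" = c("2", "3"),
                        "4-5" = c("4", "5"))) {
  nodes <- graph$nodes
  bc <- base_chrom(nodes$chrom)
  has_trans <- rep(FALSE, nrow(nodes))
  if (nrow(graph$edges)) {
    tr <- bc[graph$edges$i] != bc[graph$edges$j]
    has_trans[unique(c(graph$edges$i[tr], graph$edges$j[tr]))] <- TRUE
  }
  vapply(zone_classes, function(zs) {
    sel <- as.character(nodes$zone) %in% zs
    if (!any(sel)) NA_real_ else mean(has_trans[sel])
  }, 1)
}

#' Compare per-cell interchromosomal OR contact densities
#'
#' Per cell, density = interchromosomal OR locus pairs within \code{r}
#' divided by the number of interchromosomal OR locus pairs; the two cell
#' groups are compared with the rank-sum test.
#'
#' @param cells_a,cells_b lists of \code{structure_3d}
#' @param ann \code{or_annotation}
#' @param r radius in particle radii
#' @return list: per-group density vectors, \code{statistic}, \code{p.value}
#' @export
contact_density_compare <- function(cells_a, cells_b, ann, r = 2.5) {
  density1 <- function(s) {
    loci <- map_or_loci(s, ann)
    D <- pairwise_or_distances(s, loci)
    bc <- base_chrom(loci$chrom)
    tr <- outer(bc, bc, "!=") & upper.tri(D)
    if (!sum(tr)) return(NA_real_)
    sum(D[tr] <= r) / sum(tr)
  }
  da <- vapply(cells_a, density1, 1)
  db <- vapply(cells_b, density1, 1)
  t <- rank_sum_test(da, db)
  list(density_a = da, density_b = db, statistic = t$statistic,
       p.value = t$p.value)
}

#' Row/column ordering for OR distance heatmaps
#'
#' Either genomic order (the input order, assumed position-sorted) or
#' deterministic average-linkage hierarchical clustering of the distance
#' matrix; entries above \code{threshold} are masked to NA for display
#' (10 particle radii, roughly 600 nm, by convention).
#'
#' @param D symmetric distance matrix
#' @param order "genomic" or "hierarchical"
#' @param threshold display threshold in the units of \code{D}
#' @return list: \code{order} (permutation), \code{matrix} (reordered,
#'   thresholded)
#' @export
ordered_distance_heatmap <- function(D, order = c("genomic", "hierarchical"),
                                     threshold = 10) {
  order <- match.arg(order)
  perm <- if (order == "genomic" || nrow(D) < 3) {
    seq_len(nrow(D))
  } else {
    stats::hclust(stats::as.dist(D), method = "average")$order
  }
  M <- D[perm, perm, drop = FALSE]
  M[M > threshold] <- NA
  list(order = perm, matrix = M)
}
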