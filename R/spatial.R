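#' Spatial transcriptomic dataset container
#'
#' A spot table (barcode, array row/col, pixel x/y, in_tissue flag) paired
#' with a genes x spots sparse count matrix over the OR annotation.
#'
#' @param spots data.frame with at least barcode, row, col
#' @param counts genes x spots sparse matrix, colnames = barcodes
#' @param gene_meta data.frame (gene_id, is_OR, zone) matching rownames
#' @return a \code{spatial_dataset}
#' @export
spatial_dataset <- function(spots, counts, gene_meta) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  stopifnot(identical(colnames(counts), spots$barcode),
            identical(rownames(counts), gene_meta$gene_id),
            !anyDuplicated(spots$barcode))
  gene_meta$zone <- zone_factor(gene_meta$zone)
  x <- list(spots = spots, counts = counts, gene_meta = gene_meta)
  class(x) <- "spatial_dataset"
  x
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots (%d x %d array), %d genes\n",
              nrow(x$spots), max(x$spots$row), max(x$spots$col),
              nrow(x$counts)))
  invisible(x)
}

#' Filter spatial spots on OR content
#'
#' Keeps spots with at least \code{min_or_genes} detected OR genes (count
#' above zero) and at least \code{min_or_umis} OR transcripts; the
#' conventional cutoffs are 2 genes and 3 transcripts.
#'
#' @param x a [spatial_dataset()]
#' @param min_or_genes,min_or_umis inclusive thresholds
#' @return filtered \code{spatial_dataset} (attribute \code{n_removed})
#' @export
filter_spots <- function(x, min_or_genes = 2, min_or_umis = 3) {
  oc <- x$counts[x$gene_meta$is_OR, , drop = FALSE]
  keep <- Matrix::colSums(oc > 0) >= min_or_genes &
    Matrix::colSums(oc) >= min_or_umis
  out <- spatial_dataset(x$spots[keep, , drop = FALSE],
                         x$counts[, keep, drop = FALSE], x$gene_meta)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Median-library log normalization of OR counts
#'
#' OR counts are scaled per spot to the median OR library size and
#' log1p-transformed — a deliberately simple stand-in for variance-
#' stabilizing normalization that preserves within-spot ranks.  Spots with
#' no OR transcripts scale by 1 (all zeros anyway).
#'
#' @param x a [spatial_dataset()]
#' @return dense OR genes x spots matrix of normalized expression
#' @export
normalize_spots <- function(x) {
  oc <- as.matrix(x$counts[x$gene_meta$is_OR, , drop = FALSE])
  lib <- colSums(oc)
  med <- stats::median(lib[lib > 0])
  sf <- ifelse(lib > 0, med / lib, 1)
  log1p(sweep(oc, 2, sf, "*"))
}

#' Assign each spot the zone with the largest summed normalized expression
#'
#' Per-spot normalized OR expression is summed within each zone class
#' (class I is its own class); the spot takes the argmax class, ties going
#' to the more dorsal label.  Spots without any OR transcript are assigned
#' \code{"none"}.
#'
#' @param normalized output of [normalize_spots()]
#' @param gene_meta gene metadata aligned with its rows (gene_id, zone)
#' @return a \code{zone_score_table} data.frame: barcode, one score column
#'   per class, assigned_zone (factor with a \code{none} level)
#' @export
assign_spot_zone <- function(normalized, gene_meta) {
  stopifnot(identical(rownames(normalized), gene_meta$gene_id))
  classes <- zone_levels()[zone_levels() != "unknown"]
  scores <- vapply(classes, function(zc) {
    sel <- as.character(gene_meta$zone) == zc
    if (any(sel)) colSums(normalized[sel, , drop = FALSE]) else
      numeric(ncol(normalized))
  }, numeric(ncol(normalized)))
  scores <- matrix(scores, ncol = length(classes),
                   dimnames = list(colnames(normalized), classes))
  ord <- order(zone_rank(classes))   # dorsal-first tie-break
  assigned <- apply(scores, 1, function(s) {
    if (all(s == 0)) return("none")
    s <- s[ord]
    names(s)[which.max(s)]
  })
  out <- data.frame(barcode = colnames(normalized), scores,
                    assigned_zone = factor(assigned,
                                           levels = c(classes, "none")),
                    check.names = FALSE, row.names = NULL)
  class(out) <- c("zone_score_table", "data.frame")
  out
}

#' Top-N expressed OR panels per zone and their per-spot means
#'
#' For each zone class, the \code{n} ORs with highest mean normalized
#' expression across spots (ties broken lexicographically).  Panels frozen
#' from a reference dataset can be re-applied to another dataset (pass
#' \code{panels}), the convention for comparing a knockout against its
#' control.
#'
#' @param normalized output of [normalize_spots()]
#' @param gene_meta gene metadata aligned with its rows
#' @param n panel size (20 by convention)
#' @param panels optional frozen panels (named list of gene ids)
#' @return list: \code{panels}, \code{spot_means} (classes x spots matrix)
#' @export
top_zone_panel <- function(normalized, gene_meta, n = 20, panels = NULL) {
  if (is.null(panels)) {
    classes <- zone_levels()[zone_levels() != "unknown"]
    avg <- rowMeans(normalized)
    panels <- lapply(stats::setNames(classes, classes), function(zc) {
      g <- gene_meta$gene_id[as.character(gene_meta$zone) == zc]
      if (!length(g)) return(character())
      g[order(-avg[g], g)][seq_len(min(n, length(g)))]
    })
    panels <- panels[lengths(panels) > 0]
  }
  spot_means <- t(vapply(panels, function(g) {
    colMeans(normalized[g, , drop = FALSE])
  }, numeric(ncol(normalized))))
  list(panels = panels, spot_means = spot_means)
}

#' Cluster spatial spots on OR expression principal components
#'
#' PCA on spots (first \code{n_pcs} components) followed by k-means with a
#' fixed seed; spots without OR transcripts are excluded (label NA).
#' Cluster labels are renumbered by mean array row, so label 1 is the
#' dorsal-most band — k-means labels are otherwise arbitrary.
#'
#' @param normalized output of [normalize_spots()]
#' @param spots spot table aligned with its columns
#' @param k number of clusters (5 by convention)
#' @param n_pcs number of principal components (5 by convention)
#' @param seed RNG seed making the partition reproducible
#' @return integer labels named by barcode (NA = excluded)
#' @export
cluster_spots <- function(normalized, spots, k = 5, n_pcs = 5, seed = 1) {
  keep <- colSums(normalized) > 0
  X <- t(normalized[, keep, drop = FALSE])
  n_pcs <- min(n_pcs, ncol(X) - 1, nrow(X) - 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = min(k, nrow(scores)),
                      nstart = 10, iter.max = 100)
  lab <- km$cluster
  mean_row <- tapply(spots$row[keep], lab, mean)
  out <- rep(NA_integer_, nrow(spots))
  out[keep] <- match(as.character(lab), names(sort(mean_row)))
  stats::setNames(out, spots$barcode)
}
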