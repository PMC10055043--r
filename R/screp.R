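#' Sparse UMI count container for cells or spatial spots
#'
#' Wraps a genes x cells sparse integer matrix with cell and gene metadata.
#' Gene metadata joins the zonal OR annotation (\code{is_OR}, \code{zone},
#' \code{is_mito}); cell metadata carries stage, segment and genotype
#' labels.
#'
#' @param counts genes x cells \code{dgCMatrix} (or coercible)
#' @param cell_meta data.frame with a \code{cell_id} column matching
#'   \code{colnames(counts)}
#' @param gene_meta data.frame with \code{gene_id}, \code{is_OR},
#'   \code{zone}, \code{is_mito} matching \code{rownames(counts)}
#' @return a \code{zonal_count_matrix}
#' @export
zonal_count_matrix <- function(counts, cell_meta, gene_meta) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be non-negative integers")
  }
  cn <- colnames(counts)
  if (is.null(cn) && ncol(counts) == 0) cn <- character(0)
  stopifnot(identical(rownames(counts), gene_meta$gene_id),
            identical(cn, cell_meta$cell_id))
  gene_meta$zone <- zone_factor(gene_meta$zone)
  m <- list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta)
  class(m) <- "zonal_count_matrix"
  m
}

#' @export
print.zonal_count_matrix <- function(x, ...) {
  cat(sprintf("zonal_count_matrix: %d genes (%d OR) x %d cells\n",
              nrow(x$counts), sum(x$gene_meta$is_OR), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.zonal_count_matrix <- function(x) dim(x$counts)

subset_cells <- function(m, keep) {
  zonal_count_matrix(m$counts[, keep, drop = FALSE],
                     m$cell_meta[keep, , drop = FALSE], m$gene_meta)
}

#' Quality-control filtering of cells
#'
#' Discards cells failing any criterion: detected genes (count at or above
#' \code{detect_threshold}) below \code{min_genes}, total UMIs below
#' \code{min_umis}, or mitochondrial UMI fraction at or above
#' \code{max_mito_frac}.  The conventional cutoffs for this tissue are 1000
#' genes, 20000 UMIs and 5 percent mitochondrial reads, with the same 3-UMI
#' detection rule used for expressed-OR calling.
#'
#' @param m a [zonal_count_matrix()]
#' @param min_genes,min_umis,max_mito_frac,detect_threshold see above
#' @return filtered \code{zonal_count_matrix}; attribute \code{qc_removed}
#'   holds the number of cells failing each criterion
#' @export
qc_filter_cells <- function(m, min_genes = 1000, min_umis = 20000,
                            max_mito_frac = 0.05, detect_threshold = 3) {
  if (!"is_mito" %in% names(m$gene_meta)) {
    stop("gene metadata lacks an is_mito column")
  }
  genes <- Matrix::colSums(m$counts >= detect_threshold)
  umis <- Matrix::colSums(m$counts)
  mito <- Matrix::colSums(m$counts[m$gene_meta$is_mito, , drop = FALSE])
  frac <- ifelse(umis > 0, mito / umis, 0)
  keep <- genes >= min_genes & umis >= min_umis & frac < max_mito_frac
  out <- subset_cells(m, keep)
  attr(out, "qc_removed") <- c(low_genes = sum(genes < min_genes),
                               low_umis = sum(umis < min_umis),
                               high_mito = sum(frac >= max_mito_frac),
                               total_removed = sum(!keep))
  out
}

#' Call expressed ORs and classify each cell's zonal identity
#'
#' An OR is expressed in a cell when its count reaches \code{umi_threshold}
#' (3 UMIs by convention).  Each cell's zonal identity is the zone of its
#' most highly expressed OR; ties go to the more dorsal zone and then to the
#' lexicographically first gene id; cells without an expressed OR are
#' \code{unknown}.
#'
#' @param m a [zonal_count_matrix()]
#' @param umi_threshold minimum UMIs for an OR to count as expressed
#' @return a \code{repertoire_profile}: list with \code{cells} (per-cell
#'   data.frame: n_expressed_ors, dominant_or, dominant_zone, plus stage /
#'   segment / genotype metadata), \code{expressed} (per-cell character
#'   vectors) and \code{zone_umis} (cells x zone-class OR UMI sums)
#' @export
call_expressed_ors <- function(m, umi_threshold = 3) {
  or_idx <- which(m$gene_meta$is_OR)
  oc <- m$counts[or_idx, , drop = FALSE]
  zmat <- sapply(zone_levels(), function(zl) {
    sel <- as.character(m$gene_meta$zone[or_idx]) == zl
    if (any(sel)) Matrix::colSums(oc[sel, , drop = FALSE]) else
      numeric(ncol(oc))
  })
  zmat <- matrix(zmat, ncol = length(zone_levels()),
                 dimnames = list(m$cell_meta$cell_id, zone_levels()))
  dense <- as.matrix(oc)
  zr <- zone_rank(m$gene_meta$zone[or_idx])
  gid <- m$gene_meta$gene_id[or_idx]
  ord <- order(zr, gid)   # dorsal-first, then lexicographic: tie-break order
  expressed <- vector("list", ncol(dense))
  dom_or <- rep(NA_character_, ncol(dense))
  dom_zone <- rep("unknown", ncol(dense))
  for (j in seq_len(ncol(dense))) {
    e <- which(dense[, j] >= umi_threshold)
    expressed[[j]] <- gid[e]
    if (length(e)) {
      eo <- ord[ord %in% e]
      top <- eo[which.max(dense[eo, j])]
      dom_or[j] <- gid[top]
      dom_zone[j] <- as.character(m$gene_meta$zone[or_idx][top])
    }
  }
  cells <- data.frame(m$cell_meta,
                      n_expressed_ors = lengths(expressed),
                      dominant_or = dom_or,
                      dominant_zone = zone_factor(dom_zone),
                      stringsAsFactors = FALSE)
  names(expressed) <- m$cell_meta$cell_id
  out <- list(cells = cells, expressed = expressed, zone_umis = zmat,
              umi_threshold = umi_threshold,
              gene_zone = stats::setNames(as.character(m$gene_meta$zone),
                                          m$gene_meta$gene_id))
  class(out) <- "repertoire_profile"
  out
}

#' @rdname call_expressed_ors
#' @param profile a \code{repertoire_profile}
#' @return \code{classify_cell_zone}: factor of per-cell zone labels
#' @export
classify_cell_zone <- function(profile) {
  stats::setNames(profile$cells$dominant_zone, profile$cells$cell_id)
}

#' Cross-tabulate zonal repertoire composition by cell group
#'
#' Counts, for each (stage, segment) group, the number of cells expressing
#' at least one OR of each zone class; a cell contributes to every class it
#' expresses.
#'
#' @param profile a \code{repertoire_profile}
#' @param by grouping columns of \code{profile$cells}
#' @return data.frame: grouping columns, n_cells, one column per zone class
#' @export
repertoire_crosstab <- function(profile, by = c("stage", "segment")) {
  stopifnot(all(by %in% names(profile$cells)))
  key <- interaction(profile$cells[by], drop = TRUE, lex.order = TRUE)
  zl <- zone_levels()[zone_levels() != "unknown"]
  rows <- lapply(levels(key), function(k) {
    idx <- which(key == k)
    counts <- sapply(zl, function(zc) {
      sum(vapply(profile$expressed[idx], function(g) {
        any(profile$gene_zone[g] == zc)
      }, logical(1)))
    })
    cbind(profile$cells[idx[1], by, drop = FALSE],
          data.frame(n_cells = length(idx), t(counts),
                     check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-OR log2 fold change between two conditions, by zonal identity
#'
#' Libraries are normalized to counts per million per sample and averaged
#' within each condition before the pseudocounted log-ratio, so the result
#' is invariant under common scaling of both libraries.
#'
#' @param counts_a,counts_b genes x samples matrices (or
#'   \code{zonal_count_matrix}) for the two conditions; rownames are gene
#'   ids
#' @param ann \code{or_annotation} supplying zone labels
#' @param pseudocount added to both CPM means
#' @return data.frame: gene_id, zone, cpm_a, cpm_b, log2fc
#' @export
zonal_fold_change <- function(counts_a, counts_b, ann, pseudocount = 1) {
  get_cpm <- function(x) {
    if (inherits(x, "zonal_count_matrix")) x <- x$counts
    x <- as.matrix(x)
    lib <- colSums(x)
    if (any(lib == 0)) stop("zero library size")
    rowMeans(sweep(x, 2, lib, "/") * 1e6)
  }
  a <- get_cpm(counts_a); b <- get_cpm(counts_b)
  common <- intersect(intersect(names(a), names(b)), ann$gene_id)
  zone <- ann$zone[match(common, ann$gene_id)]
  data.frame(gene_id = common, zone = zone,
             cpm_a = a[common], cpm_b = b[common],
             log2fc = log2((a[common] + pseudocount) /
                             (b[common] + pseudocount)),
             row.names = NULL)
}

#' Rank-sum test between the fold changes of two zone classes
#'
#' @param fc output of [zonal_fold_change()]
#' @param zone_a,zone_b zone class labels
#' @return [rank_sum_test()] result (U of \code{zone_a} group, two-sided p)
#' @export
zone_shift_test <- function(fc, zone_a, zone_b) {
  x <- fc$log2fc[as.character(fc$zone) == as.character(zone_a)]
  y <- fc$log2fc[as.character(fc$zone) == as.character(zone_b)]
  rank_sum_test(x, y)
}
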