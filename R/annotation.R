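#' Construct a zonal OR annotation table
#'
#' The annotation is the universe every analysis joins against: one row per
#' OR gene with 0-based half-open genomic coordinates, a continuous
#' dorsoventral zone index, the discretized zone label, and the class I
#' flag.
#'
#' @param gene_id,chrom character vectors
#' @param start,end integer vectors, 0-based half-open (\code{start < end})
#' @param strand "+" or "-"
#' @param zone_index continuous zone index in \[0.5, 5.5), or NA
#' @param is_class_I logical
#' @param tie tie rule passed to [assign_zone()]
#' @return an \code{or_annotation}: a data.frame with an added \code{zone}
#'   factor column, sorted by (chrom, start)
#' @export
or_annotation <- function(gene_id, chrom, start, end, strand = "+",
                          zone_index = NA_real_, is_class_I = FALSE,
                          tie = "up") {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    zone_index = rep_len(as.numeric(zone_index), n),
    is_class_I = rep_len(as.logical(is_class_I), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (any(df$start >= df$end)) {
    stop("start >= end for gene(s): ",
         paste(df$gene_id[df$start >= df$end], collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df$zone <- assign_zone(df$zone_index, df$is_class_I, df$gene_id, tie = tie)
  df <- df[order(df$chrom, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("or_annotation", "data.frame")
  df
}

#' @export
print.or_annotation <- function(x, ...) {
  cat(sprintf("or_annotation: %d OR genes on %d contig(s)\n",
              nrow(x), length(unique(x$chrom))))
  print(table(zone = x$zone))
  invisible(x)
}

#' Read / write the annotation TSV
#'
#' Seven tab-separated columns (gene_id, chrom, start, end, strand,
#' zone_index, class_I as 0/1) with a `#`-prefixed header line.
#'
#' @param path file path
#' @param tie tie rule passed to [assign_zone()]
#' @return [read_or_annotation()] returns an \code{or_annotation}.
#' @examples
#' ann <- read_or_annotation(system.file("extdata", "example_genes.tsv",
#'                                       package = "zonescape"))
#' table(ann$zone)
#' @export
read_or_annotation <- function(path, tie = "up") {
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("gene_id", "chrom", "start", "end",
                                        "strand", "zone_index", "class_I"))
  or_annotation(df$gene_id, df$chrom, df$start, df$end, df$strand,
                zone_index = df$zone_index,
                is_class_I = df$class_I != 0, tie = tie)
}

#' @rdname read_or_annotation
#' @param ann an \code{or_annotation}
#' @export
write_or_annotation <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gene_id\tchrom\tstart\tend\tstrand\tzone_index\tclass_I", con)
  utils::write.table(
    data.frame(ann$gene_id, ann$chrom, ann$start, ann$end, ann$strand,
               ann$zone_index, as.integer(ann$is_class_I)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Group ORs into genomic clusters by single-linkage chaining
#'
#' Consecutive same-chromosome ORs whose gap (distance from the end of one
#' gene to the start of the next) is at most \code{cluster_gap} share a
#' cluster.  Input must already be sorted by (chrom, start); unsorted input
#' is an error rather than silently reordered.
#'
#' @param ann an \code{or_annotation} (sorted by chrom, start)
#' @param cluster_gap maximum chaining gap in bp (default 300 kb)
#' @return data.frame with one row per cluster: cluster_id, chrom,
#'   start, end, n_genes, and a list-column \code{gene_ids}
#' @export
build_clusters <- function(ann, cluster_gap = 3e5) {
  stopifnot(cluster_gap > 0)
  o <- order(ann$chrom, ann$start, ann$gene_id)
  if (!identical(o, seq_len(nrow(ann)))) {
    stop("annotation must be sorted by (chrom, start); refusing to sort silently")
  }
  if (nrow(ann) == 0) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_genes = integer()))
  }
  # chain against the running maximum end so nested/overlapping genes give
  # the same partition as all-pairs transitive closure
  run_end <- stats::ave(ann$end, ann$chrom, FUN = cummax)
  new_cluster <- c(TRUE, ann$chrom[-1] != ann$chrom[-nrow(ann)] |
                     ann$start[-1] - run_end[-nrow(ann)] > cluster_gap)
  cl <- cumsum(new_cluster)
  out <- do.call(rbind, lapply(split(seq_len(nrow(ann)), cl), function(i) {
    data.frame(chrom = ann$chrom[i[1]],
               start = min(ann$start[i]), end = max(ann$end[i]),
               n_genes = length(i), stringsAsFactors = FALSE)
  }))
  out$cluster_id <- sprintf("ORC_%s_%03d", out$chrom,
                            stats::ave(seq_len(nrow(out)), out$chrom,
                                       FUN = seq_along))
  out$gene_ids <- split(ann$gene_id, cl)
  rownames(out) <- NULL
  out[, c("cluster_id", "chrom", "start", "end", "n_genes", "gene_ids")]
}

#' Annotate fixed-resolution genome bins by resident-OR zonal identity
#'
#' Bins tiling every cluster span receive the zone of the ORs they overlap:
#' the majority zone of overlapping ORs, ties broken towards the more dorsal
#' label (class I counting as dorsal-most).  Bins overlapping no OR cluster
#' are not emitted.  Bins whose only resident ORs are class I get
#' \code{classI}.
#'
#' @param clusters output of [build_clusters()]
#' @param ann the matching \code{or_annotation}
#' @param resolution bin size in bp (50 kb is the conventional resolution
#'   for zonal contact analysis)
#' @return data.frame of bins: bin_id, chrom, start, resolution, zone
#' @export
annotate_bins <- function(clusters, ann, resolution = 5e4) {
  stopifnot(resolution > 0)
  bins <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    lo <- (clusters$start[i] %/% resolution) * resolution
    hi <- ((clusters$end[i] - 1) %/% resolution) * resolution
    data.frame(chrom = clusters$chrom[i],
               start = seq(lo, hi, by = resolution))
  }))
  bins <- unique(bins)
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  gr_bins <- GenomicRanges::GRanges(bins$chrom,
                                    IRanges::IRanges(bins$start + 1,
                                                     bins$start + resolution))
  gr_or <- GenomicRanges::GRanges(ann$chrom,
                                  IRanges::IRanges(ann$start + 1, ann$end))
  hits <- GenomicRanges::findOverlaps(gr_bins, gr_or)
  zone <- rep("unknown", nrow(bins))
  for (b in unique(S4Vectors::queryHits(hits))) {
    zs <- as.character(ann$zone[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == b]])
    tab <- table(zs)
    winners <- names(tab)[tab == max(tab)]
    zone[b] <- winners[which.min(zone_rank(winners))]
  }
  keep <- zone != "unknown"
  out <- data.frame(bin_id = seq_len(sum(keep)) - 1L,
                    chrom = bins$chrom[keep], start = bins$start[keep],
                    resolution = as.integer(resolution),
                    zone = zone_factor(zone[keep]))
  rownames(out) <- NULL
  out
}

#' Export clusters or annotated bins as BED6
#'
#' The name field carries the zone label (bins) or cluster id; scores are 0.
#'
#' @param x output of [build_clusters()] or [annotate_bins()]
#' @param path output path
#' @export
write_bed6 <- function(x, path) {
  if ("zone" %in% names(x)) {
    bed <- data.frame(x$chrom, x$start, x$start + x$resolution,
                      as.character(x$zone), 0L, ".")
  } else {
    bed <- data.frame(x$chrom, x$start, x$end, x$cluster_id, 0L, ".")
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
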