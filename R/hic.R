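#' Binned genome contact matrix container
#'
#' Sparse symmetric contacts stored as an upper-triangle triplet
#' (\code{bin1 <= bin2}) over a fixed-resolution bin table carrying zonal
#' annotation (see [annotate_bins()]).
#'
#' @param bins data.frame: bin_id (0-based), chrom, start, resolution, zone
#' @param contacts data.frame: bin1, bin2, count (bin ids)
#' @param total_contacts library size; defaults to the summed counts
#' @param normalized counts-per-billion normalization applied?
#' @return a \code{contact_matrix}
#' @export
contact_matrix <- function(bins, contacts, total_contacts = NULL,
                           normalized = FALSE) {
  stopifnot(all(c("bin_id", "chrom", "start", "resolution", "zone")
                %in% names(bins)),
            all(c("bin1", "bin2", "count") %in% names(contacts)))
  if (length(unique(bins$resolution)) != 1) {
    stop("bins must share one resolution")
  }
  if (!all(contacts$bin1 %in% bins$bin_id) ||
      !all(contacts$bin2 %in% bins$bin_id)) {
    stop("contact references a bin_id absent from the bin table")
  }
  if (any(contacts$count < 0)) stop("negative contact count")
  swap <- contacts$bin1 > contacts$bin2
  tmp <- contacts$bin1[swap]
  contacts$bin1[swap] <- contacts$bin2[swap]
  contacts$bin2[swap] <- tmp
  agg <- stats::aggregate(count ~ bin1 + bin2, contacts, sum)
  if (is.null(total_contacts)) total_contacts <- sum(agg$count)
  bins$zone <- zone_factor(bins$zone)
  cm <- list(bins = bins[order(bins$bin_id), , drop = FALSE],
             contacts = agg[order(agg$bin1, agg$bin2), , drop = FALSE],
             total_contacts = total_contacts, normalized = normalized,
             resolution = bins$resolution[1])
  class(cm) <- "contact_matrix"
  cm
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %d bins @ %g bp, %d stored pairs, %.4g contacts%s\n",
    nrow(x$bins), x$resolution, nrow(x$contacts), x$total_contacts,
    if (x$normalized) " (counts/billion)" else ""))
  invisible(x)
}

#' Read / write COO contact text with a companion bin table
#'
#' Contacts: \code{bin1<TAB>bin2<TAB>count}; bins: TSV with header
#' (bin_id, chrom, start, resolution, zone).
#'
#' @param contacts_path,bins_path file paths
#' @return \code{read_contacts} returns a \code{contact_matrix}
#' @export
read_contacts <- function(contacts_path, bins_path) {
  bins <- utils::read.table(bins_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  cc <- utils::read.table(contacts_path, header = FALSE, sep = "\t",
                          col.names = c("bin1", "bin2", "count"))
  contact_matrix(bins, cc)
}

#' @rdname read_contacts
#' @param cm a \code{contact_matrix}
#' @param prefix output path prefix; writes \code{<prefix>.coo} and
#'   \code{<prefix>.bins.tsv}
#' @export
write_contacts <- function(cm, prefix) {
  utils::write.table(cm$contacts, paste0(prefix, ".coo"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(cm$bins, paste0(prefix, ".bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Normalize contacts to counts per billion
#'
#' Each count is scaled by \code{1e9 / total_contacts}; idempotent.
#'
#' @param cm a \code{contact_matrix}
#' @return normalized \code{contact_matrix}
#' @export
normalize_cpb <- function(cm) {
  if (cm$normalized) return(cm)
  cm$contacts$count <- cm$contacts$count * 1e9 / cm$total_contacts
  cm$normalized <- TRUE
  cm
}

# dense symmetric matrix of (normalized) counts over all bins
dense_contacts <- function(cm) {
  n <- nrow(cm$bins)
  id <- match(cm$contacts$bin1, cm$bins$bin_id)
  jd <- match(cm$contacts$bin2, cm$bins$bin_id)
  M <- matrix(0, n, n)
  M[cbind(id, jd)] <- cm$contacts$count
  M[cbind(jd, id)] <- cm$contacts$count
  M
}

#' Average interchromosomal contacts between zonal bin classes
#'
#' For every ordered pair of zone classes the mean count over all bin pairs
#' on different chromosomes whose bins carry those classes.  Absent sparse
#' entries count as zero contacts; class I and unannotated bins are
#' excluded; classes with no eligible bin pair are reported as NA (missing,
#' not zero).
#'
#' @param cm a \code{contact_matrix} (normalize first for counts/billion)
#' @param zone_classes named list mapping class labels to zone labels,
#'   e.g. \code{list("1" = "1", "2-3" = c("2","3"))}; default per-zone 1..5
#' @param bins optional replacement bin annotation (bin_id, zone) when the
#'   matrix bins lack zones
#' @return a \code{zone_pair_summary}: list of \code{mean} and
#'   \code{n_pairs} matrices
#' @export
trans_zone_heatmap <- function(cm, zone_classes = NULL, bins = NULL) {
  if (!is.null(bins)) {
    if ("resolution" %in% names(bins) &&
        any(bins$resolution != cm$resolution)) {
      stop("bin annotation resolution does not match the contact matrix")
    }
    cm$bins$zone <- zone_factor(
      bins$zone[match(cm$bins$bin_id, bins$bin_id)])
  }
  if (is.null(zone_classes)) {
    zone_classes <- stats::setNames(as.list(as.character(1:5)),
                                    as.character(1:5))
  }
  M <- dense_contacts(cm)
  chrom <- cm$bins$chrom
  zone <- as.character(cm$bins$zone)
  k <- length(zone_classes)
  mean_m <- n_m <- matrix(NA_real_, k, k,
                          dimnames = list(names(zone_classes),
                                          names(zone_classes)))
  members <- lapply(zone_classes, function(zs) which(zone %in% zs))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ia <- members[[a]]; ib <- members[[b]]
    if (!length(ia) || !length(ib)) { n_m[a, b] <- 0; next }
    tr <- outer(chrom[ia], chrom[ib], "!=")
    n <- sum(tr)
    # for a == b each unordered pair appears twice; the mean is unaffected
    n_m[a, b] <- if (a == b) n / 2 else n
    if (n > 0) mean_m[a, b] <- sum(M[ia, ib, drop = FALSE][tr]) / n
  }
  out <- list(mean = mean_m, n_pairs = n_m,
              classes = zone_classes, resolution = cm$resolution)
  class(out) <- "zone_pair_summary"
  out
}

#' @export
print.zone_pair_summary <- function(x, ...) {
  cat("zone_pair_summary (mean trans contacts per bin pair):\n")
  print(round(x$mean, 3))
  invisible(x)
}

#' Dense cis contact block between two OR clusters
#'
#' Rectangular block of (normalized) counts between the bin ranges of two
#' same-chromosome clusters; values above \code{cap} are clipped for
#' display (the conventional color ceiling is 150 contacts).
#'
#' @param cm a \code{contact_matrix}
#' @param cluster_a,cluster_b rows (or single-row data.frames) with chrom,
#'   start, end
#' @param cap display ceiling; \code{Inf} to disable
#' @return numeric matrix (rows = cluster_a bins, cols = cluster_b bins)
#'   with bin start coordinates as dimnames
#' @export
cis_window <- function(cm, cluster_a, cluster_b, cap = 150) {
  if (cluster_a$chrom != cluster_b$chrom) {
    stop("cis_window requires same-chromosome clusters")
  }
  sel <- function(cl) {
    which(cm$bins$chrom == cl$chrom &
            cm$bins$start + cm$resolution > cl$start &
            cm$bins$start < cl$end)
  }
  ia <- sel(cluster_a); ib <- sel(cluster_b)
  if (!length(ia) || !length(ib)) stop("cluster overlaps no matrix bin")
  M <- dense_contacts(cm)[ia, ib, drop = FALSE]
  dimnames(M) <- list(cm$bins$start[ia], cm$bins$start[ib])
  pmin(M, cap)
}
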