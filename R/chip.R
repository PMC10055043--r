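#' Coverage track container
#'
#' Per-contig read depth as run-length encoded vectors
#' (\code{S4Vectors::RleList}-like: a plain list of \code{Rle}), together
#' with the total mapped read count used for library normalization.
#'
#' @param cov named list of \code{S4Vectors::Rle} per contig (base-pair
#'   resolution; binned tracks are Rle runs of the bin size)
#' @param total_reads total mapped reads of the library
#' @param normalized has library normalization been applied?
#' @return a \code{coverage_track}
#' @export
coverage_track <- function(cov, total_reads, normalized = FALSE) {
  stopifnot(is.list(cov), !is.null(names(cov)), total_reads > 0)
  if (any(vapply(cov, function(r) min(S4Vectors::runValue(r)), 1) < 0)) {
    stop("negative depth in coverage track")
  }
  t <- list(cov = cov, total_reads = total_reads, normalized = normalized)
  class(t) <- "coverage_track"
  t
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d contig(s), %.3g reads%s\n",
              length(x$cov), x$total_reads,
              if (x$normalized) " (library-normalized)" else ""))
  invisible(x)
}

#' Read / write bedGraph coverage
#'
#' Four-column bedGraph (contig, start, end, value; 0-based half-open).
#' Uncovered positions are depth 0.
#'
#' @param path bedGraph file
#' @param contig_lengths named contig lengths; inferred from the largest
#'   end coordinate when omitted
#' @param total_reads library size; defaults to the summed depth
#' @return \code{read_bedgraph} returns a \code{coverage_track}
#' @export
read_bedgraph <- function(path, contig_lengths = NULL, total_reads = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(contig_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(contig_lengths)
    GenomeInfoDb::seqlengths(gr) <- contig_lengths
  }
  covl <- GenomicRanges::coverage(gr, weight = gr$score)
  cov <- stats::setNames(lapply(seq_along(covl), function(i) covl[[i]]),
                         names(covl))
  if (is.null(total_reads)) {
    total_reads <- sum(vapply(cov, function(r) sum(as.numeric(
      S4Vectors::runValue(r)) * S4Vectors::runLength(r)), 1))
  }
  coverage_track(cov, total_reads)
}

#' @rdname read_bedgraph
#' @param track a \code{coverage_track}
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (contig in names(track$cov)) {
    r <- track$cov[[contig]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    v <- S4Vectors::runValue(r)
    keep <- v != 0
    if (any(keep)) {
      utils::write.table(
        data.frame(contig,
                   format(starts[keep], trim = TRUE, scientific = FALSE),
                   format(ends[keep], trim = TRUE, scientific = FALSE),
                   format(v[keep], trim = TRUE, scientific = FALSE)),
        con, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    }
  }
  invisible(path)
}

#' Normalize a track to a fixed library size
#'
#' Depth is scaled by \code{target / total_reads} (target 10 million reads
#' by convention).  Idempotent: an already normalized track is returned
#' unchanged.
#'
#' @param track a \code{coverage_track}
#' @param target target library size
#' @return normalized \code{coverage_track}
#' @export
normalize_library <- function(track, target = 1e7) {
  if (track$normalized) return(track)
  f <- target / track$total_reads
  track$cov <- lapply(track$cov, function(r) r * f)
  track$normalized <- TRUE
  track
}

#' Mean signal density over gene bodies
#'
#' Summed depth over \code{[start, end)} divided by gene length, per gene.
#'
#' @param track a \code{coverage_track}
#' @param ann \code{or_annotation} (or any data.frame with gene_id, chrom,
#'   start, end)
#' @return named numeric vector of per-bp signal densities
#' @export
gene_body_density <- function(track, ann) {
  out <- rep(NA_real_, nrow(ann))
  for (contig in unique(ann$chrom)) {
    sel <- which(ann$chrom == contig)
    r <- track$cov[[contig]]
    if (is.null(r)) stop("contig absent from track: ", contig)
    if (any(ann$end[sel] > length(r))) {
      stop("gene beyond contig bounds on ", contig)
    }
    v <- IRanges::Views(r, start = ann$start[sel] + 1, end = ann$end[sel])
    out[sel] <- IRanges::viewSums(v) / (ann$end[sel] - ann$start[sel])
  }
  stats::setNames(out, ann$gene_id)
}

# mean depth of a real-valued interval [a, b) (bp coordinates, 0-based)
# given the cumulative depth vector of a window; linear within base pairs
interval_means <- function(cum, a, b) {
  lookup <- function(p) {
    i <- floor(p)
    frac <- p - i
    base <- ifelse(i <= 0, 0, cum[pmax(i, 1)])
    step <- cum[pmin(i + 1, length(cum))] - ifelse(i <= 0, 0, cum[pmax(i, 1)])
    base + frac * ifelse(i + 1 > length(cum), 0, step)
  }
  (lookup(b) - lookup(a)) / (b - a)
}

#' Scaled metagene matrix over gene bodies
#'
#' Gene bodies are linearly rescaled to a common length (6 kb by
#' convention) by mean-within-bin resampling; flanks (2 kb each side) are
#' unscaled.  Rows of minus-strand genes are reversed so all rows read
#' 5' to 3'.  Flank positions beyond contig bounds contribute zero.
#'
#' @param track a \code{coverage_track}
#' @param ann \code{or_annotation}
#' @param body rescaled body length (bp)
#' @param flank flank length each side (bp)
#' @param binsize bin width (bp); must divide body and flank
#' @return a genes x bins matrix with attribute \code{sections} giving the
#'   number of (upstream, body, downstream) bins
#' @export
metagene_matrix <- function(track, ann, body = 6000, flank = 2000,
                            binsize = 50) {
  stopifnot(body %% binsize == 0, flank %% binsize == 0)
  nb <- body %/% binsize; nf <- flank %/% binsize
  M <- matrix(0, nrow(ann), nf + nb + nf,
              dimnames = list(ann$gene_id, NULL))
  for (i in seq_len(nrow(ann))) {
    r <- track$cov[[ann$chrom[i]]]
    L <- ann$end[i] - ann$start[i]
    lo <- ann$start[i] - flank; hi <- ann$end[i] + flank
    w <- rep(0, hi - lo)
    ok_lo <- max(lo, 0); ok_hi <- min(hi, length(r))
    if (ok_hi > ok_lo) {
      w[(ok_lo - lo + 1):(ok_hi - lo)] <-
        as.numeric(r[(ok_lo + 1):ok_hi])
    }
    cum <- cumsum(w)
    up <- vapply(seq_len(nf), function(k) {
      interval_means(cum, (k - 1) * binsize, k * binsize)
    }, 1)
    bod <- vapply(seq_len(nb), function(k) {
      interval_means(cum, flank + (k - 1) * L / nb, flank + k * L / nb)
    }, 1)
    down <- vapply(seq_len(nf), function(k) {
      interval_means(cum, flank + L + (k - 1) * binsize,
                     flank + L + k * binsize)
    }, 1)
    row <- c(up, bod, down)
    if (ann$strand[i] == "-") row <- rev(row)
    M[i, ] <- row
  }
  attr(M, "sections") <- c(upstream = nf, body = nb, downstream = nf)
  M
}

#' Zone-grouped summary of gene-body densities
#'
#' Median and quartiles per zone class, all pairwise rank-sum p-values, and
#' a monotonicity flag: TRUE when medians strictly decrease from zone 1 to
#' zone 5 (the dorsoventral heterochromatin gradient) across the zones
#' present; degenerate with fewer than two zones.
#'
#' @param densities named per-gene densities (from [gene_body_density()])
#' @param zones zone labels aligned with \code{densities}
#' @return list: \code{stats} (per-class n, median, q25, q75),
#'   \code{pairwise_p}, \code{monotone_decreasing}
#' @export
zone_group_summary <- function(densities, zones) {
  zones <- zone_factor(zones)
  classes <- zone_levels()[zone_levels() != "unknown"]
  groups <- lapply(classes, function(zc) densities[zones == zc])
  names(groups) <- classes
  groups <- groups[lengths(groups) > 0]
  st <- data.frame(
    zone = names(groups), n = lengths(groups),
    median = vapply(groups, stats::median, 1),
    q25 = vapply(groups, stats::quantile, 1, probs = 0.25),
    q75 = vapply(groups, stats::quantile, 1, probs = 0.75),
    row.names = NULL)
  pw <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(names(groups), names(groups)))
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i < j) {
      pw[i, j] <- pw[j, i] <- rank_sum_test(groups[[i]],
                                            groups[[j]])$p.value
    }
  }
  med_z <- st$median[match(as.character(1:5), st$zone)]
  med_z <- med_z[!is.na(med_z)]
  mono <- length(med_z) >= 2 && all(diff(med_z) < 0)
  list(stats = st, pairwise_p = pw, monotone_decreasing = mono)
}
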