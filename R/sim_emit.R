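#' Emit a single-cell UMI count matrix from a simulated tissue
#'
#' Transcribed ORs of INP cells and surviving (unsilenced) transcribed ORs
#' of iOSNs draw negative-binomial UMIs at \code{mu_low}; the chosen OR of
#' each mOSN draws at \code{mu_high}.  Housekeeping and mitochondrial gene
#' blocks are appended so QC filters are exercisable.  Deterministic under
#' the tissue's (params, seed).
#'
#' @param tissue a [simulate_tissue()] result
#' @return a [zonal_count_matrix()]
#' @export
emit_sc_counts <- function(tissue) {
  p <- tissue$params
  set.seed(derive_seed(p$seed, paste0("sc:", tissue$genotype, ":",
                                      nrow(tissue$cells))))
  ann <- tissue$ann
  n_or <- nrow(ann)
  hk_ids <- sprintf("Hk%03d", seq_len(p$housekeeping$n))
  mt_ids <- sprintf("mt-Gene%02d", seq_len(p$mito$n))
  gene_meta <- data.frame(
    gene_id = c(ann$gene_id, hk_ids, mt_ids),
    is_OR = c(rep(TRUE, n_or), rep(FALSE, length(hk_ids) + length(mt_ids))),
    zone = c(as.character(ann$zone),
             rep("unknown", length(hk_ids) + length(mt_ids))),
    is_mito = c(rep(FALSE, n_or + length(hk_ids)),
                rep(TRUE, length(mt_ids))),
    stringsAsFactors = FALSE)
  n_cells <- nrow(tissue$cells)
  ii <- jj <- integer(0); xx <- numeric(0)
  rnb <- function(n, mu, size) stats::rnbinom(n, mu = mu, size = size)
  for (j in seq_len(n_cells)) {
    st <- tissue$cells$stage[j]
    act <- switch(st,
                  INP = tissue$transcribed[[j]],
                  iOSN = setdiff(tissue$transcribed[[j]],
                                 tissue$silenced[[j]]),
                  mOSN = tissue$chosen[j],
                  integer())
    act <- act[!is.na(act)]
    if (length(act)) {
      mu <- if (st == "mOSN") p$expr$mu_high else p$expr$mu_low
      cnt <- rnb(length(act), mu, p$expr$size)
      keep <- cnt > 0
      ii <- c(ii, act[keep]); jj <- c(jj, rep(j, sum(keep)))
      xx <- c(xx, cnt[keep])
    }
    hk <- rnb(length(hk_ids), p$housekeeping$mu, p$housekeeping$size)
    mt <- rnb(length(mt_ids), p$mito$mu, p$mito$size)
    nz <- which(c(hk, mt) > 0)
    ii <- c(ii, n_or + nz); jj <- c(jj, rep(j, length(nz)))
    xx <- c(xx, c(hk, mt)[nz])
  }
  counts <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(nrow(gene_meta), n_cells),
    dimnames = list(gene_meta$gene_id, tissue$cells$cell_id))
  zonal_count_matrix(counts, tissue$cells, gene_meta)
}

#' Emit a ChIP-style coverage track from a simulated tissue
#'
#' Per-OR enrichment is the allele-level heterochromatin-mark frequency
#' across the tissue's iOSN/mOSN cells; per-bin depth is Poisson with rate
#' \code{depth * (base + alpha * E)} over gene bodies and
#' \code{depth * base} elsewhere, emitted at \code{binsize} resolution.
#'
#' @param tissue a [simulate_tissue()] result (simulate the segment of
#'   interest directly)
#' @param stream tag decorrelating several tracks from one tissue
#' @return a [coverage_track()] (raw counts; library size = summed counts)
#' @export
emit_chip <- function(tissue, stream = "chip") {
  p <- tissue$params
  set.seed(derive_seed(p$seed, paste0(stream, ":", tissue$genotype, ":",
                                      tissue$cells$segment[1])))
  ann <- tissue$ann
  osn <- tissue$cells$stage %in% c("iOSN", "mOSN")
  if (!any(osn)) stop("tissue has no iOSN/mOSN cells to profile")
  E <- colMeans((tissue$marked_a[osn, , drop = FALSE] +
                   tissue$marked_b[osn, , drop = FALSE]) / 2)
  bs <- p$chip$binsize
  lens <- genome_lengths(p, ann)
  cov <- lapply(names(lens), function(contig) {
    n_bins <- ceiling(lens[[contig]] / bs)
    rate <- rep(p$chip$depth * p$chip$base, n_bins)
    sel <- which(ann$chrom == contig)
    for (g in sel) {
      b0 <- ann$start[g] %/% bs + 1
      b1 <- (ann$end[g] - 1) %/% bs + 1
      rate[b0:b1] <- p$chip$depth * (p$chip$base + p$chip$alpha * E[g])
    }
    counts <- stats::rpois(n_bins, rate * bs)
    S4Vectors::Rle(counts / bs, rep.int(bs, n_bins))
  })
  names(cov) <- names(lens)
  total <- sum(vapply(cov, function(r) sum(as.numeric(
    S4Vectors::runValue(r)) * S4Vectors::runLength(r)), 1))
  coverage_track(cov, total_reads = total)
}

#' Emit a binned Hi-C contact matrix from a simulated tissue
#'
#' OR-cluster bins are annotated at the Hi-C resolution; each bin's
#' per-cell compartment propensity M is \code{q} times the mean
#' heterochromatin-mark state of its resident class II OR alleles.  Trans
#' bin pairs draw \code{Poisson(depth * (c0 + c1 * <M_i M_j>))} where
#' \code{<.>} averages over cells; cis pairs add a power-law distance decay
#' \code{cis_scale * d^-cis_decay} (d in bins).  Class I-only bins have
#' M = 0, hence near-background trans rates.
#'
#' @param tissue a [simulate_tissue()] result (mOSN cells carry marks)
#' @param stream tag decorrelating several matrices from one tissue
#' @return a [contact_matrix()] (raw counts)
#' @export
emit_hic <- function(tissue, stream = "hic") {
  p <- tissue$params
  set.seed(derive_seed(p$seed, paste0(stream, ":", tissue$genotype, ":",
                                      tissue$cells$segment[1])))
  ann <- tissue$ann
  clusters <- build_clusters(ann)
  bins <- annotate_bins(clusters, ann, resolution = p$hic$resolution)
  osn <- which(tissue$cells$stage %in% c("iOSN", "mOSN"))
  if (!length(osn)) stop("tissue has no mOSN cells")
  # resident class II ORs per bin
  res <- p$hic$resolution
  mid_bin <- ((ann$start + ann$end) %/% 2) %/% res * res
  Mcells <- matrix(0, length(osn), nrow(bins))
  alle <- (tissue$marked_a[osn, , drop = FALSE] +
             tissue$marked_b[osn, , drop = FALSE]) / 2
  for (b in seq_len(nrow(bins))) {
    g <- which(ann$chrom == bins$chrom[b] & mid_bin == bins$start[b] &
                 !ann$is_class_I)
    if (length(g)) {
      Mcells[, b] <- p$hic$q * rowMeans(alle[, g, drop = FALSE])
    }
  }
  MM <- crossprod(Mcells) / length(osn)
  n <- nrow(bins)
  chrom <- bins$chrom
  bin_idx <- bins$start %/% res
  rows <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- rows[, 1]; j <- rows[, 2]
  rate <- p$hic$c0 + p$hic$c1 * MM[cbind(i, j)]
  cis <- chrom[i] == chrom[j]
  d <- pmax(abs(bin_idx[j] - bin_idx[i]), 1)
  rate[cis] <- rate[cis] + p$hic$cis_scale * d[cis]^(-p$hic$cis_decay)
  counts <- stats::rpois(length(rate), p$hic$depth * rate)
  keep <- counts > 0
  # the OR-cluster window is a tiny slice of a whole-genome library; the
  # library size includes the unprofiled rest-of-genome contact mass so
  # counts-per-billion scaling is comparable across libraries
  contact_matrix(bins,
                 data.frame(bin1 = bins$bin_id[i[keep]],
                            bin2 = bins$bin_id[j[keep]],
                            count = counts[keep]),
                 total_contacts = sum(counts) +
                   p$hic$depth * p$hic$genome_total)
}

# uniform point in a ball of given radius
runif_ball <- function(n, radius) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  v * radius * stats::runif(n)^(1 / 3)
}

#' Emit single-cell 3D genome structures from a simulated tissue
#'
#' For each selected mOSN, both haplotypes of every chromosome are laid out
#' as particles at the Dip-C resolution.  Heterochromatin-marked OR alleles
#' join one of \code{n_centers} compartment centers (jitter sigma, in
#' particle radii); all other particles are uniform in a nucleus of radius
#' R.  Coordinates are in particle-radius units.
#'
#' @param tissue a [simulate_tissue()] result with mOSN cells
#' @param n_cells number of structures (first \code{n_cells} mOSNs)
#' @return list of \code{structure_3d}
#' @export
emit_3dg <- function(tissue, n_cells = 48) {
  p <- tissue$params
  ann <- tissue$ann
  mosn <- which(tissue$cells$stage == "mOSN")
  if (length(mosn) < n_cells) stop("not enough mOSN cells in tissue")
  mosn <- mosn[seq_len(n_cells)]
  res <- as.integer(p$dipc$resolution)
  lens <- genome_lengths(p, ann)
  scaffold <- do.call(rbind, lapply(names(lens), function(contig) {
    pos <- as.integer(seq(0, lens[[contig]] - res, by = res))
    data.frame(chrom = rep(sprintf("%s(%s)", contig, c("mat", "pat")),
                           each = length(pos)),
               pos = rep(pos, 2), stringsAsFactors = FALSE)
  }))
  mid_bin <- ((ann$start + ann$end) %/% 2) %/% res * res
  or_row <- lapply(c("mat", "pat"), function(h) {
    match(sprintf("%s(%s):%.0f", ann$chrom, h, mid_bin),
          sprintf("%s:%.0f", scaffold$chrom, scaffold$pos))
  })
  set.seed(derive_seed(p$seed, paste0("dipc:", tissue$genotype, ":",
                                      tissue$cells$segment[1], ":",
                                      n_cells)))
  lapply(seq_along(mosn), function(k) {
    ci <- mosn[k]
    np <- nrow(scaffold)
    xyz <- runif_ball(np, p$dipc$radius)
    centers <- runif_ball(p$dipc$n_centers, p$dipc$radius / 2)
    for (h in 1:2) {
      marked <- if (h == 1) tissue$marked_a[ci, ] else tissue$marked_b[ci, ]
      rowsel <- or_row[[h]][marked]
      if (length(rowsel)) {
        cidx <- sample.int(p$dipc$n_centers, length(rowsel), replace = TRUE)
        xyz[rowsel, ] <- centers[cidx, , drop = FALSE] +
          matrix(stats::rnorm(3 * length(rowsel), sd = p$dipc$sigma),
                 ncol = 3)
      }
    }
    s <- list(cell_id = tissue$cells$cell_id[ci],
              particles = data.frame(scaffold, x = xyz[, 1], y = xyz[, 2],
                                     z = xyz[, 3]),
              resolution = res)
    class(s) <- "structure_3d"
    s
  })
}

#' Emit a spatial transcriptomic grid from the generative model
#'
#' Array rows map linearly to the dorsoventral coordinate; each spot
#' aggregates \code{cells_per_spot} mOSN choice draws at its zone
#' (negative-binomial \code{mu_high} UMIs per chosen OR) plus Poisson
#' ambient counts across all ORs.  The spot table carries the ground-truth
#' zone of each row.
#'
#' @param params a [sim_params()] (the genotype field selects wt/cko)
#' @param ann optional pre-built annotation
#' @return a [spatial_dataset()]; \code{spots$true_zone} holds the
#'   generator's ground truth
#' @export
emit_spatial <- function(params, ann = NULL) {
  p <- params
  if (is.null(ann)) ann <- make_or_universe(p)
  rows <- p$spatial$rows; cols <- p$spatial$cols
  u_row <- (seq_len(rows) - 0.5) / rows
  Z_row <- pmin(1L + as.integer(floor(5 * u_row)), 5L)
  spots <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  spots <- spots[order(spots$row, spots$col), ]
  spots <- data.frame(
    barcode = sprintf("SPOT_%02d_%02d", spots$row, spots$col),
    row = spots$row, col = spots$col,
    x = spots$col * 100, y = spots$row * 100, in_tissue = TRUE,
    true_zone = as.character(Z_row[spots$row]),
    stringsAsFactors = FALSE)
  # one pool of mOSN choice draws per spot, at the spot's zone
  tissue <- simulate_tissue(
    p, n_cells = nrow(spots) * p$spatial$cells_per_spot, stage = "mOSN",
    u = rep((spots$row - 0.5) / rows, each = p$spatial$cells_per_spot),
    ann = ann, stream = "spatial")
  set.seed(derive_seed(p$seed, paste0("spatial-counts:", p$genotype)))
  n_or <- nrow(ann)
  counts <- matrix(0, n_or, nrow(spots),
                   dimnames = list(ann$gene_id, spots$barcode))
  for (s in seq_len(nrow(spots))) {
    idx <- (s - 1) * p$spatial$cells_per_spot +
      seq_len(p$spatial$cells_per_spot)
    ch <- tissue$chosen[idx]
    umi <- stats::rnbinom(length(ch), mu = p$expr$mu_high,
                          size = p$expr$size)
    for (k in seq_along(ch)) counts[ch[k], s] <- counts[ch[k], s] + umi[k]
    amb <- stats::rpois(n_or, p$spatial$ambient)
    counts[, s] <- counts[, s] + amb
  }
  gene_meta <- data.frame(gene_id = ann$gene_id, is_OR = TRUE,
                          zone = as.character(ann$zone),
                          stringsAsFactors = FALSE)
  spatial_dataset(spots, Matrix::Matrix(counts, sparse = TRUE), gene_meta)
}
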