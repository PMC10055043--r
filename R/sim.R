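#' Parameters of the opposing-rheostats generative model
#'
#' The simulator implements the interplay of two dorsoventrally graded,
#' probabilistic processes acting on each cell at dorsoventral position
#' \code{u} (segment zone \code{Z = 1 + floor(5u)}):
#' \enumerate{
#'   \item \emph{Polygenic transcription} (INP stage): a cell transcribes
#'     \code{K ~ Poisson(lambda * W(Z)/W(5))} ORs sampled without replacement
#'     from the eligible repertoire (identities \code{z <= Z}; class I only
#'     in zone 1) with geometric promoter weights \code{w(z) =
#'     promoter_decay^(z-1)}.  \code{W(Z)} is the total promoter weight of
#'     the eligible set, so the polygenic breadth grows with the repertoire
#'     (ventral INPs transcribe more ORs), and \code{lambda} is the mean at
#'     the full ventral repertoire.
#'   \item \emph{Silencing} (INP to iOSN transition), two coupled layers:
#'     a transcriptional shutoff acting on the transcribed set with
#'     probability \code{min(s0 + beta*(Z - z), cap)} (steep in the dorsal
#'     offset; this is what singular choice sees), and a heterochromatin
#'     mark deposited on every class II OR allele with a probability that is
#'     nearly saturated for ORs at or dorsal to their home zone and falls
#'     steeply for ORs ventral of the cell's position (this is what ChIP,
#'     Hi-C and Dip-C see).  Class I ORs are exempt from both layers.
#' }
#' Mature OSNs choose one OR among the surviving (transcribed, unsilenced)
#' alleles with probability proportional to the promoter weight, resampling
#' the cell if no allele survives.
#'
#' The \code{nfi_cko} genotype removes the ventral positional signal:
#' identities in \code{nfi_tx_zones} leave the eligible repertoire, the
#' zone-3 promoter weight is attenuated by \code{nfi_z3_atten}, the
#' positional input of the silencing layers collapses to
#' \code{min(Z, nfi_null_zone)}, and heterochromatin is lost from
#' identities in \code{nfi_sil_zones}.
#'
#' @param seed integer master seed; every emitted artifact is a
#'   deterministic function of (params, seed)
#' @param n_or_per_zone named counts of ORs per identity class
#' @param genome genome layout: number of chromosomes, OR clusters per
#'   chromosome, intra-cluster gene spacing and gene length (bp)
#' @param promoter_decay geometric decay of promoter weight per zone
#' @param polygenic_mean mean number of co-transcribed ORs at the full
#'   (zone 5, wild-type) repertoire
#' @param silence_same,silence_slope,silence_cap transcriptional shutoff
#'   probability \code{min(silence_same + silence_slope*(Z-z), silence_cap)}
#' @param mark heterochromatin-mark layer: probability at zero dorsal offset
#'   (\code{p0}), shallow consolidation slope above (\code{slope_up}), steep
#'   establishment slope below (\code{slope_down}), and cap
#' @param nfi_tx_zones,nfi_sil_zones,nfi_null_zone,nfi_z3_atten knockout
#'   switches (see above)
#' @param expr negative-binomial UMI emission (mu_low for polygenic
#'   transcripts, mu_high for the chosen OR, common size)
#' @param housekeeping,mito non-OR gene blocks added to single-cell output
#'   so QC filters are exercisable
#' @param chip,hic,dipc,spatial emitter settings (see the methods vignette)
#' @param genotype "wt" or "nfi_cko"
#' @return a \code{sim_params} list
#' @export
sim_params <- function(seed = 1L,
                       n_or_per_zone = c(classI = 20, `1` = 40, `2` = 40,
                                         `3` = 30, `4` = 25, `5` = 15),
                       genome = list(n_chrom = 4, clusters_per_chrom = 3,
                                     spacing = 50000, gene_length = 2000),
                       promoter_decay = 0.95,
                       polygenic_mean = 8,
                       silence_same = 0.5,
                       silence_slope = 0.45,
                       silence_cap = 0.99,
                       mark = list(p0 = 0.82, slope_up = 0.02,
                                   slope_down = 0.15, cap = 0.95),
                       nfi_tx_zones = c(4, 5),
                       nfi_sil_zones = c(3, 4, 5),
                       nfi_null_zone = 2,
                       nfi_z3_atten = 0.3,
                       expr = list(mu_low = 5, mu_high = 500, size = 2),
                       housekeeping = list(n = 300, mu = 30, size = 5),
                       mito = list(n = 10, mu = 8, size = 5),
                       chip = list(base = 0.5, alpha = 3, depth = 1,
                                   binsize = 50),
                       hic = list(c0 = 2, c1 = 200, q = 1, cis_scale = 50,
                                  cis_decay = 1, depth = 1,
                                  resolution = 50000, genome_total = 1e7),
                       dipc = list(n_centers = 5, sigma = 0.8, radius = 40,
                                   resolution = 20000),
                       spatial = list(rows = 20, cols = 12,
                                      cells_per_spot = 12, ambient = 0.05),
                       genotype = c("wt", "nfi_cko")) {
  genotype <- match.arg(genotype)
  stopifnot(promoter_decay > 0, promoter_decay <= 1,
            silence_same >= 0, silence_same <= 1, silence_cap <= 1,
            polygenic_mean > 0, seed == as.integer(seed))
  p <- list(seed = as.integer(seed), n_or_per_zone = n_or_per_zone,
            genome = genome, promoter_decay = promoter_decay,
            polygenic_mean = polygenic_mean, silence_same = silence_same,
            silence_slope = silence_slope, silence_cap = silence_cap,
            mark = mark, nfi_tx_zones = nfi_tx_zones,
            nfi_sil_zones = nfi_sil_zones, nfi_null_zone = nfi_null_zone,
            nfi_z3_atten = nfi_z3_atten, expr = expr,
            housekeeping = housekeeping, mito = mito, chip = chip,
            hic = hic, dipc = dipc, spatial = spatial, genotype = genotype)
  class(p) <- "sim_params"
  p
}

# Deterministic sub-stream seed: a small rolling hash of (seed, tag) kept
# inside 32-bit integer range so set.seed() accepts it on any platform.
derive_seed <- function(seed, tag) {
  s <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(tag)) s <- (s * 31 + c) %% 2147483647
  as.integer(max(s, 1))
}

#' Build the synthetic OR universe implied by simulation parameters
#'
#' Lays ORs out in genomic clusters (round-robin over
#' \code{n_chrom * clusters_per_chrom} clusters in randomized order, so
#' clusters have mixed zonal constitution), gives each a continuous zone
#' index that rounds back to its identity, and returns the standard
#' annotation table.  Depends only on (params, seed), not on genotype.
#'
#' @param params a [sim_params()] list
#' @return an \code{or_annotation}
#' @export
make_or_universe <- function(params) {
  set.seed(derive_seed(params$seed, "universe"))
  g <- params$genome
  zones <- rep(names(params$n_or_per_zone), params$n_or_per_zone)
  n <- length(zones)
  n_clusters <- g$n_chrom * g$clusters_per_chrom
  # randomized order then round-robin: every cluster gets a mixed identity
  zones <- sample(zones)
  cluster <- rep_len(seq_len(n_clusters), n)
  o <- order(cluster)
  zones <- zones[o]; cluster <- cluster[o]
  chrom <- sprintf("chr%d", (cluster - 1L) %/% g$clusters_per_chrom + 1L)
  cluster_in_chrom <- (cluster - 1L) %% g$clusters_per_chrom
  idx_in_cluster <- stats::ave(seq_len(n), cluster, FUN = seq_along) - 1L
  start <- as.integer(1e6 + cluster_in_chrom * 2e6 +
                        idx_in_cluster * g$spacing)
  is_cI <- zones == "classI"
  zone_num <- ifelse(is_cI, 1, suppressWarnings(as.numeric(zones)))
  zone_index <- zone_num + stats::runif(n, -0.25, 0.25)
  or_annotation(
    gene_id = sprintf("Olfr%s%04d", ifelse(is_cI, "I", ""), seq_len(n)),
    chrom = chrom, start = start, end = start + as.integer(g$gene_length),
    strand = sample(c("+", "-"), n, replace = TRUE),
    zone_index = zone_index, is_class_I = is_cI)
}

# total chromosome length implied by the layout (uniform across
# chromosomes): the largest gene end plus a 1 Mb margin, rounded up to 1 Mb
genome_lengths <- function(params, ann = NULL) {
  if (is.null(ann)) ann <- make_or_universe(params)
  len <- ceiling((max(ann$end) + 1e6) / 1e6) * 1e6
  stats::setNames(rep(len, params$genome$n_chrom),
                  sprintf("chr%d", seq_len(params$genome$n_chrom)))
}

#' Eligible OR repertoire of a cell
#'
#' Wild type: ORs with identity \code{z <= Z}, plus class I when (and only
#' when) \code{Z == 1}.  \code{nfi_cko}: identities in \code{nfi_tx_zones}
#' are additionally removed, an effective ceiling of
#' \code{min(Z, 3)} under defaults.
#'
#' @param ann \code{or_annotation}
#' @param Z segment zone, integer in 1..5
#' @param genotype "wt" or "nfi_cko"
#' @param params [sim_params()] (for the knockout zone sets)
#' @return integer indices into \code{ann}
#' @export
eligibility <- function(ann, Z, genotype = "wt", params = sim_params()) {
  stopifnot(Z %in% 1:5)
  z <- zone_number(ann$zone)
  ok <- !is.na(z) & z <= Z
  ok[ann$is_class_I] <- Z == 1
  if (genotype == "nfi_cko") {
    ok <- ok & !(z %in% params$nfi_tx_zones & !ann$is_class_I)
  }
  which(ok)
}

# promoter weights of a gene set; class I shares the zone-1 weight; the
# knockout attenuates zone-3 promoters
promoter_weights <- function(ann, params, genotype) {
  z <- zone_number(ann$zone, classI_as = 1)
  w <- params$promoter_decay^(z - 1)
  if (genotype == "nfi_cko") {
    w[z == 3 & !ann$is_class_I] <- w[z == 3 & !ann$is_class_I] *
      params$nfi_z3_atten
  }
  w
}

# transcriptional shutoff probability for OR identity z in a cell at
# segment zone Z (class I exempt -> 0 handled by caller masks)
p_shutoff <- function(z, Z, params) {
  pmin(pmax(params$silence_same + params$silence_slope * (Z - z), 0),
       params$silence_cap)
}

# heterochromatin-mark probability; broken-stick in dorsal offset d = Z - z
p_mark <- function(z, Z, params) {
  d <- Z - z
  p <- params$mark$p0 +
    ifelse(d >= 0, params$mark$slope_up * d, params$mark$slope_down * d)
  pmin(pmax(p, 0), params$mark$cap)
}

# per-cell effective positional input of the silencing layers
sil_zone <- function(Z, params, genotype) {
  if (genotype == "nfi_cko") pmin(Z, params$nfi_null_zone) else Z
}

segment_bounds <- function(segment) {
  switch(segment,
         dorsal = c(0, 0.2), dorsomedial = c(0.2, 0.6),
         ventral = c(0.6, 1), whole = c(0, 1),
         stop("unknown segment: ", segment))
}

#' Simulate a tissue of cells under the opposing-rheostats model
#'
#' @param params a [sim_params()] list (its \code{genotype} is used)
#' @param n_cells number of cells
#' @param stage one stage for all cells, or a named vector of proportions
#'   over \code{GBC, INP, iOSN, mOSN}
#' @param segment dorsoventral band the cells are dissected from:
#'   "whole" (u uniform in \[0,1\]), "dorsal" (zone 1), "dorsomedial"
#'   (zones 2-3) or "ventral" (zones 4-5)
#' @param u optional explicit dorsoventral positions (overrides segment)
#' @param ann optional pre-built annotation (must come from
#'   [make_or_universe()] with the same params)
#' @param stream extra tag mixed into the random stream, so several tissues
#'   can be drawn independently from one master seed
#' @return a \code{sim_tissue}: list with the annotation, a per-cell
#'   data.frame (\code{cells}), per-cell transcribed/silenced index lists,
#'   per-allele heterochromatin mark matrices (\code{marked_a},
#'   \code{marked_b}) and the chosen OR index per mOSN
#' @export
simulate_tissue <- function(params, n_cells, stage = "mOSN",
                            segment = "whole", u = NULL, ann = NULL,
                            stream = "tissue") {
  if (is.null(ann)) ann <- make_or_universe(params)
  set.seed(derive_seed(params$seed, paste(stream, segment, n_cells,
                                          params$genotype, sep = ":")))
  if (is.null(u)) {
    b <- segment_bounds(segment)
    u <- stats::runif(n_cells, b[1], b[2])
  }
  stopifnot(length(u) == n_cells, all(u >= 0 & u <= 1))
  stages <- c("GBC", "INP", "iOSN", "mOSN")
  if (length(stage) == 1 && is.null(names(stage))) {
    st <- rep(match.arg(stage, stages), n_cells)
  } else {
    stopifnot(all(names(stage) %in% stages))
    st <- sample(names(stage), n_cells, replace = TRUE,
                 prob = unname(stage))
  }
  Z <- pmin(1L + as.integer(floor(5 * u)), 5L)
  gt <- params$genotype
  n_genes <- nrow(ann)
  z_id <- zone_number(ann$zone, classI_as = 1)
  w_all <- promoter_weights(ann, params, gt)
  # reference promoter mass: full wild-type repertoire (zone 5)
  elig_by_Z <- lapply(1:5, function(zz) eligibility(ann, zz, gt, params))
  W_ref <- sum(promoter_weights(ann, params, "wt")[
    eligibility(ann, 5, "wt", params)])
  cI <- ann$is_class_I

  transcribed <- vector("list", n_cells)
  silenced <- vector("list", n_cells)
  chosen <- rep(NA_integer_, n_cells)
  marked_a <- matrix(FALSE, n_cells, n_genes)
  marked_b <- matrix(FALSE, n_cells, n_genes)
  mark_p_of <- function(Zi) {
    Zs <- sil_zone(Zi, params, gt)
    p <- p_mark(z_id, Zs, params)
    p[cI] <- 0
    if (gt == "nfi_cko") p[z_id %in% params$nfi_sil_zones & !cI] <- 0
    p
  }
  for (i in seq_len(n_cells)) {
    if (st[i] == "GBC") { transcribed[[i]] <- integer(); silenced[[i]] <- integer(); next }
    elig <- elig_by_Z[[Z[i]]]
    if (!length(elig)) stop("empty eligibility at Z=", Z[i])
    w <- w_all[elig]
    lam <- params$polygenic_mean * sum(w) / W_ref
    Zs <- sil_zone(Z[i], params, gt)
    p_tx <- p_shutoff(z_id[elig], Zs, params)
    for (attempt in 1:100) {
      K <- min(stats::rpois(1, lam), length(elig))
      tr <- if (K > 0) sort(sample.int(length(elig), K, prob = w)) else integer()
      sil <- if (st[i] %in% c("iOSN", "mOSN") && length(tr)) {
        tr[stats::runif(length(tr)) < p_tx[tr]]
      } else integer()
      if (st[i] != "mOSN") break
      surv <- setdiff(tr, sil)
      if (length(surv)) {
        chosen[i] <- elig[if (length(surv) == 1) surv else
          sample(surv, 1, prob = w[surv])]
        break
      }
      if (attempt == 100) stop("mOSN resampling failed to find a survivor")
    }
    transcribed[[i]] <- elig[tr]
    silenced[[i]] <- elig[sil]
    if (st[i] %in% c("iOSN", "mOSN")) {
      p <- mark_p_of(Z[i])
      marked_a[i, ] <- stats::runif(n_genes) < p
      marked_b[i, ] <- stats::runif(n_genes) < p
    }
  }
  tissue <- list(params = params, genotype = gt, ann = ann,
                 cells = data.frame(
                   cell_id = sprintf("cell_%05d", seq_len(n_cells)),
                   u = u, Z = Z, stage = st, segment = segment,
                   genotype = gt, stringsAsFactors = FALSE),
                 transcribed = transcribed, silenced = silenced,
                 chosen = chosen, marked_a = marked_a, marked_b = marked_b)
  class(tissue) <- "sim_tissue"
  tissue
}

#' @export
print.sim_tissue <- function(x, ...) {
  cat(sprintf("sim_tissue: %d cells (%s), genotype %s, %d ORs\n",
              nrow(x$cells), paste(unique(x$cells$stage), collapse = "/"),
              x$genotype, nrow(x$ann)))
  invisible(x)
}

#' Per-OR silencing and choice frequencies by segment zone
#'
#' @param tissue a \code{sim_tissue}
#' @return data.frame: gene_id, zone, segment zone Z, silencing frequency
#'   (transcriptional shutoff among cells transcribing the OR), mark
#'   frequency (allele-level heterochromatin), choice frequency among the
#'   segment's mOSNs
#' @export
tissue_summary <- function(tissue) {
  ann <- tissue$ann
  out <- do.call(rbind, lapply(sort(unique(tissue$cells$Z)), function(zz) {
    sel <- tissue$cells$Z == zz
    n_tr <- n_sil <- numeric(nrow(ann))
    for (i in which(sel)) {
      n_tr[tissue$transcribed[[i]]] <- n_tr[tissue$transcribed[[i]]] + 1
      n_sil[tissue$silenced[[i]]] <- n_sil[tissue$silenced[[i]]] + 1
    }
    osn <- sel & tissue$cells$stage %in% c("iOSN", "mOSN")
    mosn <- which(sel & tissue$cells$stage == "mOSN")
    ch <- tabulate(tissue$chosen[mosn], nbins = nrow(ann))
    data.frame(gene_id = ann$gene_id, zone = ann$zone, Z = zz,
               silencing_freq = ifelse(n_tr > 0, n_sil / n_tr, NA),
               mark_freq = if (any(osn))
                 colMeans((tissue$marked_a[osn, , drop = FALSE] +
                             tissue$marked_b[osn, , drop = FALSE]) / 2)
               else NA,
               choice_freq = if (length(mosn)) ch / length(mosn) else NA)
  }))
  rownames(out) <- NULL
  out
}
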