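#' Configuration of an end-to-end pipeline run
#'
#' A flat, fully serializable configuration: simulation parameters (or
#' paths to existing inputs), analysis thresholds, stage toggles, seed and
#' output directory.  A run is reproducible from its persisted config.
#'
#' @param seed master seed
#' @param out_dir output directory
#' @param genotypes genotypes to simulate ("wt", "nfi_cko" or both)
#' @param n_cells cells per simulated tissue stage
#' @param stages character vector of pipeline stages to run, from
#'   \code{simulate, screp, chip, hic, dipc, spatial}
#' @param umi_threshold expressed-OR UMI threshold
#' @param qc QC thresholds passed to [qc_filter_cells()]; the conventional
#'   full-scale values (1000 genes, 20000 UMIs, 5 percent mito) are scaled
#'   here to the synthetic library sizes
#' @param dipc_cells structures per segment
#' @param radius Dip-C proximity radius (particle radii)
#' @param sim_args extra arguments for [sim_params()]
#' @return a \code{run_config} list
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("zonescape_run_"),
                       genotypes = c("wt", "nfi_cko"),
                       n_cells = 600,
                       stages = c("simulate", "screp", "chip", "hic",
                                  "dipc", "spatial"),
                       umi_threshold = 3,
                       qc = list(min_genes = 50, min_umis = 500,
                                 max_mito_frac = 0.05),
                       dipc_cells = 24, radius = 2.5,
                       sim_args = list()) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              genotypes = genotypes, n_cells = n_cells, stages = stages,
              umi_threshold = umi_threshold, qc = qc,
              dipc_cells = dipc_cells, radius = radius,
              sim_args = sim_args)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration and input files
#'
#' Schema checks for the configuration and, when file inputs are given,
#' cross-checks between annotation and matrices.
#'
#' @param cfg a [run_config()]
#' @return character vector of diagnostics (empty when clean)
#' @export
validate_inputs <- function(cfg) {
  diag <- character()
  if (!length(cfg$genotypes) ||
      !all(cfg$genotypes %in% c("wt", "nfi_cko"))) {
    diag <- c(diag, "genotypes must be drawn from {wt, nfi_cko}")
  }
  known <- c("simulate", "screp", "chip", "hic", "dipc", "spatial")
  if (!all(cfg$stages %in% known)) {
    diag <- c(diag, paste("unknown stage(s):",
                          paste(setdiff(cfg$stages, known), collapse = ", ")))
  }
  if (cfg$n_cells < 10) diag <- c(diag, "n_cells too small (< 10)")
  for (f in c("min_genes", "min_umis", "max_mito_frac")) {
    if (is.null(cfg$qc[[f]])) diag <- c(diag, paste("qc$", f, " missing"))
  }
  if (cfg$radius <= 0) diag <- c(diag, "radius must be positive")
  diag
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline: simulate, analyse, report
#'
#' Executes the requested stages in dependency order for each genotype,
#' writes every intermediate artifact in its on-disk format plus summary
#' TSVs, and a manifest with seeds and md5 checksums of all outputs.
#' Numeric outputs are byte-identical across runs with the same config.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a report list: file paths, zone-gradient summaries,
#'   knockout shift statistics and the manifest path
#' @export
run_pipeline <- function(cfg) {
  diag <- validate_inputs(cfg)
  if (length(diag)) stop("invalid config: ", paste(diag, collapse = "; "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, files = character())
  add_file <- function(p) report$files <<- c(report$files, p)
  fc_inputs <- list()

  for (gt in cfg$genotypes) {
    pars <- do.call(sim_params, c(list(seed = cfg$seed, genotype = gt),
                                  cfg$sim_args))
    gdir <- file.path(cfg$out_dir, gt)
    dir.create(gdir, showWarnings = FALSE)
    ann <- make_or_universe(pars)
    add_file(write_or_annotation(ann, file.path(gdir, "genes.tsv")))
    clusters <- build_clusters(ann)
    add_file(write_bed6(clusters, file.path(gdir, "clusters.bed")))
    bins <- annotate_bins(clusters, ann, pars$hic$resolution)
    add_file(write_bed6(bins, file.path(gdir, "bins.bed")))

    if (any(c("simulate", "screp") %in% cfg$stages)) {
      mix <- c(INP = 0.4, mOSN = 0.6)
      tis <- simulate_tissue(pars, cfg$n_cells, stage = mix, ann = ann,
                             stream = "pipeline-sc")
      m <- emit_sc_counts(tis)
      write_counts_dir(m, file.path(gdir, "sc_counts"))
      add_file(file.path(gdir, "sc_counts", "matrix.mtx"))
      if ("screp" %in% cfg$stages) {
        mq <- qc_filter_cells(m, min_genes = cfg$qc$min_genes,
                              min_umis = cfg$qc$min_umis,
                              max_mito_frac = cfg$qc$max_mito_frac)
        prof <- call_expressed_ors(mq, cfg$umi_threshold)
        add_file(write_tsv(prof$cells, file.path(gdir, "profiles.tsv")))
        add_file(write_tsv(repertoire_crosstab(prof, by = "stage"),
                           file.path(gdir, "crosstab.tsv")))
        mosn <- mq$cell_meta$stage == "mOSN"
        fc_inputs[[gt]] <- list(counts = mq$counts[, mosn, drop = FALSE],
                                ann = ann)
      }
    }
    if ("chip" %in% cfg$stages) {
      tis <- simulate_tissue(pars, cfg$n_cells, stage = "mOSN", ann = ann,
                             stream = "pipeline-chip")
      track <- emit_chip(tis)
      add_file(write_bedgraph(track, file.path(gdir, "chip.bedgraph")))
      dens <- gene_body_density(normalize_library(track), ann)
      add_file(write_tsv(data.frame(gene_id = names(dens),
                                    zone = as.character(ann$zone),
                                    density = dens),
                         file.path(gdir, "chip_density.tsv")))
      zs <- zone_group_summary(dens, ann$zone)
      add_file(write_tsv(zs$stats, file.path(gdir, "chip_zone_stats.tsv")))
      report[[paste0("chip_monotone_", gt)]] <- zs$monotone_decreasing
    }
    if ("hic" %in% cfg$stages) {
      tis <- simulate_tissue(pars, cfg$n_cells, stage = "mOSN",
                             segment = "ventral", ann = ann,
                             stream = "pipeline-hic")
      cmx <- emit_hic(tis)
      write_contacts(cmx, file.path(gdir, "hic"))
      add_file(file.path(gdir, "hic.coo"))
      hm <- trans_zone_heatmap(normalize_cpb(cmx))
      add_file(write_tsv(as.data.frame(hm$mean),
                         file.path(gdir, "hic_zone_heatmap.tsv")))
      report[[paste0("hic_heatmap_", gt)]] <- hm$mean
    }
    if ("dipc" %in% cfg$stages) {
      tis <- simulate_tissue(pars, max(cfg$dipc_cells, 10) * 2,
                             stage = "mOSN", segment = "ventral",
                             ann = ann, stream = "pipeline-dipc")
      structs <- emit_3dg(tis, n_cells = cfg$dipc_cells)
      ddir <- file.path(gdir, "3dg")
      dir.create(ddir, showWarnings = FALSE)
      for (s in structs) {
        add_file(write_3dg(s, file.path(ddir, paste0(s$cell_id, ".3dg"))))
      }
      stats <- do.call(rbind, lapply(structs, function(s) {
        g <- neighbors_within(s, map_or_loci(s, ann), cfg$radius)
        agg <- aggregate_stats(g)
        data.frame(cell_id = s$cell_id, n_edges = nrow(g$edges),
                   max_aggregate = max(agg$n_ors),
                   max_chroms = max(agg$n_chromosomes))
      }))
      add_file(write_tsv(stats, file.path(gdir, "dipc_stats.tsv")))
    }
    if ("spatial" %in% cfg$stages) {
      sp <- emit_spatial(pars, ann)
      add_file(write_tsv(sp$spots, file.path(gdir, "spots.tsv")))
      spf <- filter_spots(sp)
      nrm <- normalize_spots(spf)
      zt <- assign_spot_zone(nrm, spf$gene_meta)
      add_file(write_tsv(zt, file.path(gdir, "spot_zones.tsv")))
      acc <- mean(ifelse(as.character(zt$assigned_zone) == "classI", "1",
                         as.character(zt$assigned_zone)) ==
                    spf$spots$true_zone)
      report[[paste0("spatial_accuracy_", gt)]] <- acc
    }
  }

  if (length(fc_inputs) == 2) {
    fc <- zonal_fold_change(fc_inputs$nfi_cko$counts, fc_inputs$wt$counts,
                            fc_inputs$wt$ann)
    add_file(write_tsv(fc, file.path(cfg$out_dir, "cko_shift.tsv")))
    sh <- zone_shift_test(fc, "2", "5")
    report$cko_shift <- list(fold_changes = fc, zone2_vs_zone5 = sh)
  }

  manifest <- data.frame(file = report$files,
                         md5 = unname(tools::md5sum(report$files)))
  manifest_path <- file.path(cfg$out_dir, "manifest.tsv")
  write_tsv(manifest, manifest_path)
  report$manifest <- manifest_path
  invisible(report)
}
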