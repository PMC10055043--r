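# zonescape

Analysis of dorsoventral **zonal regulation of olfactory receptor (OR)
genes** in the mouse main olfactory epithelium (MOE), for computational
biologists working on OR gene choice, heterochromatic silencing and 3D
genome compartmentalization.

Every mature olfactory neuron expresses a single OR allele, and which ORs
are eligible depends on the neuron's position along the dorsoventral (DV)
axis: the MOE divides into five zones (zone 1 dorsal-most, zone 5
ventral-most; class I ORs are a separate zone-1-resident class). The
package quantifies the two opposing, DV-graded processes that implement
this map — low-level *polygenic OR transcription* in progenitors, which
admits ORs with identity z ≤ Z ("correct or more dorsal"), and
*heterochromatic silencing* with probability increasing in the dorsal
offset (Z − z), which removes dorsal identities in ventral cells — plus
their readouts in five assay types:

* **or_annotation** — zonal OR annotation (nearest-integer binning of
  continuous zone indices, class I flags), genomic cluster construction,
  and 50 kb bin annotation by resident-OR identity.
* **sc_repertoire** — single-cell QC (1000 genes / 20,000 UMIs / <5%
  mito), expressed-OR calling (≥3 UMIs), per-cell zonal classification by
  the most highly expressed OR, repertoire crosstabs, CPM log2
  fold-changes and Wilcoxon rank-sum zone-shift tests.
* **chip_zonal** — library normalization to 10M reads, length-normalized
  gene-body signal densities, 6 kb-rescaled metagene matrices, zone-group
  summaries with a monotonicity flag.
* **hic_zonal** — counts/billion normalization, average interchromosomal
  contacts between zonally annotated OR bins (class I excluded), long-
  range cis cluster windows with a 150-contact display cap.
* **dipc_compartments** — dip-c `.3dg` structures: pairwise OR distances
  in particle radii, radius-neighborhood graphs (2.5/5/10 radii ≈
  150/300/600 nm), aggregate (connected-component) size and chromosome
  complexity, interchromosomal proximity fractions per zone class,
  per-cell contact-density comparisons.
* **spatial_zones** — spatial spot filtering (≥2 OR genes, ≥3 OR UMIs),
  OR-restricted normalization, argmax zonal spot assignment, frozen
  top-20 zone panels, PCA/k-means spot clustering (5 PCs, 5 clusters).
* **synthetic_data** — a seeded generative model of the opposing
  rheostats (eligibility + Poisson polygenic transcription with geometric
  promoter weights; shutoff probability `min(s0 + β(Z−z), cap)`; a
  broken-stick heterochromatin-mark layer; NFI-knockout switches) that
  emits all six on-disk input formats: MTX counts, bedGraph, COO
  contacts + bin table, `.3dg`, spot tables.

## Worked example

Simulate a wild-type tissue, profile progenitor repertoires, and measure
the zonal Hi-C contact gradient:

```r
library(zonescape)

p   <- sim_params(seed = 1)          # study conditions, fully seeded
ann <- make_or_universe(p)
ann
#> or_annotation: 170 OR genes on 4 contig(s)
#>  classI      1      2      3      4      5 unknown
#>      20     40     40     30     25     15       0

# polygenic transcription is broader ventrally
tis  <- simulate_tissue(p, 1000, stage = "INP", stream = "readme")
prof <- call_expressed_ors(emit_sc_counts(tis))
mean(prof$cells$n_expressed_ors[prof$cells$Z == 1])   # 2.46
mean(prof$cells$n_expressed_ors[prof$cells$Z == 5])   # 5.68

# ventral mOSNs: average trans contacts between zonally annotated bins
mosn <- simulate_tissue(p, 800, stage = "mOSN", segment = "ventral",
                        ann = ann, stream = "readme")
hm <- trans_zone_heatmap(normalize_cpb(emit_hic(mosn)),
        zone_classes = list("1" = "1", "2-3" = c("2","3"),
                            "4-5" = c("4","5")))
round(hm$mean)
#>         1   2-3   4-5
#> 1   13668 13282 12199
#> 2-3 13282 12913 11860
#> 4-5 12199 11860 10868
```

Dorsal INPs average ~2.5 expressed ORs against ~5.7 in ventral INPs — the
polygenic breadth gradient. The heatmap entries are mean interchromosomal
contacts per bin pair in counts/billion: in ventral neurons every zone
class participates in OR compartments (all cells far above the ~200
counts/billion background), whereas in a dorsal tissue only the zone-1
rows stay high. Running the same code with
`sim_params(seed = 1, genotype = "nfi_cko")` collapses the 4-5 × 4-5
entry to background while leaving 1 × 1 unchanged.

Real data enter through `read_or_annotation()`, `read_counts_dir()`,
`read_bedgraph()`, `read_contacts()` and `read_3dg()`; an end-to-end
seeded run (simulate → analyse → manifest with checksums) is
`run_pipeline(run_config(seed = 1))`, also available from the shell via
`Rscript inst/cli/zonescape.R run --seed 1 --out DIR`.

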