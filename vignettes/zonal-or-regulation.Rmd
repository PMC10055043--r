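---
title: "Modelling and measuring dorsoventral zonal regulation of olfactory receptor genes"
author: "zonescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring dorsoventral zonal regulation of olfactory receptor genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological problem

Each mature olfactory sensory neuron (mOSN) of the mouse main olfactory
epithelium (MOE) expresses exactly one allele of one olfactory receptor
(OR) gene out of more than a thousand candidates. Which ORs are available
for choice depends on where the neuron sits along the dorsoventral (DV)
axis: the MOE is divided into about five bands ("zones"), zone 1
dorsal-most and zone 5 ventral-most, and each OR has a characteristic zone
of expression. Class I (fish-like) ORs are expressed in zone 1 but are
regulated by a separate mechanism and are treated as their own identity
class throughout this package.

Zonal restriction is not enforced by a single switch. Progenitor cells
(INPs) transiently co-transcribe many ORs at low level — *polygenic
transcription* — and the transcribed set is positionally biased: a cell in
zone Z transcribes ORs whose native zone z satisfies z ≤ Z ("correct or
more dorsal"). During the INP→iOSN transition, non-chosen ORs acquire
heterochromatic marks and coalesce into multi-chromosomal nuclear
aggregates (OR compartments), detectable as enriched long-range Hi-C and
Dip-C contacts. Silencing is also graded: an OR is silenced most
frequently in cells ventral to its native zone. The balance of these two
opposing, DV-graded rheostats — transcription that opens the repertoire
dorsally-first and silencing that removes dorsal identities ventrally —
leaves, in each zone, the zone-appropriate ORs most available for singular
choice. NFI transcription factors (NFIA/B/X), expressed in a dorsal-low /
ventral-high gradient, supply the ventral positional signal: their triple
knockout (cKO) dorsalizes the ventral MOE, with zone 2 identities
expanding ventrally, zone 4–5 expression and heterochromatin lost, and OR
compartments collapsing.

`zonescape` implements (i) the zonal OR annotation and genomic binning,
(ii) the five measurement pipelines that quantify these gradients
(single-cell repertoires, ChIP gene-body densities, Hi-C trans-contact
aggregation, Dip-C 3D-structure statistics, spatial-transcriptomic spot
classification), and (iii) a seeded generative model that emits all six
input data kinds, so every stage runs and is testable at desk scale.

## The generative model

A simulated cell at DV position $u \in [0,1]$ has segment zone
$Z = 1 + \lfloor 5u \rfloor$ (clipped to 5). The model has two coupled
stochastic layers on top of a transcription-eligibility rule.

**Eligibility and polygenic transcription.** The eligible repertoire in a
wild-type cell is $\{ \mathrm{OR}: z(\mathrm{OR}) \le Z \}$, plus class I
if and only if $Z = 1$. Promoter strength decays geometrically with
ventral identity, $w(z) = \rho^{\,z-1}$ with $\rho = 0.95$ (class I shares
the zone-1 weight). An INP transcribes
$K \sim \mathrm{Poisson}\!\left(\lambda \, W(Z)/W(5)\right)$ ORs sampled
without replacement with probability proportional to $w$, where $W(Z)$ is
the summed weight of the eligible set and $\lambda = 8$ is the polygenic
mean at the full (zone-5) repertoire. Scaling the Poisson mean by the
eligible promoter mass makes the polygenic breadth grow with the
repertoire, which is what single-cell data show: ventral INPs transcribe
more ORs than dorsal INPs. A fixed per-cell mean independent of $Z$ cannot
produce that gradient, because the number of distinct sampled ORs would
have the same distribution in every zone.

**Transcriptional shutoff (what choice sees).** Each transcribed OR of
identity $z$ in a cell at $Z$ is shut off with probability
$\min(s_0 + \beta\,(Z - z),\; 0.99)$, with $s_0 = 0.5$ and
$\beta = 0.45$ per zone of dorsal offset. The steep slope concentrates the
surviving set on the cell's own zone, so the mOSN choice — one OR drawn
proportionally to $w$ among surviving transcribed ORs, resampling the cell
if none survives — lands on a zone-appropriate OR in the large majority of
cells. The resample-on-empty rule models the feedback-driven retry; an
OR-less mOSN is not a state the biology permits.

**Heterochromatin mark layer (what ChIP, Hi-C and Dip-C see).** Chromatin
state is not a deterministic copy of the shutoff decision: marks cover
most of the repertoire in every mOSN, with a graded frequency. Each class
II OR allele is independently marked with probability given by a
broken-stick function of the dorsal offset $d = Z - z$:
$p(d) = 0.82 + 0.02\,d$ for $d \ge 0$ (shallow consolidation above the
native zone) and $p(d) = 0.82 + 0.15\,d$ floored at 0 for $d < 0$ (steep
establishment below it), capped at 0.95. Class I ORs are never marked.
Two layers are necessary, not a convenience: dorsal-OR compartment
contacts are nearly constant across segments (the "default" aggregation of
zone-1 ORs) while singular choice requires a steep offset dependence; one
probability cannot be both flat and steep in the same variable. The
broken-stick gives dorsal ORs a nearly saturated, segment-insensitive mark
frequency and ventral ORs a strong DV gradient, reproducing both the
linear-genome (ChIP) and 3D (Hi-C/Dip-C) patterns.

**The NFI knockout.** `genotype = "nfi_cko"` applies four switches with
one interpretation — the ventral positional signal is lost and cells read
their position as dorsomedial: identities in `nfi_tx_zones` ({4, 5}) leave
the eligible repertoire; the zone-3 promoter weight is attenuated ×0.3
(zone-3 transcription is partially NFI-dependent, leaving zone 3 present
but minor); the positional input of the shutoff layer collapses to
$\min(Z, 2)$; and marks are lost from identities in `nfi_sil_zones`
({3, 4, 5}). Together these reproduce the knockout phenotypes: zone-2
dominance of ventral spots, heterochromatin loss from zones 3–5,
collapse of zone-4–5 trans contacts to background with zone-1 contacts
unchanged, and depletion of zone-4–5 transcripts with a positive zone-2
fold change.

## What the emitters produce

* `emit_sc_counts()` — sparse UMI matrix: negative-binomial counts
  (`mu_low = 5` for polygenic transcripts, `mu_high = 500` for the chosen
  OR, size 2), plus housekeeping and mitochondrial blocks so QC filters
  have something to reject.
* `emit_chip()` — binned coverage (50 bp): Poisson depth at
  `base + alpha * E` over gene bodies, where E is the tissue's measured
  per-OR allele-mark frequency, and `base` elsewhere.
* `emit_hic()` — COO contacts over OR-cluster bins at 50 kb. Bin
  propensity M is the mean mark state of resident class II OR alleles;
  trans pairs draw Poisson(`c0 + c1 * <M_i M_j>`), cis pairs add a
  power-law distance decay. The recorded library size includes a constant
  unprofiled rest-of-genome mass (`genome_total = 1e7`), because the OR
  window is a tiny slice of a real library; without it, counts-per-billion
  scaling would be dominated by the compartment signal itself and
  cross-library comparisons would be distorted.
* `emit_3dg()` — dip-c-format 3D structures at 20 kb particles: marked OR
  alleles join one of 5 compartment centers (Gaussian jitter σ = 0.8
  particle radii), everything else is uniform in a nucleus of radius 40
  particle radii (1 radius ≈ 60 nm, so ≈ 2.4 µm — a realistic nucleus;
  a much smaller ball would let random proximity percolate the
  neighborhood graph and drown the compartment signal).
* `emit_spatial()` — a rows×cols spot grid whose rows map linearly to
  $u$; each spot aggregates 12 mOSN choice draws at its zone plus Poisson
  ambient counts (rate 0.05 per OR).

Determinism: every emitter reseeds from a hash of (master seed, stream
tag), so artifacts are reproducible individually and independent of
execution order; two runs of the full pipeline under one seed are
byte-identical.

## Parameters that matter

| parameter | default | units / range | role |
|---|---|---|---|
| `promoter_decay` (ρ) | 0.95 | per zone | dorsal bias of transcription; smaller values overweight dorsal ORs in choice |
| `polygenic_mean` (λ) | 8 | ORs/cell | polygenic breadth at the full repertoire |
| `silence_same` (s₀) | 0.5 | probability | shutoff at zero offset; exposed as free because the data do not fix whether own-zone silencing is mechanistically distinct |
| `silence_slope` (β) | 0.45 | per zone | steepness of shutoff; drives zonal fidelity of choice |
| `mark$p0 / slope_up / slope_down` | 0.82 / 0.02 / 0.15 | probability, per zone | heterochromatin gradient; `slope_up` small keeps dorsal contacts segment-stable |
| `hic$c0, c1` | 2, 200 | counts | background and compartment contact rates |
| `dipc$n_centers, sigma, radius` | 5, 0.8, 40 | —, radii, radii | compartment number, tightness, nucleus size |
| QC / calling thresholds | 3 UMI, 1000 genes, 20000 UMIs, 5% mito | — | the field's standard cutoffs; synthetic libraries are smaller, so the pipeline config scales them |
| `hic$resolution` | 50 kb (100 kb for cluster maps) | bp | zonal bin annotation resolution |
| Dip-C radii | 2.5 / 5 / 10 | particle radii | ≈150/300/600 nm proximity scales |

All numeric rate forms (linear shutoff, broken-stick marks, geometric
weights, Poisson polygenic count) are the simplest monotone
parameterizations that jointly reproduce the qualitative patterns; they
were fixed from the analytic calculations above before the test suite was
written and are not tuned per test.

## Numerical and design choices

* **Tie-breaks are deterministic and documented**: zone index x.5 rounds
  half-up (configurable); mixed bins take the majority zone, dorsal-most
  on ties; a cell's dominant OR resolves ties dorsal-first then
  lexicographically; spot argmax ties go dorsal.
* **Rank-sum test**: Mann-Whitney U, exact two-sided p for tie-free
  groups of ≤ 20 (matching exhaustive permutation enumeration), normal
  approximation with midrank tie correction otherwise.
* **CPM + pseudocount fold changes** stand in for DESeq2-style shrinkage:
  size-factor machinery is out of scope, and CPM keeps the examples
  closed-form and scale-invariant.
* **Median-library log1p normalization** stands in for variance
  stabilization of spatial counts; it preserves within-spot ranks, which
  is all the argmax assignment consumes.
* **Unbalanced Hi-C counts** are the primary path (library-normalized
  counts/billion); matrix balancing is out of scope.
* **Gene-body ChIP density** uses base-pair coverage, not fragment
  overlap counts — a deliberate dialect choice; with the metagene body
  rescaled to 6 kb (2 kb flanks) by exact fractional-bin averaging,
  minus-strand rows reversed.
* **Aggregates** are formalized as connected components of the
  r-neighborhood graph over OR loci (haplotypes distinct); per-locus
  neighbor counts are also exposed. Average linkage, index tie-break, for
  heatmap leaf ordering.
* **classI in spot scores** is its own class, merged with zone 1 only
  when evaluating against ground truth (class I is a zone-1-resident
  identity).
* **Degenerate inputs**: empty survivor sets resample the cell; zero-OR
  spots are `none` and excluded from clustering; empty zone classes
  report NA (missing), never 0.

## Problem sizes

The shipped tests and the acceptance script use: 2,000 INPs for the
polygenic gradient; 2,500 (whole) plus 5×1,200 (per-segment) mOSNs for
ChIP; 800 mOSNs per segment for Hi-C; 48+48 Dip-C structures over a
4-chromosome, 170-OR universe; a 20×12 spatial grid with 12 cells per
spot; and a 300-cell paired pipeline for the determinism check. These
sizes give the oracle and direction checks comfortable statistical
margins while a full suite run stays in the minutes range on one CPU.

## What passing tests do and do not show

The generator emulates the *statistical structure* of the real assays:
zonally annotated clustered OR genes, graded polygenic repertoires, graded
allele-level silencing, compartment-driven contact enrichment, spot-level
mixtures with ambient noise. It does not emulate: read-level artifacts
(alignment, duplicates, mapping bias), doublets or ambient RNA in the
single-cell sense, chromosome territories or polymer constraints in 3D
structures (non-compartment particles are uniform), enhancer-hub (Greek
Island) dynamics, or batch and section effects in spatial data. Passing
the acceptance properties therefore demonstrates that the analysis code
measures what it claims to measure on data with known ground truth — not
that the biological parameter values are estimates of the real system's
rates. Real-data use starts at the file-format readers
(`read_or_annotation()`, `read_counts_dir()`, `read_bedgraph()`,
`read_contacts()`, `read_3dg()`), which consume the standard formats
directly.

## Known limitations

* The continuous zone indices of real ORs come from an external
  reference annotation; the package consumes them but cannot re-derive
  them, and class I membership is taken from the input flag, not from
  homology.
* Spot clustering is PCA + k-means with a fixed seed — a stand-in with
  the conventional cluster count (5) and PC count (5), not a
  re-implementation of graph-based clustering.
* The cKO model compresses NFI dose dependence into one switch; the
  intermediate phenotypes of partial-allele knockouts are outside its
  scope.
* Hi-C emission covers OR-cluster bins only; genome-wide compartment
  eigenvectors, TADs and loops are out of scope.
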