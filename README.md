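# msapseq

Simulation and analysis of **MSAP-Seq** experiments: methylation-sensitive
amplification polymorphism coupled to high-throughput sequencing, for
profiling DNA methylation at CCGG sites in plants — including crops with
large, repetitive genomes where whole-genome bisulfite sequencing is
impractical.

## What the method does

Genomic DNA is double-digested with EcoRI (GAATTC, methylation-insensitive
rare cutter) and HpaII (CCGG), whose cleavage is blocked when the internal
CG of the site is methylated on both strands. End-specific adapters are
ligated and fragments amplified with partially selective primers (the
default pair E-AC / H-TG carries two selective nucleotides, giving
4² = 16 primer combinations to tune library complexity). Amplicons are
sonicated to ~300 bp and sequenced; reads carrying the HpaII adapter tail
followed by the `CGG` remnant are the countable *tags*. Per CCGG site
*s* and sample *j*, tag counts are normalized to reads per million,

    RPM(s, j) = raw(s, j) × 10⁶ / N(j),

with *N(j)* the sample's total site-assigned tags. Because HpaII only cuts
unmethylated sites, **lower tag abundance means higher methylation**:
a significant abundance drop between conditions is a new-methylation event,
a rise is a demethylation. Replicated designs are tested per site with an
exact conditional binomial rate-ratio test (given n = x₁ + x₂, under the
null x₁ ~ Binomial(n, N₁/(N₁+N₂)); two-sided, Benjamini–Hochberg
corrected); unreplicated pooled designs use the fold-change rule
FC ≥ 5. Single-locus validation follows the MSRE-qPCR closed form
FC = E^ΔCp with ΔCp = Cp(digested) − Cp(mock).

The package also contains a molecule-level simulator of the whole wet-lab
protocol (methylation-aware digestion, selective amplification, sonication,
read synthesis) that emits FASTQ plus a ground-truth table, so every
pipeline stage is testable against known truth.

## Worked example

Simulate a drought study (two conditions × two replicates) on a synthetic
genome, then run the analysis side of the package on the simulated reads:

```r
library(msapseq)

sg      <- simulate_genome(n_sites = 300, seed = 7)
ctrl    <- random_methylome(sg$genome, p_methylated = 0.5, seed = 8)
drought <- ctrl
gain    <- which(ctrl == 0)[1:40]          # 40 sites gain methylation
drought[gain] <- 1

cfg <- list(
  genome = sg$genome,
  samples = c(
    lapply(1:2, function(i) list(name = paste0("ctrl", i),    methylome = ctrl,
                                 n_molecules = 25, seed = 100 + i)),
    lapply(1:2, function(i) list(name = paste0("drought", i), methylome = drought,
                                 n_molecules = 25, seed = 200 + i))))
sim <- simulate_experiment(cfg)

asn    <- lapply(sim$samples, function(s)
  map_tags_builtin(filter_reads(s$reads)$tags, sg$genome))
counts <- apply_min_coverage(normalize_rpm(count_sites(asn)), 2)
counts
#> <site_count_table> 79 site(s) x 4 sample(s), RPM-normalized

dms <- call_dms_replicated(
  site_count_table(counts$raw[, c("ctrl1", "ctrl2")]),
  site_count_table(counts$raw[, c("drought1", "drought2")]))
sig <- dms[dms$significant, ]
head(sig[order(sig$q), c("site_id", "mean_rpm_a", "mean_rpm_b",
                         "log2_fc", "q", "direction")], 3)
#>               site_id mean_rpm_a mean_rpm_b log2_fc        q       direction
#> chr1:40144 chr1:40144      20648          0   -6.36 1.39e-21 new_methylation
#> chr1:5256   chr1:5256      20650          0   -6.36 1.39e-21 new_methylation
#> chr1:48421 chr1:48421      20206          0   -6.33 2.96e-21 new_methylation
```

This run calls 24 DMS, 23 of them new methylations, all among the spiked
sites. (Only spiked sites that were amplifiable *and* detectable in the
control can be recovered: sites whose flanks don't match the selective
primers, or whose counts fall under the coverage floor, never enter the
table — exactly as in the real assay.) Reading the top record: the site at
`chr1:40144` had ~20,600 RPM in control and none under drought
(log₂ FC −6.36, BH q ≈ 10⁻²¹), i.e. a stress-induced methylation gain
silenced HpaII cleavage there.

Other entry points: `read_annotation_gff3()` + `classify_sites()` for the
four-category genomic annotation and `go_enrichment()`;
`call_dms_unreplicated()` and `classify_reversibility()` for pooled designs
and recovery phases; `sample_distance_matrix()` + `hierarchical_cluster()`
for replicate QC; `analyze_qpcr()` for MSRE-qPCR validation tables;
`run_pipeline()` for config-driven end-to-end runs (a thin CLI wrapper
lives in `inst/scripts/msapseq.R`). See the methods vignette
(`vignettes/msapseq-methods.Rmd`) for models, parameter defaults and
design choices.

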