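---
title: "MSAP-Seq simulation and analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSAP-Seq simulation and analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapseq)
```

## The assay in brief

MSAP-Seq profiles DNA methylation at CCGG sites by coupling the classic
methylation-sensitive amplification polymorphism (MSAP) chemistry to
high-throughput sequencing. Genomic DNA is double-digested with EcoRI
(GAATTC, methylation-insensitive rare cutter) and HpaII (CCGG,
blocked when the internal CG is methylated on both strands). Adapters
specific to the two sticky ends are ligated, and fragments are amplified
with partially selective primers — only fragments whose ends were actually
cut, carry the matching adapter, and whose first genomic bases match the
primer's selective nucleotides are amplified. Amplicons are sonicated to
~300 bp and sequenced. A read is informative ("a tag") when it carries the
HpaII-adapter tail followed by the CGG restriction remnant: its count at a
CCGG site is inversely related to the site's methylation. Lower abundance
between conditions means new methylation; higher abundance means
demethylation.

`msapseq` implements both halves of this design: a molecule-level simulator
of the wet-lab protocol and the full downstream analysis (tag filtering,
site assignment, RPM normalization, annotation, differential calling,
clustering QC, and the MSRE-qPCR validation arithmetic).

## The simulator

### Digestion model

Each of `n_molecules` genome copies is digested independently. EcoRI cuts
at every GAATTC (`G^AATTC`). HpaII cuts a CCGG site (`C^CGG`) with
probability `1 - m`, where `m` is the site's methylated fraction in the
`MethylomeMap`. `m` is the fraction of molecules in the cell population on
which the site is protected; `m = 1` is fully methylated, `m = 0`
unmethylated, intermediate values model mixed populations. Hemimethylation
and the internal/external cytosine distinction are deliberately not
modeled: the assay reads out exactly two states per molecule (cut or not),
so a binary per-molecule blocking model matches the assay's interpretive
resolution. Deterministic mode (`digest(..., mode = "deterministic")`)
requires a binary methylome and is used where exact ground truth is wanted.
Fragments always tile each chromosome exactly; this invariant is tested.

### Selective amplification

A fragment becomes an amplicon when both ends are cut ends whose
inward-reading strands begin with the matching primer's remnant
(`CGG` for HpaII, `AATTC` for EcoRI) followed by that primer's selective
nucleotides, and when its insert length lies in the size-selection window
(default 50-1000 bp). For the fragment right of a cut the selective context
is read on the forward strand just past the recognition site; for the
fragment left of a cut it is the reverse complement of the bases just
upstream — by palindromy both ends present the same remnant. EcoRI-EcoRI
products are excluded by default: they carry no HpaII adapter and can never
pass the downstream tag filter. The default primers are the protocol pair
E-AC (`GACTGCGTACCAATTCAC`) and H-TG (`GATGAGTCTAGAACGGTG`); with two
selective nucleotides there are `4^2 = 16` primer combinations, the lever
used to tune library complexity.

Amplicon sequences are represented as adapter tail + genomic insert
(through the filled-in remnant of the far end) + reverse-complemented far
tail, so the adapter-ligation chemistry is abstracted to its read-level
consequence only.

### Sonication and read synthesis

Shear piece lengths follow a normal distribution (mean 300 bp, the
protocol's sonication target; sd 100 bp as a plausible sonicator spread)
truncated to `[1, amplicon length]`, drawn sequentially; an amplicon not
longer than the mean is left unsheared. One read is synthesized from each
piece end (a forward read and a reverse-complement read; mates /1 and /2
in paired mode). In single-end mode a piece no longer than the read length
is emitted once — its reverse-complement twin would be a duplicate
observation of the same molecule, which would double-count tags. Reads are
Q30 throughout with optional uniform substitution errors.

Two consequences of this model are worth knowing when interpreting tests:

* Terminal pieces shorter than 63 bp yield tags shorter than the 50 bp
  minimum after the 13 bp adapter tail is trimmed, so a small,
  amplicon-length-dependent fraction of molecule ends is lost. Recovered
  counts therefore sit slightly *below* truth abundances (ratios ~0.8-1.0
  at the default settings), never above.
* Counts are exactly deterministic only when every amplicon is a single
  unsheared piece; the reverse-complement invariance check therefore uses a
  size-selection window below the sonication mean, which pins the
  deterministic core of the pipeline without shear noise.

### The synthetic genome generator

`simulate_genome()` plants recognition sites in a random background that is
kept free of accidental CCGG/GAATTC occurrences. Defaults, chosen once as
study conditions: inter-site spacing uniform on 200-900 bp (bracketing the
300 bp sonication target, so amplicons realistically straddle the shear
size), one EcoRI site per eight CCGG sites (rare vs frequent cutter), and
a 0.8 probability that each flank matches the selective primer (so most
planted sites are assayable while the selectivity logic is exercised by
real negatives). `random_methylome()` methylates each site with
probability 0.5 by default — a neutral, balanced default that gives
presence and absence classes equal weight in recovery tests. What the
generator does *not* emulate: repetitive or duplicated contexts (every
site's flanking sequence is unique, so mapping ambiguity must be
constructed explicitly in tests), CHG/CHH methylation, PCR amplification
bias (abundance is proportional to molecule count), and indel or
quality-profile sequencing errors. Passing recovery tests on this generator
therefore demonstrates the pipeline's bookkeeping is exact, not that real
repetitive genomes will map uniquely.

## The analysis pipeline

### Tag filtering

A read is retained iff the HpaII adapter tail `GATGAGTCTAGAA` is found at
the read 5' end (or reverse-complemented at the 3' end), the trimmed read
retains `CGG` at the adapter-proximal terminus, and the trimmed length is
at least 50 bp. Trimming removes only the tail: the CGG remnant and the
selective bases are genomic and must survive for the downstream filter and
for mapping. One substitution is tolerated in the 13 bp adapter — enough
for a Q30 error, short enough that random 13-mers essentially never match.
Filtering a stream of already-filtered tags is a no-op, and mates of a
pair are filtered independently (each qualifying mate is one countable
fragment-end observation).

### Site assignment and counting

The built-in mapper places a tag at the CCGG site whose cut remnant its
leading CGG coincides with — a forward-strand match starting at
`start0 + 1` or a reverse-complement match ending at `start0 + 3` — by
exact full-length string match. Unique placements are assigned; multi-site
placements are discarded as ambiguous (protecting site-level
quantification); everything else is unmapped. The mapper is intentionally
exact-match: it is a desk-scale stand-in for an external aligner, whose
output can be ingested from SAM instead (`ingest_sam()`), applying the same
cut-coincidence rule plus primary/unique filters. For genome-free designs,
`denovo_tag_table()` counts tags by the exact 30-mer following the remnant.

RPM is `raw * 1e6 / library size` with the library size defined as the
total number of tags assigned to any CCGG site in that sample. This
denominator (rather than raw or filtered read totals) makes RPM comparable
across samples with different contamination and unmapped fractions, and
makes per-sample RPM sum to exactly one million. The coverage floor
(2 reads per sample, applied per sample with any-sample retention) follows
the assay's reporting convention; library sizes are kept from the pre-floor
totals so the floor does not silently rescale RPM.

### Annotation

Sites are classified into the four standard categories — gene body (TSS to
gene end, introns included), promoter (the 1000 bp upstream of the TSS,
strand-aware), repeat, intergenic — with precedence gene_body > promoter >
repeat > intergenic on overlap. The tie rule is a package choice: the
assay's stated strength is gene-containing regions, so gene-linked evidence
wins. A site in two genes' features carries both gene ids but is counted
once in distributions. GO enrichment uses the one-sided hypergeometric
upper tail with BH adjustment; the universe is the set of genes with at
least one MSAP-Seq site, conditioning on assayability so enrichment is not
driven by CCGG density. GO terms are used as given (no is-a propagation).

### Differential methylation

For replicated designs, within-group counts are pooled and each site is
tested with an exact conditional binomial rate-ratio test: given
`n = x1 + x2`, under the null `x1 ~ Binomial(n, N1/(N1+N2))`; the
two-sided p sums all outcomes no more likely than the observed one.
This self-contained exact test replaces the external count-model package a
production pipeline might call; the trade-off, documented as a limitation,
is that pooling provides no overdispersion control between replicates, and
the conditional test is conservative (type-I error below nominal, which the
null simulation verifies). BH q-values gate significance at `q <= 0.05` by
default; both p and q are reported because the assay's conventional
threshold ("P < 0.05") does not state an adjustment.

Fold changes are `log2((meanRPM_B + c)/(meanRPM_A + c))` with pseudocount
`c` equal to half a read at the median library depth, expressed in RPM —
keeping presence/absence sites finite while their qualitative flag records
the presence/absence event explicitly. For unreplicated (pooled-material)
designs, a site is differentially methylated when the pseudocounted RPM
ratio is at least 5 in either direction, the assay's published rule.
Direction follows the abundance-methylation inversion: significant decrease
= new methylation, increase = demethylation. A stress-induced change is
reversible when the recovery-vs-control comparison is *not* significant
under the same caller and thresholds.

One simulation design note: validation spikes are modeled as methylation
gains (8-fold abundance loss) — the event class validated by MSRE-qPCR in
the assay's development. This choice also keeps the library-mass shift of
the spikes near 2%, where total-count library sizes remain interpretable.
Spiking strong abundance *gains* into a large site fraction shifts every
null site's conditional rate (composition bias); the exact conditional test
has no size-factor machinery to absorb that, which is a known limitation of
the defined test relative to negative-binomial GLM pipelines.

### Clustering QC and MSRE-qPCR

Sample distances default to `1 - Pearson` on RPM over the union of sites
(scale invariant; range 0-2), clustered by UPGMA; both are configurable
(`euclidean` on `log1p(RPM)` is the alternative metric). Samples are
ordered lexicographically before clustering so the tree is invariant to
input order; trees serialize to newick. On simulated replicate designs the
top bipartition separates conditions before replicates.

MSRE-qPCR validation implements `FC = E^dCp` with
`dCp = Cp_digested - Cp_mock` and `E` the mean amplification efficiency
(an input, `1 < E <= 2`; efficiency estimation from fluorescence curves is
out of scope). With this subtraction order, more surviving template after
digestion (less methylation) gives higher FC; because the convention is
ambiguous in the field, the `E^(-dCp)` view is reported alongside. Group
comparisons use the equal-variance two-sample t-test at `p <= 0.05`, with
`p = 1` by convention for identical zero-variance groups.

## Numerical choices and degenerate inputs

* Exact-test ties: outcomes with probability within a `1 + 1e-7` relative
  factor of the observed outcome count into the tail, the classical exact
  binomial convention; `n = 0` gives `p = 1`.
* `bh_adjust()` delegates to the standard step-up implementation and is
  verified against a brute-force oracle.
* Site identifiers are `"chrom:start0"` with `start0` the 0-based offset of
  the first C of CCGG — one canonical key per palindromic site. All internal
  coordinates are 0-based half-open; GFF3 is converted on read (1-based
  inclusive) and BED written 0-based half-open.
* N bases are allowed in genomes but no recognition site may overlap one.
* Zero library sizes, fragments outside the size window, tags shorter than
  the de novo key, strandless genes, non-symmetric distance matrices and
  zero-variance samples under the correlation metric are all rejected or
  tallied explicitly rather than silently dropped.

## Problem sizes used in the tests

The bundled checks run on synthetic genomes of 40-1,000 planted sites
(up to ~550 kb), 8-30 genome copies per sample, and count-level simulations
of 2,000 sites x 3 replicates (differential recovery) and 10,000 null
sites (type-I error) — sizes chosen so the full suite exercises every
stage end-to-end in about a minute while keeping Monte-Carlo tolerances
tight (binomial 3-sigma bands throughout).

## Known limitations

* Pooled replicate counts: no overdispersion control; biological
  replicate variance beyond Poisson inflates the false-positive rate of
  the exact test relative to its nominal level.
* Composition effects: total-count library sizes assume differential sites
  carry a small fraction of library mass.
* The built-in mapper is exact-match and desk-scale; real genomes need an
  external aligner via SAM.
* Methylation states outside CCGG (CHG/CHH contexts, hemimethylation) are
  invisible to the assay and not modeled.
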