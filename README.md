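# tadtarget

Classifying a transcriptional repressor's **direct** versus **indirect**
target genes by integrating chromatin and transcriptome data inside
topologically associated domains (TADs).

## The problem

When a repressor such as SNAI2 is knocked down in a tumor that fails to
differentiate (e.g. fusion-negative rhabdomyosarcoma), hundreds of genes
go up. Some are *direct* targets — the repressor sat on an enhancer in
their regulatory neighborhood — while others rise *indirectly*,
downstream of a direct target such as MYOG. Distinguishing the two
requires stitching together several genome-scale measurements:

- ChIP-seq peak calls for the repressor in several cell lines, reduced
  to **consensus peaks** supported by at least *k* of *n* lines;
- co-occupancy of the repressor with a lineage activator (e.g. MYOD),
  the Venn of factor-only and shared sites;
- chromatin-state segmentations, summarized as peaks per Gb of each
  state;
- ROSE-style **super-enhancer** calling (stitch peaks within 12.5 kb,
  exclude ±2.5 kb promoter windows, rank by background-subtracted
  signal, cut at the hockey-stick inflection where the min–max-scaled
  rank/signal curve first exceeds slope 1);
- spike-in-normalized signal tracks (**RRPM**, reference-adjusted reads
  per million mapped reads) and knockdown-minus-control **delta
  tracks**;
- TAD-constrained target assignment: a consistently upregulated gene is
  a **direct** target if its TAD contains a consensus repressor peak,
  **indirect** if its TAD is peak-free, **excluded** if its TSS falls in
  a TAD boundary gap.

The package implements each step as a small, tested function on plain
data frames (0-based half-open BED coordinates throughout), plus a
seeded synthetic-data generator with planted ground truth so the whole
chain can be validated end to end, and supporting statistics: BH FDR
correction, grouped Pearson correlation, ΔΔCt fold change, a preranked
running-sum gene-set enrichment statistic (ES/NES with gene-relabeling
permutations), and E-box (CANNTG) motif scanning with a binomial
enrichment test.

## Worked example

Run the full pipeline on the default synthetic study (3 cell lines,
3 × 2 Mb genome, 30 TADs, 300 genes with 30 direct / 100 indirect
planted targets):

```r
library(tadtarget)
cfg <- pipeline_config(simulate = TRUE, sim = sim_config(seed = 1),
                       seed = 1, outdir = "run1")
report <- run_pipeline(cfg)
report
#> <pipeline_report>
#>   consensus peaks (>=k lines): 277 (all lines: 181)
#>   co-occupancy a/b/shared: 110/370/167
#>   enhancers: 170 (79 super, 91 typical)
#>   delta (kd - ctrl): shared 10.732 vs activator-only 0.171
#>   candidates 118 = direct 29 + indirect 89 + excluded 0
#>   enrichment: ES 0.924, NES 2.330, p 0.000999
#>   runtime: 5.0 s -> run1
```

Reading the report: of 300 repressor master peaks dropped into 3 cell
lines at 85 % reproducibility, 277 consensus regions survive the
≥ 2-of-3 filter (181 in all three lines). 167 of them co-occur with an
activator consensus peak; at those shared sites the activator's
spike-in-normalized signal rises by ~10.7 RRPM units upon knockdown
versus ~0.2 at activator-only sites — the planted "activator invades
vacated repressor sites" effect. Of 118 consistently upregulated
myogenic candidates, 29 sit in peak-containing TADs (direct) and 89 in
peak-free TADs (indirect); comparison with the generator's ground truth
gives precision = recall = 1.00 for the direct label. The candidate set
is strongly enriched at the top of the knockdown log2FC ranking
(ES 0.92, nominal p ≈ 0.001 at 1000 permutations).

Individual steps are exported — `consensus_peaks()`,
`classify_cooccupancy()`, `peaks_per_gb()`, `call_super_enhancers()`,
`rrpm_scale()` / `normalize_track()` / `delta_track()`,
`composite_profile()` / `profile_matrix()`, `assign_to_tads()` /
`classify_targets()`, `consistent_upregulated()`,
`preranked_enrichment()`, `scan_ebox()` / `ebox_enrichment()` — see the
vignette in `vignettes/tadtarget-methods.Rmd` for the model behind each.
A thin command-line front end lives in `inst/scripts/tadtarget.R`
(`simulate`, `run`, `version` subcommands).

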