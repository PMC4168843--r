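# barcodegap

Tools for asking, of a candidate DNA barcode locus: *would it actually
separate species?* — with scleractinian corals, where the canonical COI
barcode is nearly invariant, as the motivating case.

The package implements an evaluation pipeline in three parts, plus the
simulator that makes every part testable offline:

1. **Divergence scan.** Given two aligned congeneric mitochondrial
   genomes and a region annotation (BED/GFF), compute a sliding-window
   Kimura 2-parameter (K2P) divergence track (default 500-bp windows
   every 25 bp) and rank the annotated coding regions by divergence.
   In *Agaricia*, this is the analysis that nominates cytochrome b
   (~2.4% divergence) over COI (~1.6%).
2. **Barcode-gap analysis.** Given a labeled alignment of candidate
   locus sequences across many genera, parse taxonomy from the labels
   (including `sp.`, `cf.`, `aff.` qualifiers, which demote a sequence
   to genus-level comparability), classify every pairwise K2P distance
   as intraspecific / intrageneric / other, and summarize the three
   distributions: counts, order statistics, reflected Gaussian kernel
   densities (display-truncated at 0.05), and an *overlap fraction* —
   the share of non-conspecific contrasts falling inside the
   intraspecific range. No gap ⇒ no single-locus barcoding.
3. **Neighbor-joining tree** of the same K2P matrix (Saitou–Nei
   agglomeration with documented tie-breaking and negative-branch
   clamping), written as Newick.

The K2P distance, from transition proportion *P* (A↔G, C↔T) and
transversion proportion *Q* over the *n* sites comparable in a pair
(pairwise deletion of gaps/ambiguities):

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

Saturated pairs (non-positive log argument) carry an `Inf` sentinel and
a flag; pairs with fewer than `min_sites` comparable sites (default
100) are *missing*, not zero. Every run reconciles
`intraspecific + intrageneric + other + missing + skipped = N(N-1)/2`.

## Worked example

The analysis scripts under `analysis/` run the whole study on
simulated data (each is a thin driver over package functions; run them
in order from the repository root):

```sh
Rscript analysis/01_simulate.R     # genome pair + survey alignment
Rscript analysis/02_genome_scan.R  # window track + region ranking
Rscript analysis/03_barcode_gap.R  # contrasts + densities + summary
Rscript analysis/04_nj_tree.R      # Newick tree
```

which prints, step by step:

```
genome pair: 18667 nt, 10 annotated regions -> results/simulated/genome_pair.fasta
barcode survey: 360 sequences (40 genera), truth for 64620 pairs -> results/simulated/barcode_survey.fasta
top coding region: cob [11573, 12786) with d_region = 0.0260 (window mean 0.0288) over 1213 sites
alignment: 360 sequences x 800 columns
contrasts: 342 intraspecific, 1098 intrageneric, 63180 other (of 64620 pairs; 0 missing, 0 saturated, 0 skipped)
intraspecific K2P: median 0.0050, max 0.0113; overlap fraction 0.0003
neighbor-joining tree: 360 tips, total branch length 3.775 -> results/nj_tree/nj_tree.nwk
```

Reading the numbers: the simulated genome pair encodes a coding
baseline of 1.6% divergence with cytochrome b (`cob`) elevated to an
expected 2.4%, and the scan duly ranks `cob` first (here at 0.026 — a
1.2-kb region carries sampling noise of a few thousandths). The
simulated survey has well-separated strata (expected depths
0.005 / 0.03 / 0.10), so the overlap fraction is ~0 — a clean barcode
gap, which is exactly what the *real* coral survey does **not** show.
The same three drivers accept real inputs (`--alignment`, `--format
nexus`, etc.); every output directory gets a `manifest.json` recording
parameters, seeds and input checksums.

Interactively:

```r
library(barcodegap)
k2p_distance(list(n = 100, ts = 10, tv = 5))
#> [1] 0.1701812

cfg <- sim_config(seed = 42)
gp  <- simulate_genome_pair(cfg)
rd  <- region_divergence(gp$alignment, regions = gp$regions)
head(rank_regions(rd)[, c("name", "n", "d_region")], 3)
#>   name    n   d_region
#> 1  cob 1213 0.03296940
#> 2 nad5 1867 0.01954262
#> 3 nad2 1494 0.01900048
```

See `vignettes/barcode-locus-evaluation.Rmd` for the model, parameter
and design details.

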