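---
title: "Evaluating candidate barcode loci: divergence scans and distance contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating candidate barcode loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

DNA barcoding identifies species from a short, standardized gene region.
It works when a "barcode gap" exists: the distribution of genetic
distances between conspecific sequences is separated from the
distribution of distances between different species. In scleractinian
corals the canonical metazoan barcode, mitochondrial COI, is nearly
invariant, so the question becomes whether any other mitochondrial
region does better. This package implements the two analyses that
question requires:

1. **a divergence scan** — given two aligned congeneric mitochondrial
   genomes, compute a sliding-window track of Kimura 2-parameter (K2P)
   divergence and rank annotated coding regions by divergence, to
   nominate a candidate locus (in *Agaricia*, cytochrome b, at roughly
   2.4% divergence against roughly 1.6% for COI);
2. **a barcode-gap analysis** — given a labeled alignment of candidate
   locus sequences across many genera, classify every pairwise K2P
   distance as intraspecific, intrageneric (congeneric excluding
   conspecific) or other, and compare the three distributions.

A neighbor-joining tree of the same distance matrix provides the
accompanying phylogeny, and a K2P simulator generates both kinds of
input so that the whole pipeline is testable without any downloads.

## The K2P distance and its bookkeeping

For an aligned sequence pair, a column is *comparable* only when both
characters are unambiguous nucleotides; gaps, `?`, `N` and IUPAC
ambiguity codes are excluded per pair (pairwise deletion, not complete
deletion — survey alignments built from GenBank "reads" are ragged, and
complete deletion would discard most of the data). With `n` comparable
sites, transition proportion $P$ (A↔G, C↔T) and transversion proportion
$Q$, the K2P distance is

$$ d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q). $$

Two failure modes are kept distinct by design:

* **saturation** — when $1-2P-Q \le 0$ or $1-2Q \le 0$ the multiple-hit
  correction is undefined; the pair gets an `Inf` sentinel and a
  `saturated` flag rather than raising, so one saturated pair cannot
  abort a 360-sequence matrix. Saturated pairs count in totals but are
  excluded from order statistics and densities.
* **insufficient overlap** — pairs with fewer than `min_sites`
  comparable sites (default 100, configurable everywhere it matters)
  are recorded as *missing*, not zero: two short reads overlapping a
  few dozen sites give wild distances. The threshold is reported in
  every output.

Every barcode run asserts the bookkeeping identity
`intraspecific + intrageneric + other + missing + skipped = N(N-1)/2`
(saturated pairs are inside their category counts).

```{r k2p}
k2p_distance(list(n = 100, ts = 10, tv = 5))
```

## The divergence scan

Windows are defined on alignment columns (default 500 columns every 25,
the usual mitogenome-scan resolution), because gap columns cannot be
assigned to a single genome's coordinate frame; gaps simply never count
as comparable sites. If the final full window stops short of the end,
one short window is appended and flagged `partial`, so the track covers
the whole alignment; circular wrap-around windows are *not* generated —
the choice is recorded in the output metadata, and nothing downstream
assumes circularity.

Per region we report two statistics, because "mean divergence of a
region" is used in both senses in the literature: `d_region`, a single
K2P computation over exactly the region's columns (the headline number;
site counts are additive, so this is the count-weighted aggregate), and
`mean_window_d`, the mean of fully-contained window distances. Ranking
uses `d_region`, descending, ties broken by start coordinate, and by
default keeps only coding regions — the candidates on which conserved
primers could be designed.

```{r scan}
cfg <- sim_config(seed = 42)
gp <- simulate_genome_pair(cfg)
rd <- region_divergence(gp$alignment, regions = gp$regions)
rank_regions(rd)[, c("name", "category", "n", "d_region", "mean_window_d")]
```

## Taxonomy from labels, and the three strata

GenBank-derived labels mix taxonomy with accessions
(`Agaricia_fragilis_KM051016`, `Discosoma sp.`, `Pavona_cf._varians`).
The parser takes the first alphabetic token as the genus and the next
as the epithet, unless that token is a qualifier: `sp.` (identified to
genus only) or `cf.`/`aff.` (uncertain identification, treated
identically). Tokens containing digits are treated as accession
material and retained only in the raw label. Matching is
case-insensitive; labels are stored verbatim.

Classification then follows one rule: a pair is **intraspecific** only
if the genera match, both epithets are present and match, and *neither*
name carries a qualifier; qualified or genus-only sequences are
comparable at the genus level, so their congeneric pairs land in
**intrageneric**; different genera are **other**. This is deliberately
conservative — an underdescribed `Discosoma sp.` may or may not be
conspecific with *Discosoma nummiforme*, so the pair must not inflate
the intraspecific distribution.

## Distribution summaries

Counts, minima, maxima, means and medians are computed over all finite
distances. Densities are Gaussian KDEs with Silverman's rule-of-thumb
bandwidth (configurable), *reflected at* $d = 0$ so no mass leaks below
zero — distances are non-negative and the intraspecific stratum piles
up near 0, where an unreflected kernel would lose up to half its mass.
The display grid is truncated (default 0.05, where the intraspecific
and nearly all intrageneric contrasts live); truncation affects only
the exported grid, never a statistic. When a category's distances are
all equal the KDE degenerates; a narrow fixed fallback bandwidth
(1e-4) renders the point mass as a tight spike rather than erroring.

The qualitative failure of a barcode gap is made quantitative by the
**overlap fraction**: the proportion of intrageneric + other contrasts
whose distance does not exceed the intraspecific maximum. A usable
barcode locus gives ~0.

## Neighbor joining

The tree is the standard Saitou–Nei agglomeration, joining the pair
minimizing $Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$ with the two-point
branch-length formulas, ties broken by the smallest node-index pair
(input order, then creation order) so results are reproducible.
Negative branch lengths, which arise on non-additive matrices, are by
default clamped to zero with the deficit moved to the sister branch so
the joined pair's path length is preserved; the clamp is toggleable for
consumers that accept negatives. NJ requires a complete matrix;
`drop_incomplete()` implements the documented pruning policy (greedily
drop the sequence with the most missing/saturated distances until the
matrix is complete, reporting what was dropped). On any additive matrix
the output tree reproduces the input path distances exactly — the
round-trip against random additive matrices is the suite's oracle,
since a published tree cannot be byte-reproduced without the original
data and the original program's tie-breaking.

## The simulator: what it emulates, and what it does not

`simulate_genome_pair()` draws a uniform ancestor and evolves two
descendants site-independently with the *exact* K2P
transition-probability matrix at the target branch length (not a
Poisson-event approximation), so expected divergences are analytic and
recovery tests can be tight. A site in region $r$ gets branch length
`base_divergence * relative_rate(r) / 2` per descendant. The default
region map mimics a coral mitogenome: 18,667 nt; coding baseline 1.6%
divergence; cytochrome b at 1.5× (2.4% expected); ribosomal RNAs at
0.6×; a non-coding control region at 3× — the configuration in which a
scan should, and does, nominate cytochrome b. With per-region
divergences this close together and regions ~1.2–1.7 kb long, sampling
noise occasionally reorders the top ranks across replicates; that is a
property of the biology being emulated, and the recovery guarantee is
therefore stated (and tested) for a clearly elevated region (10×
rate), where the top rank is stable in ≥95% of replicates.

`simulate_barcode_set()` evolves sequences down a two-level taxonomy
(genus ancestors, species ancestors, replicate sequences) with branch
lengths chosen so the *expected pairwise* K2P distances of the three
strata equal the configured depths — K2P distances are additive along
branches, which makes that calibration exact. Defaults: 40 genera × 3
species × 3 sequences (360 sequences, the scale of the published
cytochrome b survey of 361), locus 800 nt, depths 0.005 / 0.03 / 0.10,
κ = 2 (a generic mtDNA-like transition:transversion rate ratio; no
value is fixed by the motivating study), and 5% of species relabeled
with `sp.`/`cf.` qualifiers so the parser and the demotion rule are
exercised end to end. Ground truth for every pair is returned, and at
`qualifier_fraction = 0` the pipeline's classification reproduces it
exactly (the "pipeline closure" test).

What the simulator does **not** emulate: indels and alignment error
(gaps enter fixtures only by explicit masking), rate variation among
sites within a region, base-composition bias (the K2P model assumes
equal base frequencies), ragged taxon sampling (real surveys have very
uneven species/genus sizes), misidentified sequences, and recombination
or heteroplasmy. Passing tests therefore demonstrate the *methods* are
correct under their stated model, not that real coral data are as
clean; in particular the real survey's strata overlap far more than
the well-separated default depths do.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; BED/GFF
  conventions are converted at the file boundary only.
* Whether the original survey's distance run used pairwise or complete
  deletion is not documented; pairwise deletion is this package's
  stated default, and the minimum-overlap threshold is exposed because
  the choice matters for partial reads.
* U→T normalization lets RNA-coded records compare against DNA; inputs
  are assumed co-oriented (an alignment implies orientation), so no
  reverse-complementing is attempted.
* The saturation sentinel is `Inf`, distinct from `NA` (missing):
  saturation is information (the pair is very divergent), missingness
  is not.
* Simulation problem sizes used by the test-suite recovery studies —
  100 replicates of 18-kb genome pairs for the scan, 30 replicates of a
  36-sequence survey for stratum recovery, 100 random 5–12-taxon
  additive matrices for NJ — were chosen so each study completes in
  seconds to a couple of minutes while leaving standard errors tight
  enough for 2-SE recovery checks.

## Known limitations

* Only the K2P model is implemented (no JC69/GTR, no gamma rates, no
  ML distances): the pipeline's contract is to reproduce a K2P-based
  protocol, not to be a general distance toolbox.
* `read_nexus_alignment()` parses the DATA/CHARACTERS matrix dialects
  common in survey supplements (sequential and interleaved, quoted
  labels, comments); it is not a full NEXUS implementation.
* The label parser encodes one schema (genus, optional qualifier,
  optional epithet, trailing accession tokens). Labels outside it are
  skipped and reported, never guessed.
* Published counts from any specific survey depend on that survey's
  exact label conventions; a handful of qualifier-labeled taxa can move
  single pairs between strata, so small count differences against a
  publication are expected and the bookkeeping is reported
  transparently instead of forced.
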