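#!/usr/bin/env Rscript

# Step 4 — neighbor-joining phylogeny of the survey sequences.
#
# Rebuilds the K2P distance matrix from the barcode alignment, drops
# the minimal set of sequences with missing/saturated distances (none,
# for the simulated survey), runs neighbor joining and writes Newick.

suppressMessages({
  library(optparse)
  library(barcodegap)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--alignment", type = "character",
              default = "results/simulated/barcode_survey.fasta"),
  make_option("--format", type = "character", default = "fasta"),
  make_option("--out_dir", type = "character", default = "results/nj_tree"),
  make_option("--min_overlap", type = "integer", default = 100L),
  make_option("--no_clamp_negative", action = "store_true", default = FALSE)
)))

aln <- switch(opts$format,
              fasta = read_fasta(opts$alignment),
              nexus = read_nexus_alignment(opts$alignment),
              stop("--format must be fasta or nexus"))
dmat <- pairwise_distance_matrix(aln, min_sites = opts$min_overlap)
pruned <- drop_incomplete(dmat)
if (length(pruned$dropped)) {
  message(sprintf("dropped %d sequence(s) with incomplete distances: %s",
                  length(pruned$dropped),
                  paste(pruned$dropped, collapse = ", ")))
}
if (nrow(pruned$d) < 3L) stop("fewer than 3 sequences with complete distances")

tree <- neighbor_joining(pruned$d,
                         clamp_negative = !opts$no_clamp_negative)

dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
newick <- file.path(opts$out_dir, "nj_tree.nwk")
dropped_tsv <- file.path(opts$out_dir, "dropped_sequences.tsv")
write_newick(tree, newick)
write_tsv(data.frame(label = if (length(pruned$dropped)) pruned$dropped
                     else character(0)), dropped_tsv)

message(sprintf("neighbor-joining tree: %d tips, total branch length %.3f -> %s",
                length(tree$tip.label), sum(tree$edge.length), newick))

write_run_manifest(
  opts$out_dir, "tree",
  parameters = list(min_overlap = opts$min_overlap,
                    clamp_negative = !opts$no_clamp_negative),
  inputs = opts$alignment,
  outputs = c(newick, dropped_tsv)
)
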