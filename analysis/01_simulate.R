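#!/usr/bin/env Rscript

# Step 1 — generate the study inputs.
#
# Two fixtures, written under results/simulated/:
#   * an aligned mitochondrial genome pair (FASTA) with its region map
#     (BED): 18,667 nt, protein-coding baseline divergence 1.6%, with
#     cytochrome b elevated to an expected 2.4% and a fast non-coding
#     control region — the configuration the divergence scan is meant
#     to detect;
#   * a survey-scale cytochrome b barcode alignment (FASTA): 40 genera
#     x 3 species x 3 sequences at expected K2P depths 0.005 / 0.03 /
#     0.10, with a few species labeled 'sp.'/'cf.', plus the
#     ground-truth pair classification (TSV).

suppressMessages({
  library(optparse)
  library(barcodegap)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20260925L),
  make_option("--out_dir", type = "character", default = "results/simulated")
)))

dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = opts$seed)

gp <- simulate_genome_pair(cfg)
fa_genomes <- file.path(opts$out_dir, "genome_pair.fasta")
bed_regions <- file.path(opts$out_dir, "genome_pair_regions.bed")
write_fasta(gp$alignment, fa_genomes)
write_regions(gp$regions[c("name", "start", "end", "category")], bed_regions)
message(sprintf("genome pair: %d nt, %d annotated regions -> %s",
                gp$alignment$width, nrow(gp$regions), fa_genomes))

bs <- simulate_barcode_set(cfg)
fa_barcode <- file.path(opts$out_dir, "barcode_survey.fasta")
truth_tsv <- file.path(opts$out_dir, "barcode_survey_truth.tsv")
write_fasta(bs$alignment, fa_barcode)
write_tsv(bs$truth, truth_tsv)
message(sprintf("barcode survey: %d sequences (%d genera), truth for %d pairs -> %s",
                bs$alignment$n, length(unique(bs$taxonomy$genus)),
                nrow(bs$truth), fa_barcode))

write_run_manifest(
  opts$out_dir, "simulate",
  parameters = cfg[setdiff(names(cfg), "regions")],
  outputs = c(fa_genomes, bed_regions, fa_barcode, truth_tsv),
  seed = opts$seed
)
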