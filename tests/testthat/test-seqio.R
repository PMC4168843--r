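test_that("FASTA records are parsed in order, normalized, and shape-checked", {
  p <- write_tmp(c(">a", "ACGT", ">b", "AC-T"), ".fasta")
  aln <- read_fasta(p)
  expect_s3_class(aln, "seq_alignment")
  expect_equal(aln$labels, c("a", "b"))
  expect_equal(aln$n, 2L)
  expect_equal(aln$width, 4L)

  p2 <- write_tmp(c(">a", "acgu"), ".fasta")
  expect_equal(unname(read_fasta(p2, as_alignment = FALSE)), "ACGT")

  p3 <- write_tmp(c(">a", "ACGT", ">b", "ACG"), ".fasta")
  expect_error(read_fasta(p3), "length")

  p4 <- write_tmp(character(0), ".fasta")
  expect_error(read_fasta(p4), "empty|malformed")
})

test_that("FASTA write/read round-trip preserves labels, sequences, shape", {
  set.seed(11)
  aln <- random_alignment(5, 83, gap_p = 0.05, amb_p = 0.02)
  p <- tempfile(fileext = ".fasta")
  write_fasta(aln, p)
  back <- read_fasta(p)
  expect_equal(back$labels, aln$labels)
  expect_equal(back$seqs, aln$seqs)
})

test_that("sequential NEXUS matrix is parsed", {
  p <- write_tmp(c(
    "#NEXUS",
    "BEGIN DATA;",
    "DIMENSIONS NTAX=2 NCHAR=8;",
    "FORMAT DATATYPE=DNA MISSING=? GAP=-;",
    "MATRIX",
    "taxA ACGTACGT",
    "taxB ACG-AC?T",
    ";",
    "END;"), ".nex")
  aln <- read_nexus_alignment(p)
  expect_equal(aln$n, 2L)
  expect_equal(aln$width, 8L)
  expect_equal(aln$seqs, c("ACGTACGT", "ACG-AC?T"))
})

test_that("interleaved NEXUS concatenates per-taxon rows, matching ape", {
  p <- write_tmp(c(
    "#NEXUS",
    "BEGIN DATA;",
    "DIMENSIONS NTAX=3 NCHAR=12;",
    "FORMAT DATATYPE=DNA GAP=- INTERLEAVE=YES;",
    "MATRIX",
    "taxA ACGTAC",
    "taxB AC-TAC",
    "taxC ACGTTT",
    "",
    "taxA GGTTAA",
    "taxB GGTTAA",
    "taxC GG--AA",
    ";",
    "END;"), ".nex")
  aln <- read_nexus_alignment(p)
  expect_equal(aln$width, 12L)
  expect_equal(aln$seqs[1], "ACGTACGGTTAA")
  # independent parser on the same fixture
  ref <- ape::read.nexus.data(p)
  expect_equal(aln$labels, names(ref))
  expect_equal(aln$seqs,
               unname(toupper(vapply(ref, paste, character(1), collapse = ""))))
})

test_that("quoted NEXUS taxon labels are preserved verbatim minus quotes", {
  p <- write_tmp(c(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    "DIMENSIONS NCHAR=4;",
    "MATRIX",
    "'Agaricia fragilis' ACGT",
    "taxB               ACGA",
    ";",
    "END;"), ".nex")
  aln <- read_nexus_alignment(p)
  expect_equal(aln$labels[1], "Agaricia fragilis")
})

test_that("NEXUS without a matrix block is a format error", {
  p <- write_tmp(c("#NEXUS", "BEGIN TREES;", "END;"), ".nex")
  expect_error(read_nexus_alignment(p), "block")
})

test_that("taxon labels parse into genus/epithet/qualifier", {
  t1 <- parse_taxon_label("Agaricia_fragilis_KM051016")
  expect_equal(t1$genus, "Agaricia")
  expect_equal(t1$epithet, "fragilis")
  expect_equal(t1$qualifier, "none")

  t2 <- parse_taxon_label("Discosoma sp.")
  expect_equal(t2$genus, "Discosoma")
  expect_true(is.na(t2$epithet))
  expect_equal(t2$qualifier, "sp")

  t3 <- parse_taxon_label("Pavona_cf._varians")
  expect_equal(t3$genus, "Pavona")
  expect_equal(t3$epithet, "varians")
  expect_equal(t3$qualifier, "cf")

  t4 <- parse_taxon_label("Leptoseris_aff._scabra_JX123456")
  expect_equal(t4$qualifier, "aff")
  expect_equal(t4$epithet, "scabra")

  # genus-only label with accession: no epithet, no qualifier
  t5 <- parse_taxon_label("Agaricia_KM051016")
  expect_true(is.na(t5$epithet))
  expect_equal(t5$qualifier, "none")

  expect_error(parse_taxon_label("12345_678"), "alphabetic")
  expect_error(parse_taxon_label(""), "non-empty")
})

test_that("label parsing is deterministic and total on alphabetic labels", {
  set.seed(42)
  genera <- c("Agaricia", "Pavona", "Discosoma", "Leptoseris")
  quals <- c("", "sp.", "cf.", "aff.")
  for (i in 1:50) {
    g <- sample(genera, 1)
    q <- sample(quals, 1)
    ep <- if (q == "sp.") "" else sample(c("fragilis", "varians", ""), 1)
    sep <- sample(c("_", " "), 1)
    toks <- c(g, q, ep, sprintf("KM%06d", sample.int(999999, 1)))
    lab <- paste(toks[nzchar(toks)], collapse = sep)
    a <- parse_taxon_label(lab)
    b <- parse_taxon_label(lab)
    expect_identical(a, b)
    expect_equal(a$genus, g)
    expect_equal(a$raw_label, lab)
  }
})

test_that("BED and GFF intervals convert to 0-based half-open", {
  pb <- write_tmp("chrM\t100\t600\tCYB", ".bed")
  rb <- read_regions(pb)
  expect_equal(rb$start, 100L)
  expect_equal(rb$end, 600L)
  expect_equal(rb$category, "coding")

  pg <- write_tmp(c("##gff-version 3",
                    "chrM\tx\tgene\t101\t600\t.\t+\t.\tID=CYB;Name=CYB"),
                  ".gff3")
  rg <- read_regions(pg)
  expect_equal(rg$start, 100L)
  expect_equal(rg$end, 600L)

  expect_error(read_regions(write_tmp("chrM\t600\t600\tCYB", ".bed")),
               "interval")
  expect_error(read_regions(pb, seq_length = 500), "exceed")
})

test_that("region coordinate conversion is involutive", {
  regions <- data.frame(name = c("cox1", "rnl", "CR"),
                        start = c(0L, 300L, 900L),
                        end = c(250L, 700L, 1000L),
                        category = c("coding", "ribosomal", "other"))
  for (fmt in c("bed", "gff")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_regions(regions, p, format = fmt)
    back <- read_regions(p, format = fmt)
    expect_equal(back[c("name", "start", "end", "category")], regions,
                 ignore_attr = TRUE)
  }
})

test_that("region categories fall back to name/type inference", {
  p <- write_tmp(c("chrM\t0\t100\trnl", "chrM\t100\t200\tnad5",
                   "chrM\t200\t300\tmysteryORF"), ".bed")
  r <- read_regions(p)
  expect_equal(r$category, c("ribosomal", "coding", "other"))
  r2 <- read_regions(p, categories = c(mysteryORF = "coding"))
  expect_equal(r2$category[3], "coding")
})

test_that("newick output quotes labels and round-trips through a re-parse", {
  star <- ape::read.tree(text = "(a:1,b:2,c:3);")
  p <- tempfile(fileext = ".nwk")
  write_newick(star, p)
  back <- ape::read.tree(p)
  expect_equal(sort(back$tip.label), c("a", "b", "c"))
  expect_equal(sort(back$edge.length), c(1, 2, 3))

  sp <- ape::read.tree(text = "('Discosoma sp.':0.1,b:0.2,c:0.3);")
  p2 <- tempfile(fileext = ".nwk")
  write_newick(sp, p2)
  expect_match(readLines(p2), "'Discosoma sp.'", fixed = TRUE)
  back2 <- ape::read.tree(p2)
  # ape keeps the protective quotes on the label; strip them to compare
  expect_true("Discosoma sp." %in% gsub("^'|'$", "", back2$tip.label))

  dup <- star
  dup$tip.label <- c("a", "a", "c")
  expect_error(write_newick(dup, tempfile()), "duplicate")
})
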