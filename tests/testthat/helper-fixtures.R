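# in-code fixtures shared across test files

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random gapped alignment; gap_p/amb_p inject '-' and 'N'
random_alignment <- function(n_seq, width, gap_p = 0, amb_p = 0,
                             labels = sprintf("seq%02d", seq_len(n_seq))) {
  seqs <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    if (gap_p > 0) chars[stats::runif(width) < gap_p] <- "-"
    if (amb_p > 0) chars[stats::runif(width) < amb_p] <- "N"
    paste(chars, collapse = "")
  }, character(1L))
  seq_alignment(labels, seqs)
}

# independently coded closed-form K2P, used as the oracle throughout
k2p_oracle <- function(ts, tv, n) {
  P <- ts / n
  Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(Inf)
  -log(1 - 2 * P - Q) / 2 - log(1 - 2 * Q) / 4
}

# random tree with strictly positive branch lengths and its additive
# path-distance matrix
random_additive_matrix <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 0.5))
  tree <- ape::unroot(tree)
  list(tree = tree, d = stats::cophenetic(tree))
}

# related sequences: a shared base with per-sequence point mutations, so
# pairwise divergences stay well inside the K2P log domain
related_alignment <- function(n_seq, width, mutate = 0.03, gap_p = 0,
                              labels = sprintf("seq%02d", seq_len(n_seq))) {
  base <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- base
    k <- max(1L, round(mutate * width))
    pos <- sample(width, k)
    s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    if (gap_p > 0) s[stats::runif(width) < gap_p] <- "-"
    paste(s, collapse = "")
  }, character(1L))
  seq_alignment(labels, seqs)
}

taxon <- function(label) parse_taxon_label(label)
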