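#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators.
#' Defaults describe a coral-like mitochondrial comparison: an
#' 18,667-nt genome whose protein-coding regions sit near 1.6%
#' divergence with cytochrome b elevated to 2.4%, ribosomal RNAs more
#' conserved and a fast non-coding control region; and a barcode study
#' of 40 genera x 3 species x 3 sequences (360 sequences, close to the
#' 361-sequence survey scale) with expected K2P depths of 0.005 within
#' species, 0.03 within genera and 0.10 between genera.
#'
#' @param seed integer seed; every generator call is deterministic given
#'   the config.
#' @param genome_length alignment length of the simulated genome pair.
#' @param regions `data.frame` with `name`, `start`, `end`, `category`,
#'   `relative_rate`; sites outside any region evolve at relative rate 1.
#' @param base_divergence expected total (tip-to-tip) substitutions/site
#'   at relative rate 1.
#' @param kappa transition/transversion rate ratio of the K2P process
#'   (default 2, a generic mtDNA-like value).
#' @param n_genera,species_per_genus,seqs_per_species taxonomy shape of
#'   the barcode set.
#' @param depth_within_species,depth_within_genus,depth_between_genus
#'   expected pairwise K2P distances of the three strata (must be
#'   non-decreasing).
#' @param locus_length barcode locus length in nt.
#' @param qualifier_fraction fraction of species whose labels are
#'   rewritten with an uncertainty qualifier (`sp.` or `cf.`).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 18667L,
                       regions = NULL,
                       base_divergence = 0.016,
                       kappa = 2,
                       n_genera = 40L,
                       species_per_genus = 3L,
                       seqs_per_species = 3L,
                       depth_within_species = 0.005,
                       depth_within_genus = 0.03,
                       depth_between_genus = 0.10,
                       locus_length = 800L,
                       qualifier_fraction = 0.05) {
  if (is.null(regions)) regions <- default_mito_regions(genome_length)
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    genome_length >= 1L, locus_length >= 1L,
    base_divergence >= 0, kappa > 0,
    n_genera >= 1L, species_per_genus >= 1L, seqs_per_species >= 1L,
    depth_within_species >= 0,
    qualifier_fraction >= 0, qualifier_fraction <= 1
  )
  if (!(depth_within_species <= depth_within_genus &&
        depth_within_genus <= depth_between_genus)) {
    stop("stratum depths must be ordered: within-species <= within-genus ",
         "<= between-genus", call. = FALSE)
  }
  if (n_genera * species_per_genus * seqs_per_species < 2L) {
    stop("taxonomy must yield at least 2 sequences", call. = FALSE)
  }
  req <- c("name", "start", "end", "category", "relative_rate")
  if (!all(req %in% names(regions))) {
    stop("regions must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(regions$relative_rate <= 0)) {
    stop("relative_rate must be > 0", call. = FALSE)
  }
  if (any(regions$start < 0L) || any(regions$end > genome_length) ||
      any(regions$start >= regions$end)) {
    stop("region intervals must satisfy 0 <= start < end <= genome_length",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         regions = regions, base_divergence = base_divergence, kappa = kappa,
         n_genera = as.integer(n_genera),
         species_per_genus = as.integer(species_per_genus),
         seqs_per_species = as.integer(seqs_per_species),
         depth_within_species = depth_within_species,
         depth_within_genus = depth_within_genus,
         depth_between_genus = depth_between_genus,
         locus_length = as.integer(locus_length),
         qualifier_fraction = qualifier_fraction),
    class = "sim_config"
  )
}

#' Default region map for a simulated coral-like mitogenome
#'
#' A compact annotation in the spirit of the scleractinian SII gene
#' order: large protein-coding regions at baseline rate, two ribosomal
#' RNAs at a reduced rate, cytochrome b at 1.5x baseline (so 2.4%
#' expected divergence at the 1.6% baseline) and a fast non-coding
#' control region.
#'
#' @param genome_length total length; region intervals are scaled to it.
#' @return regions `data.frame` with `relative_rate` column.
#' @export
default_mito_regions <- function(genome_length = 18667L) {
  # fractions of the genome, loosely modeled on a coral mitogenome map
  spec <- data.frame(
    name = c("rnl", "nad5", "nad1", "cox1", "rns", "cox3",
             "nad2", "cob", "nad4", "CR"),
    f_start = c(0.01, 0.08, 0.20, 0.27, 0.38, 0.44,
                0.52, 0.62, 0.70, 0.82),
    f_end = c(0.07, 0.18, 0.26, 0.36, 0.43, 0.50,
              0.60, 0.685, 0.78, 0.92),
    category = c("ribosomal", "coding", "coding", "coding", "ribosomal",
                 "coding", "coding", "coding", "coding", "other"),
    relative_rate = c(0.6, 1.0, 0.9, 1.0, 0.6, 0.9, 1.0, 1.5, 0.9, 3.0),
    stringsAsFactors = FALSE
  )
  data.frame(
    name = spec$name,
    start = as.integer(floor(spec$f_start * genome_length)),
    end = as.integer(floor(spec$f_end * genome_length)),
    category = spec$category,
    relative_rate = spec$relative_rate,
    stringsAsFactors = FALSE
  )
}

# Evolve an integer-coded sequence for K2P branch length d (may be a
# per-site vector). Substitutions are drawn per site from the exact K2P
# transition-probability matrix, so expected distances are analytic:
#   p_ts      = 1/4 + 1/4 e2 - 1/2 e1
#   p_tv each = 1/4 - 1/4 e2
# with e1 = exp(-2(a+b)d), e2 = exp(-4bd), a = kappa/(kappa+2),
# b = 1/(kappa+2) (rates normalized so a + 2b = 1 substitution/site).
evolve_k2p <- function(seq_int, d, kappa = 2) {
  L <- length(seq_int)
  if (length(d) == 1L) d <- rep(d, L)
  stopifnot(length(d) == L, all(is.finite(d)), all(d >= 0))
  a <- kappa / (kappa + 2)
  b <- 1 / (kappa + 2)
  e1 <- exp(-2 * (a + b) * d)
  e2 <- exp(-4 * b * d)
  p_ts <- 0.25 + 0.25 * e2 - 0.5 * e1
  p_tv <- 0.25 - 0.25 * e2
  u <- stats::runif(L)
  ts_map <- c(3L, 4L, 1L, 2L)
  tv1_map <- c(2L, 1L, 2L, 1L)
  tv2_map <- c(4L, 3L, 4L, 3L)
  out <- seq_int
  is_ts <- u < p_ts
  is_tv1 <- !is_ts & u < p_ts + p_tv
  is_tv2 <- !is_ts & !is_tv1 & u < p_ts + 2 * p_tv
  out[is_ts] <- ts_map[seq_int[is_ts]]
  out[is_tv1] <- tv1_map[seq_int[is_tv1]]
  out[is_tv2] <- tv2_map[seq_int[is_tv2]]
  out
}

#' Simulate a two-genome alignment with region-specific divergence
#'
#' Draws a uniform-random ancestor and evolves two descendants
#' independently under a K2P process in which a site in region `r`
#' accumulates an expected `base_divergence * relative_rate(r) / 2`
#' substitutions/site on each branch (so the expected pairwise
#' divergence of the region is `base_divergence * relative_rate(r)`).
#' Substitutions are placed site-independently from the exact K2P
#' transition probabilities. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `alignment` (2-record `seq_alignment`, labels
#'   `genomeA`/`genomeB`), `regions` (the config's regions), `site_rate`
#'   (per-site relative rate vector) and `config`.
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  rate <- rep(1, L)
  for (r in seq_len(nrow(config$regions))) {
    rate[(config$regions$start[r] + 1L):config$regions$end[r]] <-
      config$regions$relative_rate[r]
  }
  branch_d <- config$base_divergence * rate / 2
  anc <- sample.int(4L, L, replace = TRUE)
  g1 <- evolve_k2p(anc, branch_d, config$kappa)
  g2 <- evolve_k2p(anc, branch_d, config$kappa)
  aln <- seq_alignment(c("genomeA", "genomeB"),
                       c(decode_sequence(g1), decode_sequence(g2)))
  list(alignment = aln, regions = config$regions, site_rate = rate,
       config = config)
}

#' Simulate a labeled multi-genus barcode alignment
#'
#' Evolves sequences down a two-level taxonomy: genus ancestors at
#' depth `(depth_between_genus - depth_within_genus) / 2` from the
#' root-level pool, species ancestors at
#' `(depth_within_genus - depth_within_species) / 2` below their genus,
#' and sequences at `depth_within_species / 2` below their species, so
#' the expected pairwise K2P distances of the three strata equal the
#' configured depths (K2P distances are additive along branches).
#'
#' Labels follow the GenBank-like pattern `Genus_species_ACC#####`. A
#' `qualifier_fraction` of species are relabeled with an uncertainty
#' qualifier — alternately `Genus_sp._ACC#####` (identified to genus
#' only) and `Genus_cf._species_ACC#####` (uncertain identification) —
#' which downstream classification must demote to the genus level. The
#' ground-truth category of every unordered pair (with that demotion
#' applied) is returned alongside.
#'
#' @param config a [sim_config()].
#' @return list with `alignment` (a `seq_alignment`), `taxonomy`
#'   (`data.frame`: `label`, `genus`, `species`, `qualifier`,
#'   `accession`), `truth` (`data.frame`: `labelA`, `labelB`,
#'   `category`) and `config`.
#' @export
simulate_barcode_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  G <- config$n_genera
  S <- config$species_per_genus
  K <- config$seqs_per_species
  L <- config$locus_length
  kappa <- config$kappa
  b_genus <- (config$depth_between_genus - config$depth_within_genus) / 2
  b_species <- (config$depth_within_genus - config$depth_within_species) / 2
  b_seq <- config$depth_within_species / 2

  root <- sample.int(4L, L, replace = TRUE)
  n_species <- G * S
  qualified <- integer(0)
  n_qual <- floor(config$qualifier_fraction * n_species)
  if (n_qual > 0L) qualified <- sort(sample.int(n_species, n_qual))

  labels <- character(0)
  seqs <- character(0)
  tax <- list()
  acc <- 0L
  sp_index <- 0L
  for (g in seq_len(G)) {
    genus_name <- alpha_name("Genus", g)
    genus_anc <- evolve_k2p(root, b_genus, kappa)
    for (s in seq_len(S)) {
      sp_index <- sp_index + 1L
      species_name <- alpha_name("species", s)
      species_anc <- evolve_k2p(genus_anc, b_species, kappa)
      qualifier <- "none"
      if (sp_index %in% qualified) {
        qualifier <- if (match(sp_index, qualified) %% 2L == 1L) "sp" else "cf"
      }
      for (k in seq_len(K)) {
        acc <- acc + 1L
        accession <- sprintf("ACC%05d", acc)
        label <- switch(
          qualifier,
          none = paste(genus_name, species_name, accession, sep = "_"),
          sp = paste(genus_name, "sp.", accession, sep = "_"),
          cf = paste(genus_name, "cf.", species_name, accession, sep = "_")
        )
        labels <- c(labels, label)
        seqs <- c(seqs, decode_sequence(evolve_k2p(species_anc, b_seq, kappa)))
        tax[[length(tax) + 1L]] <- data.frame(
          label = label, genus = genus_name, species = species_name,
          qualifier = qualifier, accession = accession,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  taxonomy <- do.call(rbind, tax)
  aln <- seq_alignment(labels, seqs)
  list(alignment = aln, taxonomy = taxonomy,
       truth = ground_truth_pairs(taxonomy), config = config)
}

# purely alphabetic synthetic names ("Genusaa", "speciesab", ...) so the
# taxon-label parser treats them as genus/epithet, not accession tokens
alpha_name <- function(prefix, i) {
  paste0(prefix, letters[(i - 1L) %/% 26L + 1L], letters[(i - 1L) %% 26L + 1L])
}

# expected classification of every unordered pair given the true
# taxonomy, with uncertainty qualifiers demoted to genus-level
ground_truth_pairs <- function(taxonomy) {
  n <- nrow(taxonomy)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  same_genus <- taxonomy$genus[i] == taxonomy$genus[j]
  plain <- taxonomy$qualifier == "none"
  conspecific <- same_genus & plain[i] & plain[j] &
    taxonomy$species[i] == taxonomy$species[j]
  data.frame(
    labelA = taxonomy$label[i],
    labelB = taxonomy$label[j],
    category = ifelse(conspecific, "intraspecific",
                      ifelse(same_genus, "intrageneric", "other")),
    stringsAsFactors = FALSE
  )
}
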