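test_that("pairs classify as intraspecific / intrageneric / other", {
  af <- taxon("Agaricia_fragilis_KM051016")
  af2 <- taxon("Agaricia fragilis DQ000001")
  ah <- taxon("Agaricia_humilis_DQ643831")
  pv <- taxon("Pavona_varians_X1")
  dsp <- taxon("Discosoma sp.")
  dnu <- taxon("Discosoma_nummiforme_Y2")
  dcf <- taxon("Discosoma_cf._nummiforme_Y3")

  expect_equal(classify_pair(af, af2), "intraspecific")
  expect_equal(classify_pair(af, ah), "intrageneric")
  expect_equal(classify_pair(af, pv), "other")
  # genus-only and uncertain identifications compare at the genus level
  expect_equal(classify_pair(dsp, dnu), "intrageneric")
  expect_equal(classify_pair(dcf, dnu), "intrageneric")
  expect_equal(classify_pair(dsp, dsp), "intrageneric")
})

test_that("classification is symmetric over generated name pairs", {
  set.seed(77)
  labs <- c("Agaricia_fragilis_A1", "Agaricia_fragilis_A2",
            "Agaricia_humilis_B1", "Agaricia_sp._C1", "Agaricia_cf._humilis_C2",
            "Pavona_varians_D1", "Pavona_sp._D2", "Discosoma_nummiforme_E1")
  names_parsed <- lapply(labs, taxon)
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      expect_equal(classify_pair(names_parsed[[i]], names_parsed[[j]]),
                   classify_pair(names_parsed[[j]], names_parsed[[i]]))
    }
  }
})

make_dmat <- function(labels, width = 400, seed = 1, mutate = 0.01) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  seqs <- vapply(seq_along(labels), function(i) {
    s <- base
    k <- max(1L, round(mutate * width))
    pos <- sample(width, k)
    s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  pairwise_distance_matrix(seq_alignment(labels, seqs), min_sites = 10)
}

test_that("contrast table enumerates pairs with correct category counts", {
  labs <- c("GenusA_speciesX_1", "GenusA_speciesX_2",
            "GenusA_speciesY_1", "GenusA_speciesY_2")
  ct <- contrast_table(make_dmat(labs))
  tally <- attr(ct, "tally")
  expect_equal(unname(tally["intraspecific"]), 2)
  expect_equal(unname(tally["intrageneric"]), 4)
  expect_equal(unname(tally["other"]), 0)
  expect_equal(nrow(ct), 6L)

  # matrix rows agree with classify_pair on the parsed labels
  for (r in seq_len(nrow(ct))) {
    expect_equal(ct$category[r],
                 classify_pair(taxon(ct$labelA[r]), taxon(ct$labelB[r])))
  }

  # k sequences of one binomial: all pairs conspecific
  labs2 <- sprintf("GenusA_speciesX_%d", 1:5)
  ct2 <- contrast_table(make_dmat(labs2))
  expect_equal(unname(attr(ct2, "tally")["intraspecific"]), 10)
})

test_that("category counts are invariant under label permutation", {
  labs <- c("GenusA_speciesX_1", "GenusA_speciesX_2", "GenusA_speciesY_1",
            "GenusB_speciesZ_1", "GenusB_sp._2", "GenusC_speciesW_1")
  t1 <- attr(contrast_table(make_dmat(labs, seed = 3)), "tally")
  set.seed(42)
  perm <- sample(length(labs))
  t2 <- attr(contrast_table(make_dmat(labs[perm], seed = 3)), "tally")
  expect_equal(t1[c("intraspecific", "intrageneric", "other")],
               t2[c("intraspecific", "intrageneric", "other")])
})

test_that("bookkeeping identity holds with skipped, missing and saturated pairs", {
  # one unparseable label, one low-overlap pair, one saturated pair
  labs <- c("GenusA_speciesX_1", "GenusA_speciesX_2", "12345",
            "GenusB_speciesZ_1", "GenusB_speciesZ_2")
  w <- 200
  base <- paste(rep("ACGT", w / 4), collapse = "")
  seqs <- c(base, base, base,
            paste0(strrep("-", w - 40), substr(base, w - 39, w)),  # low overlap
            chartr("ACGT", "GTAC", base))  # all transitions+transversions
  dm <- pairwise_distance_matrix(seq_alignment(labs, seqs), min_sites = 100)
  ct <- contrast_table(dm)
  tally <- attr(ct, "tally")
  expect_equal(attr(ct, "skipped_labels"), "12345")
  expect_gte(unname(tally["saturated"]), 1)
  expect_gte(unname(tally["missing"]), 1)
  expect_gte(unname(tally["skipped"]), 4)
  expect_equal(nrow(ct) + unname(tally["missing"]) + unname(tally["skipped"]),
               unname(tally["total_pairs"]))
  expect_equal(unname(tally["total_pairs"]), 10)
})

test_that("summaries report order statistics untouched by truncation", {
  labs <- c("GenusA_speciesX_1", "GenusA_speciesX_2",
            "GenusA_speciesY_1", "GenusB_speciesZ_1")
  ct <- contrast_table(make_dmat(labs, seed = 8, mutate = 0.05))
  # overwrite with hand-picked distances to check arithmetic exactly
  ct$d <- c(0.01, 0.02, 0.03, 0.20, 0.30, 0.40)
  ct$category <- c("intraspecific", "intraspecific", "intraspecific",
                   "other", "other", "other")
  s <- summarize_contrasts(ct, truncation = 0.05)
  intra <- s$categories$intraspecific
  expect_equal(intra$count, 3L)
  expect_equal(intra$mean, 0.02)
  expect_equal(intra$median, 0.02)
  # distances beyond the display truncation still drive the statistics
  expect_equal(s$categories$other$max, 0.40)
  expect_equal(s$categories$intrageneric$count, 0L)
  expect_true(is.na(s$categories$intrageneric$mean))
})

test_that("per-category densities integrate to ~1 on the full grid", {
  labs <- c(sprintf("GenusA_speciesX_%d", 1:6),
            sprintf("GenusB_speciesY_%d", 1:4))
  ct <- contrast_table(make_dmat(labs, seed = 15, mutate = 0.04))
  s <- summarize_contrasts(ct, truncation = 0.05)
  for (cat in c("intraspecific", "other")) {
    g <- s$categories[[cat]]$density
    integral <- sum(diff(g$x) * (utils::head(g$y, -1) + utils::tail(g$y, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
    expect_true(all(g$x >= 0))
    # the reflected-kernel mixture itself has unit mass on [0, Inf)
    fin <- ct$d[ct$category == cat & is.finite(ct$d)]
    bw <- s$categories[[cat]]$bandwidth
    f <- function(t) {
      vapply(t, function(tt) {
        mean(stats::dnorm(tt, fin, bw) + stats::dnorm(tt, -fin, bw))
      }, numeric(1))
    }
    mass <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("overlap fraction quantifies stratum separation", {
  ct_template <- function(d_intra, d_rest) {
    structure(
      data.frame(
        labelA = "a", labelB = "b",
        category = c(rep("intraspecific", length(d_intra)),
                     rep("intrageneric", length(d_rest))),
        n = 500L, d = c(d_intra, d_rest), flag = "ok"
      ),
      class = c("contrast_table", "data.frame")
    )
  }
  # perfectly separated strata
  expect_equal(overlap_fraction(ct_template(c(0.01, 0.02), c(0.1, 0.2, 0.3))), 0)
  # exactly one of m below the intraspecific max
  expect_equal(overlap_fraction(ct_template(c(0.05), c(0.01, 0.6, 0.7, 0.8))),
               1 / 4)
  # both strata from one distribution: fraction = rank of the intraspecific
  # max among the rest, checked by direct enumeration
  set.seed(99)
  pool <- stats::runif(60, 0, 0.1)
  d_intra <- pool[1:20]
  d_rest <- pool[21:60]
  expect_equal(overlap_fraction(ct_template(d_intra, d_rest)),
               sum(d_rest <= max(d_intra)) / 40)
  expect_gt(overlap_fraction(ct_template(d_intra, d_rest)), 0.5)

  expect_error(overlap_fraction(ct_template(numeric(0), c(0.1))),
               "intraspecific")
})

test_that("summary exports carry counts, densities and settings", {
  labs <- c("GenusA_speciesX_1", "GenusA_speciesX_2",
            "GenusA_speciesY_1", "GenusB_speciesZ_1")
  ct <- contrast_table(make_dmat(labs, seed = 4, mutate = 0.05))
  s <- summarize_contrasts(ct)
  json <- tempfile(fileext = ".json")
  write_summary_json(s, json)
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$categories$intraspecific$count, 1L)
  expect_equal(parsed$tally$total_pairs, 6L)

  dens <- tempfile(fileext = ".tsv")
  write_density_tsv(s, dens)
  grid <- utils::read.delim(dens)
  expect_true(all(grid$x <= s$truncation))
  expect_true(all(c("category", "x", "y") %in% names(grid)))

  tsv <- tempfile(fileext = ".tsv")
  write_contrasts_tsv(ct, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), nrow(ct))
})
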