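#' Count pairwise site differences
#'
#' Classifies the columns shared by two aligned sequences into
#' comparable sites, transitions and transversions, the ingredients of
#' the Kimura 2-parameter distance. A column is comparable only when
#' both characters are unambiguous nucleotides (`A`, `C`, `G`, `T`);
#' gaps, `?`, `N` and IUPAC ambiguity codes are excluded pairwise, so a
#' ragged column is dropped only for the pairs it affects.
#'
#' @param seq_a,seq_b equal-length aligned sequences (character strings,
#'   or integer encodings from [encode_alignment()]).
#' @return list with `n` (comparable sites), `ts` (transitions: A/G and
#'   C/T mismatches) and `tv` (transversions: all other mismatches).
#' @examples
#' count_site_differences("AAAA", "GAAT") # n = 4, ts = 1, tv = 1
#' @export
count_site_differences <- function(seq_a, seq_b) {
  a <- if (is.character(seq_a)) encode_sequence(normalize_sequence(seq_a)) else seq_a
  b <- if (is.character(seq_b)) encode_sequence(normalize_sequence(seq_b)) else seq_b
  if (length(a) != length(b)) {
    stop("sequences differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  valid <- a > 0L & b > 0L
  av <- a[valid]
  bv <- b[valid]
  diff <- av != bv
  # with A=1, C=2, G=3, T=4 a mismatch is a transition iff codes share parity
  ts <- sum(diff & (av - bv) %% 2L == 0L)
  list(n = sum(valid), ts = as.integer(ts), tv = as.integer(sum(diff) - ts))
}

#' Kimura 2-parameter distance from site counts
#'
#' With transition proportion `P = ts/n` and transversion proportion
#' `Q = tv/n`, the K2P distance is
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`
#' substitutions per site. When a log argument is non-positive the
#' distance is saturated (multiple hits cannot be corrected) and the
#' sentinel `Inf` is returned rather than an error, so one saturated
#' pair cannot abort a large distance matrix.
#'
#' @param counts a list with `n`, `ts`, `tv` (as returned by
#'   [count_site_differences()]), or the number of comparable sites if
#'   `ts` and `tv` are given separately.
#' @param ts,tv transition and transversion counts (used when `counts`
#'   is the site count).
#' @return distance in substitutions/site (`Inf` when saturated).
#' @examples
#' k2p_distance(list(n = 100, ts = 10, tv = 5)) # ~0.17018
#' @export
k2p_distance <- function(counts, ts = NULL, tv = NULL) {
  if (is.list(counts)) {
    n <- counts$n; ts <- counts$ts; tv <- counts$tv
  } else {
    n <- counts
  }
  if (is.null(n) || is.na(n) || n <= 0) {
    stop("K2P distance undefined: no comparable sites (n = 0)", call. = FALSE)
  }
  k2p_from_proportions(ts / n, tv / n)
}

# vectorized core shared with the window scan
k2p_from_proportions <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(w1 > 0 & w2 > 0,
              -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                0.25 * log(pmax(w2, .Machine$double.xmin)),
              Inf)
  unname(d)
}

#' Pairwise K2P distance matrix
#'
#' Computes all N(N-1)/2 K2P distances of an alignment under pairwise
#' deletion. Pairs whose comparable-site count falls below `min_sites`
#' are recorded as missing (`NA`), not zero — short GenBank reads can
#' overlap a few dozen sites and give wild distances. Saturated pairs
#' carry the `Inf` sentinel and a `"saturated"` flag; neither aborts the
#' matrix.
#'
#' @param aln a `seq_alignment` with at least 2 records.
#' @param min_sites minimum comparable sites for a pair to be usable
#'   (default 100).
#' @return an object of class `k2p_dist`: list with `labels`, symmetric
#'   matrices `d`, `sites`, `ts`, `tv`, a character matrix `flag`
#'   (`"ok"`, `"missing"`, `"saturated"`) and `min_sites`.
#' @export
pairwise_distance_matrix <- function(aln, min_sites = 100L) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (aln$n < 2L) stop("alignment must have >= 2 records", call. = FALSE)
  m <- encode_alignment(aln)
  n <- aln$n
  d <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  sites <- matrix(0L, n, n, dimnames = dimnames(d))
  ts <- matrix(0L, n, n, dimnames = dimnames(d))
  tv <- matrix(0L, n, n, dimnames = dimnames(d))
  flag <- matrix("ok", n, n, dimnames = dimnames(d))
  valid <- m > 0L
  diag(sites) <- as.integer(rowSums(valid))
  for (i in seq_len(n - 1L)) {
    ai <- m[i, ]
    vi <- valid[i, ]
    for (j in (i + 1L):n) {
      both <- vi & valid[j, ]
      av <- ai[both]
      bv <- m[j, both]
      mism <- av != bv
      nts <- sum(mism & (av - bv) %% 2L == 0L)
      ntv <- sum(mism) - nts
      nn <- length(av)
      sites[i, j] <- sites[j, i] <- nn
      ts[i, j] <- ts[j, i] <- as.integer(nts)
      tv[i, j] <- tv[j, i] <- as.integer(ntv)
      if (nn < min_sites) {
        d[i, j] <- d[j, i] <- NA_real_
        flag[i, j] <- flag[j, i] <- "missing"
      } else {
        dij <- k2p_from_proportions(nts / nn, ntv / nn)
        d[i, j] <- d[j, i] <- dij
        if (is.infinite(dij)) flag[i, j] <- flag[j, i] <- "saturated"
      }
    }
  }
  structure(
    list(labels = aln$labels, d = d, sites = sites, ts = ts, tv = tv,
         flag = flag, min_sites = as.integer(min_sites)),
    class = "k2p_dist"
  )
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$labels)
  np <- n * (n - 1L) / 2L
  up <- upper.tri(x$d)
  cat(sprintf("k2p_dist: %d sequences, %d pairs (%d missing, %d saturated)\n",
              n, np, sum(x$flag[up] == "missing"),
              sum(x$flag[up] == "saturated")))
  fin <- x$d[up][is.finite(x$d[up])]
  if (length(fin)) {
    cat(sprintf("  finite distances: min %.4g, median %.4g, max %.4g\n",
                min(fin), stats::median(fin), max(fin)))
  }
  invisible(x)
}

#' Export a distance matrix
#'
#' `write_phylip_dist()` writes the PHYLIP square distance format
#' (missing and saturated entries rendered as -1). `write_dist_tsv()`
#' writes the long form, one row per unordered pair, with site counts
#' and flags.
#'
#' @param x a `k2p_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(x, path) {
  stopifnot(inherits(x, "k2p_dist"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(x$labels)), con)
  dd <- x$d
  dd[!is.finite(dd)] <- -1
  for (i in seq_along(x$labels)) {
    writeLines(paste0(sprintf("%-10s", gsub("\\s", "_", x$labels[i])),
                      paste(sprintf("%.6f", dd[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
write_dist_tsv <- function(x, path) {
  stopifnot(inherits(x, "k2p_dist"))
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  df <- data.frame(
    labelA = x$labels[idx[, 1L]],
    labelB = x$labels[idx[, 2L]],
    n = x$sites[idx],
    ts = x$ts[idx],
    tv = x$tv[idx],
    d = x$d[idx],
    flag = x$flag[idx]
  )
  write_tsv(df, path)
}

#' Write a TSV with a header row
#'
#' @param rows a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
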