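#' Sliding-window K2P divergence between two aligned genomes
#'
#' Scans a two-genome alignment with windows of `window_size` alignment
#' columns advanced by `step`, computing the K2P distance within each
#' window under pairwise deletion. Windows are defined on alignment
#' columns: gap columns stay in the coordinate frame but never count as
#' comparable sites. Windows with fewer than `min_sites` comparable
#' sites are reported with a missing distance. If the last full window
#' does not reach the end of the alignment, one final short window is
#' appended and flagged `"partial"` so the track covers every column;
#' wrap-around (circular) windows are not generated.
#'
#' @param genome_a,genome_b the two aligned sequences (character
#'   strings), or a 2-record `seq_alignment` passed as `genome_a`.
#' @param window_size window width in alignment columns (default 500).
#' @param step distance between window starts (default 25).
#' @param min_sites minimum comparable sites per window (default 100).
#' @return a `data.frame` of class `window_track` with columns `start`,
#'   `end` (0-based half-open), `n`, `ts`, `tv`, `d`, `flag` (`"ok"`,
#'   `"missing"`, `"partial"`, `"saturated"`), ordered by `start`.
#'   Attributes `window_size`, `step`, `min_sites` record the settings.
#' @export
sliding_window_divergence <- function(genome_a, genome_b = NULL,
                                      window_size = 500L, step = 25L,
                                      min_sites = 100L) {
  pair <- as_genome_pair(genome_a, genome_b)
  L <- length(pair$a)
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (window_size < 1L || window_size > L) {
    stop("window_size must be in [1, alignment length = ", L, "]",
         call. = FALSE)
  }
  cs <- pair_cumsums(pair$a, pair$b)
  starts <- seq.int(0L, L - window_size, by = step)
  ends <- starts + window_size
  flags <- rep("ok", length(starts))
  if (ends[length(ends)] < L) {
    starts <- c(starts, starts[length(starts)] + step)
    ends <- c(ends, L)
    flags <- c(flags, "partial")
  }
  n <- cs$valid[ends + 1L] - cs$valid[starts + 1L]
  ts <- cs$ts[ends + 1L] - cs$ts[starts + 1L]
  tv <- cs$tv[ends + 1L] - cs$tv[starts + 1L]
  d <- rep(NA_real_, length(starts))
  usable <- n >= min_sites
  d[usable] <- k2p_from_proportions(ts[usable] / n[usable],
                                    tv[usable] / n[usable])
  flags[!usable] <- "missing"
  flags[usable & is.infinite(d)] <- "saturated"
  out <- data.frame(start = starts, end = ends, n = n, ts = ts, tv = tv,
                    d = d, flag = flags)
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  attr(out, "min_sites") <- as.integer(min_sites)
  class(out) <- c("window_track", "data.frame")
  out
}

as_genome_pair <- function(genome_a, genome_b) {
  if (inherits(genome_a, "seq_alignment")) {
    if (genome_a$n != 2L) {
      stop("genome-pair scan needs exactly 2 aligned records, got ",
           genome_a$n, call. = FALSE)
    }
    m <- encode_alignment(genome_a)
    return(list(a = m[1L, ], b = m[2L, ]))
  }
  a <- if (is.character(genome_a)) encode_sequence(normalize_sequence(genome_a)) else genome_a
  b <- if (is.character(genome_b)) encode_sequence(normalize_sequence(genome_b)) else genome_b
  if (length(a) != length(b)) {
    stop("genomes differ in aligned length", call. = FALSE)
  }
  list(a = a, b = b)
}

# column-wise cumulative counts (index k+1 = prefix of length k) so any
# interval's site counts come from two subtractions
pair_cumsums <- function(a, b) {
  valid <- a > 0L & b > 0L
  diff <- valid & a != b
  ts <- diff & (a - b) %% 2L == 0L
  list(valid = c(0L, cumsum(valid)),
       ts = c(0L, cumsum(ts)),
       tv = c(0L, cumsum(diff & !ts)))
}

#' Per-region K2P divergence
#'
#' For each annotated region, computes the K2P distance over exactly the
#' region's alignment columns (`d_region`, one "window" spanning the
#' region) and, alongside it, the mean of sliding-window distances for
#' windows fully contained in the region (`mean_window_d`, `NA` when no
#' full window fits or none is usable). Both statistics are reported
#' because "mean divergence of a region" is used in both senses in the
#' literature.
#'
#' @inheritParams sliding_window_divergence
#' @param regions regions `data.frame` from [read_regions()] (or the
#'   simulator).
#' @param track optional precomputed `window_track`; computed on the fly
#'   when omitted.
#' @return `data.frame` with columns `name`, `start`, `end`, `category`,
#'   `n`, `ts`, `tv`, `d_region`, `mean_window_d`, `n_windows`.
#' @export
region_divergence <- function(genome_a, genome_b = NULL, regions,
                              window_size = 500L, step = 25L,
                              min_sites = 100L, track = NULL) {
  pair <- as_genome_pair(genome_a, genome_b)
  L <- length(pair$a)
  if (any(regions$start < 0L) || any(regions$end > L)) {
    bad <- regions$name[regions$start < 0L | regions$end > L]
    stop("region(s) outside alignment bounds [0, ", L, "): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(track) && window_size <= L) {
    track <- sliding_window_divergence(pair$a, pair$b,
                                       window_size = window_size,
                                       step = step, min_sites = min_sites)
  }
  cs <- pair_cumsums(pair$a, pair$b)
  n <- cs$valid[regions$end + 1L] - cs$valid[regions$start + 1L]
  ts <- cs$ts[regions$end + 1L] - cs$ts[regions$start + 1L]
  tv <- cs$tv[regions$end + 1L] - cs$tv[regions$start + 1L]
  d_region <- rep(NA_real_, nrow(regions))
  ok <- n >= 1L
  d_region[ok] <- k2p_from_proportions(ts[ok] / n[ok], tv[ok] / n[ok])
  mean_window_d <- rep(NA_real_, nrow(regions))
  n_windows <- integer(nrow(regions))
  if (!is.null(track)) {
    full <- track$flag != "partial"
    for (r in seq_len(nrow(regions))) {
      inside <- full & track$start >= regions$start[r] &
        track$end <= regions$end[r]
      dvals <- track$d[inside]
      dvals <- dvals[is.finite(dvals)]
      n_windows[r] <- sum(inside)
      if (length(dvals)) mean_window_d[r] <- mean(dvals)
    }
  }
  data.frame(name = regions$name, start = regions$start, end = regions$end,
             category = regions$category, n = n, ts = ts, tv = tv,
             d_region = d_region, mean_window_d = mean_window_d,
             n_windows = n_windows, stringsAsFactors = FALSE)
}

#' Rank regions by divergence
#'
#' Orders regions by `d_region`, descending, keeping only the requested
#' categories (coding regions by default — the usual candidates for
#' conserved primer development). Ties are broken by start coordinate.
#'
#' @param region_div output of [region_divergence()].
#' @param categories categories to keep (default `"coding"`).
#' @return the filtered `data.frame`, ordered; the top row is the
#'   scan's headline region.
#' @export
rank_regions <- function(region_div, categories = "coding") {
  keep <- region_div[region_div$category %in% categories, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop("no regions left after category filter (",
         paste(categories, collapse = ", "), ")", call. = FALSE)
  }
  keep <- keep[order(-keep$d_region, keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Export a window track
#'
#' `write_track_tsv()` writes the full per-window table;
#' `write_track_bedgraph()` writes a BedGraph of the distance column
#' (missing/saturated windows omitted) for genome-browser display.
#'
#' @param track a `window_track`.
#' @param path output path.
#' @param seqname sequence name for the BedGraph.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  write_tsv(as.data.frame(track), path)
}

#' @rdname write_track_tsv
#' @export
write_track_bedgraph <- function(track, path, seqname = "chrM") {
  ok <- is.finite(track$d)
  df <- data.frame(seqname, track$start[ok], track$end[ok],
                   sprintf("%.6f", track$d[ok]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=k2p_divergence", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
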