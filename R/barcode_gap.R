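#' Classify a pair of taxon names
#'
#' Codes a pair of sequences by taxonomic relationship:
#'
#' * `intraspecific` (conspecific) — same genus, both species epithets
#'   present and equal, and neither name carries an uncertainty
#'   qualifier (`sp.`, `cf.`, `aff.`);
#' * `intrageneric` (congeneric, excluding conspecific) — same genus
#'   otherwise. Sequences identified only to genus, or flagged
#'   uncertain, are comparable at the genus level and never form
#'   intraspecific pairs, even when their raw labels match;
#' * `other` — different genera.
#'
#' Genus and epithet matching is case-insensitive. The function is
#' symmetric and total on parsed names.
#'
#' @param name_a,name_b `taxon_name` objects from [parse_taxon_label()].
#' @return one of `"intraspecific"`, `"intrageneric"`, `"other"`.
#' @export
classify_pair <- function(name_a, name_b) {
  stopifnot(inherits(name_a, "taxon_name"), inherits(name_b, "taxon_name"))
  if (tolower(name_a$genus) != tolower(name_b$genus)) return("other")
  if (name_a$qualifier == "none" && name_b$qualifier == "none" &&
      !is.na(name_a$epithet) && !is.na(name_b$epithet) &&
      tolower(name_a$epithet) == tolower(name_b$epithet)) {
    return("intraspecific")
  }
  "intrageneric"
}

#' Build the pairwise contrast table
#'
#' Turns a K2P distance matrix into one row per unordered sequence pair,
#' coded by [classify_pair()] on the parsed labels. Pairs with a missing
#' distance (too few comparable sites) and pairs involving an
#' unparseable label are excluded from the table but tallied, and the
#' bookkeeping identity
#' `nrow(contrasts) + missing + skipped = N(N-1)/2`
#' is asserted on every run. Saturated pairs are kept in the table with
#' the `Inf` sentinel (they are real, very divergent contrasts) but are
#' excluded from order statistics and densities downstream.
#'
#' @param dmat a `k2p_dist` from [pairwise_distance_matrix()].
#' @return a `data.frame` of class `contrast_table` with columns
#'   `labelA`, `labelB`, `category`, `n`, `d`, `flag`; attributes
#'   `skipped_labels` (unparseable labels), and `tally`, a named vector
#'   with `intraspecific`, `intrageneric`, `other`, `saturated`,
#'   `missing`, `skipped`, `total_pairs`.
#' @export
contrast_table <- function(dmat) {
  stopifnot(inherits(dmat, "k2p_dist"))
  parsed <- parse_taxon_labels(dmat$labels)
  ok_label <- !vapply(parsed$names, is.null, logical(1L))
  N <- length(dmat$labels)
  idx <- which(upper.tri(dmat$d), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  pair_ok <- ok_label[i] & ok_label[j]
  missing <- dmat$flag[idx] == "missing"
  keep <- pair_ok & !missing
  ki <- i[keep]; kj <- j[keep]
  # vectorized classification, one field vector per sequence; equivalent
  # to classify_pair() per pair (asserted in the test suite)
  genus <- tolower(vapply(parsed$names, function(p) {
    if (is.null(p)) NA_character_ else p$genus
  }, character(1L)))
  epithet <- tolower(vapply(parsed$names, function(p) {
    if (is.null(p)) NA_character_ else p$epithet
  }, character(1L)))
  plain <- vapply(parsed$names, function(p) {
    !is.null(p) && p$qualifier == "none"
  }, logical(1L))
  same_genus <- genus[ki] == genus[kj]
  conspecific <- same_genus & plain[ki] & plain[kj] &
    !is.na(epithet[ki]) & !is.na(epithet[kj]) & epithet[ki] == epithet[kj]
  category <- ifelse(conspecific, "intraspecific",
                     ifelse(same_genus, "intrageneric", "other"))
  out <- data.frame(
    labelA = dmat$labels[ki],
    labelB = dmat$labels[kj],
    category = category,
    n = dmat$sites[idx][keep],
    d = dmat$d[idx][keep],
    flag = dmat$flag[idx][keep],
    stringsAsFactors = FALSE
  )
  tally <- c(
    intraspecific = sum(category == "intraspecific"),
    intrageneric = sum(category == "intrageneric"),
    other = sum(category == "other"),
    saturated = sum(out$flag == "saturated"),
    missing = sum(missing & pair_ok),
    skipped = sum(!pair_ok),
    total_pairs = N * (N - 1L) / 2L
  )
  stopifnot(nrow(out) + tally[["missing"]] + tally[["skipped"]] ==
              tally[["total_pairs"]])
  attr(out, "skipped_labels") <- parsed$skipped
  attr(out, "tally") <- tally
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Summarize the three contrast distributions
#'
#' Computes, per category (intraspecific / intrageneric / other), the
#' pair count and order statistics of the finite K2P distances, and a
#' Gaussian kernel density estimate with Silverman's rule-of-thumb
#' bandwidth, reflected at the d = 0 boundary so no density mass leaks
#' below zero. The density is evaluated on a full grid (out to the
#' largest distance plus six bandwidths, so it integrates to ~1) and a
#' truncated display grid `[0, truncation]` is exported for plotting;
#' truncation never affects counts or statistics.
#'
#' @param contrasts a `contrast_table`.
#' @param truncation upper bound of the display grid (default 0.05,
#'   where intraspecific and almost all intrageneric contrasts live).
#' @param bandwidth kernel bandwidth; `NULL` (default) uses Silverman's
#'   rule ([stats::bw.nrd0()]).
#' @param grid_n number of grid points for the full density grid.
#' @return object of class `contrast_summary`: list with `categories`
#'   (per-category list of `count`, `n_finite`, `n_saturated`, `min`,
#'   `max`, `mean`, `median`, `density` data.frame with `x`, `y`, and
#'   `bandwidth`), `overlap_fraction`, `truncation`, `tally`.
#' @export
summarize_contrasts <- function(contrasts, truncation = 0.05,
                                bandwidth = NULL, grid_n = 2048L) {
  stopifnot(inherits(contrasts, "contrast_table"))
  cats <- c("intraspecific", "intrageneric", "other")
  per <- stats::setNames(vector("list", length(cats)), cats)
  for (cat in cats) {
    dd <- contrasts$d[contrasts$category == cat]
    fin <- dd[is.finite(dd)]
    entry <- list(count = length(dd), n_finite = length(fin),
                  n_saturated = sum(is.infinite(dd)))
    if (length(fin)) {
      entry$min <- min(fin); entry$max <- max(fin)
      entry$mean <- mean(fin); entry$median <- stats::median(fin)
      entry$density <- reflected_density(fin, bandwidth, grid_n)
      entry$bandwidth <- attr(entry$density, "bandwidth")
    } else {
      entry[c("min", "max", "mean", "median")] <- NA_real_
      entry$density <- NULL
      entry$bandwidth <- NA_real_
    }
    per[[cat]] <- entry
  }
  ov <- tryCatch(overlap_fraction(contrasts), error = function(e) NA_real_)
  structure(
    list(categories = per, overlap_fraction = ov,
         truncation = truncation, bandwidth = bandwidth,
         tally = attr(contrasts, "tally"),
         skipped_labels = attr(contrasts, "skipped_labels")),
    class = "contrast_summary"
  )
}

# Gaussian KDE reflected at 0: estimate on c(x, -x), keep x >= 0, double.
# Degenerate spread (all values equal) falls back to a narrow fixed
# bandwidth so a point mass is rendered as a tight spike.
reflected_density <- function(x, bandwidth = NULL, grid_n = 2048L) {
  bw <- bandwidth
  if (is.null(bw)) {
    bw <- if (length(x) >= 2L && stats::sd(x) > 0) stats::bw.nrd0(x) else 1e-4
  }
  upper <- max(x) + 6 * bw
  dens <- stats::density(c(x, -x), bw = bw, from = 0, to = upper,
                         n = grid_n, kernel = "gaussian")
  out <- data.frame(x = dens$x, y = 2 * dens$y)
  attr(out, "bandwidth") <- bw
  out
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat("contrast_summary\n")
  for (cat_name in names(x$categories)) {
    e <- x$categories[[cat_name]]
    cat(sprintf("  %-14s n=%-6d mean=%-8.4g median=%-8.4g range=[%.4g, %.4g]\n",
                cat_name, e$count,
                ifelse(is.na(e$mean), NA, e$mean),
                ifelse(is.na(e$median), NA, e$median),
                ifelse(is.na(e$min), NA, e$min),
                ifelse(is.na(e$max), NA, e$max)))
  }
  cat(sprintf("  overlap_fraction = %.4g\n", x$overlap_fraction))
  invisible(x)
}

#' Fraction of non-intraspecific contrasts inside the intraspecific range
#'
#' A quantitative statement of barcode-gap failure: the proportion of
#' intrageneric + other contrasts whose distance does not exceed the
#' largest intraspecific distance. A clean barcode gap gives 0; values
#' well above 0 mean between-taxon divergence is not separable from
#' within-species diversity at this locus.
#'
#' @param contrasts a `contrast_table`.
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(contrasts) {
  d_intra <- contrasts$d[contrasts$category == "intraspecific"]
  d_intra <- d_intra[is.finite(d_intra)]
  if (length(d_intra) == 0L) {
    stop("overlap_fraction undefined: no finite intraspecific contrasts",
         call. = FALSE)
  }
  d_rest <- contrasts$d[contrasts$category != "intraspecific"]
  d_rest <- d_rest[is.finite(d_rest)]
  if (length(d_rest) == 0L) {
    stop("overlap_fraction undefined: no finite non-intraspecific contrasts",
         call. = FALSE)
  }
  mean(d_rest <= max(d_intra))
}

#' Export barcode-gap results
#'
#' `write_contrasts_tsv()` writes the contrast table;
#' `write_density_tsv()` writes the per-category density grids truncated
#' to the display bound; `write_summary_json()` writes counts,
#' statistics, overlap fraction and settings as JSON.
#'
#' @param contrasts a `contrast_table`.
#' @param summary a `contrast_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contrasts_tsv <- function(contrasts, path) {
  write_tsv(as.data.frame(contrasts), path)
}

#' @rdname write_contrasts_tsv
#' @export
write_density_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "contrast_summary"))
  grids <- list()
  for (cat_name in names(summary$categories)) {
    g <- summary$categories[[cat_name]]$density
    if (is.null(g)) next
    g <- g[g$x <= summary$truncation, , drop = FALSE]
    grids[[cat_name]] <- data.frame(category = cat_name, x = g$x, y = g$y)
  }
  write_tsv(do.call(rbind, grids), path)
}

#' @rdname write_contrasts_tsv
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "contrast_summary"))
  out <- list(
    categories = lapply(summary$categories, function(e) {
      e$density <- NULL
      e
    }),
    overlap_fraction = summary$overlap_fraction,
    truncation = summary$truncation,
    tally = as.list(summary$tally),
    skipped_labels = summary$skipped_labels
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
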