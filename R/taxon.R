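#' Parse taxonomy from a sequence label
#'
#' Labels in GenBank-derived alignments mix taxonomy and accession
#' information, with underscores or spaces as separators, e.g.
#' `"Agaricia_fragilis_KM051016"`, `"Discosoma sp."` or
#' `"Pavona_cf._varians"`. The parser extracts:
#'
#' * `genus` — the first purely alphabetic token;
#' * `epithet` — the following alphabetic token, unless it is the `sp.`
#'   placeholder or looks like an accession (contains digits);
#' * `qualifier` — `"sp"` when the species is unidentified, `"cf"` /
#'   `"aff"` when the identification is flagged uncertain, otherwise
#'   `"none"`.
#'
#' Trailing tokens (accession numbers, haplotype codes) are kept only in
#' `raw_label`. Uncertain-identification qualifiers mean the sequence is
#' comparable at the genus level only, never the species level (see
#' [classify_pair()]).
#'
#' @param label a single non-empty character label.
#' @return an object of class `taxon_name`: list with `genus`, `epithet`
#'   (`NA_character_` when absent), `qualifier` (one of `"none"`, `"sp"`,
#'   `"cf"`, `"aff"`) and `raw_label`.
#' @examples
#' parse_taxon_label("Agaricia_fragilis_KM051016")
#' parse_taxon_label("Discosoma sp.")
#' parse_taxon_label("Pavona_cf._varians")
#' @export
parse_taxon_label <- function(label) {
  if (length(label) != 1L || is.na(label) || !nzchar(label)) {
    stop("label must be a single non-empty string", call. = FALSE)
  }
  tokens <- strsplit(label, "[ _]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  is_alpha <- grepl("^[A-Za-z]+\\.?$", tokens)
  first_alpha <- which(is_alpha & !is_qualifier_token(tokens))
  if (length(first_alpha) == 0L) {
    stop("no alphabetic token in label '", label, "'", call. = FALSE)
  }
  gi <- first_alpha[1L]
  genus <- sub("\\.$", "", tokens[gi])
  epithet <- NA_character_
  qualifier <- "none"
  i <- gi + 1L
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (grepl("^sp\\.?$", tok, ignore.case = TRUE)) {
      qualifier <- "sp"
      epithet <- NA_character_
      break
    }
    q <- qualifier_of(tok)
    if (!is.na(q)) {
      qualifier <- q
      i <- i + 1L
      next
    }
    if (grepl("^[A-Za-z]+$", tok)) {
      epithet <- tok
    }
    break
  }
  structure(
    list(genus = genus, epithet = epithet, qualifier = qualifier,
         raw_label = label),
    class = "taxon_name"
  )
}

is_qualifier_token <- function(tok) {
  grepl("^(sp|cf|aff)\\.?$", tok, ignore.case = TRUE)
}

qualifier_of <- function(tok) {
  if (grepl("^cf\\.?$", tok, ignore.case = TRUE)) return("cf")
  if (grepl("^aff\\.?$", tok, ignore.case = TRUE)) return("aff")
  NA_character_
}

#' @export
print.taxon_name <- function(x, ...) {
  cat(sprintf("taxon_name: genus=%s epithet=%s qualifier=%s (raw: '%s')\n",
              x$genus, ifelse(is.na(x$epithet), "<absent>", x$epithet),
              x$qualifier, x$raw_label))
  invisible(x)
}

#' Parse many labels, collecting failures
#'
#' @param labels character vector.
#' @return list with `names` (list of `taxon_name` or `NULL`) and
#'   `skipped` (character vector of unparseable labels).
#' @keywords internal
parse_taxon_labels <- function(labels) {
  names_out <- vector("list", length(labels))
  skipped <- character(0)
  for (i in seq_along(labels)) {
    res <- tryCatch(parse_taxon_label(labels[i]), error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, labels[i])
    names_out[[i]] <- res
  }
  list(names = names_out, skipped = skipped)
}
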