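#' Read region annotations from BED or GFF3
#'
#' Region annotations mark the coding and ribosomal regions of the
#' genome (or alignment) coordinate system used by the divergence scan.
#' All intervals are converted to the internal 0-based half-open
#' convention: BED is already half-open; a GFF3 feature with start `s`
#' and end `e` (1-based inclusive) becomes `[s-1, e)`.
#'
#' The region category (`coding` / `ribosomal` / `other`) is taken from,
#' in order of precedence: the `categories` argument (named by region),
#' the GFF3 feature type (`CDS`/`gene`/`mRNA` are coding, `rRNA` and
#' ribosomal-RNA types ribosomal), or the region name (`COI`, `CYB`,
#' `nad*`, `atp*`, `cox*`, `cob` are coding; `rnl`, `rns`, `rrn*`,
#' `12S`/`16S` ribosomal; anything else `other`).
#'
#' @param path path to the annotation file.
#' @param format `"bed"` or `"gff"`; guessed from the file extension when
#'   omitted.
#' @param seq_length optional total sequence length; intervals beyond it
#'   raise a bounds error.
#' @param categories optional named character vector mapping region names
#'   to categories.
#' @return a `data.frame` with columns `name`, `start`, `end` (0-based
#'   half-open), `category`.
#' @export
read_regions <- function(path, format = c("auto", "bed", "gff"),
                         seq_length = NULL, categories = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) "gff" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff") "gff3" else "bed")
  meta <- S4Vectors::mcols(gr)
  name <- if (format == "gff") {
    nm <- if ("Name" %in% colnames(meta)) as.character(meta$Name) else NA
    id <- if ("ID" %in% colnames(meta)) as.character(meta$ID) else NA
    ifelse(!is.na(nm), nm, id)
  } else {
    as.character(meta$name)
  }
  if (anyNA(name)) stop("regions without a name in ", path, call. = FALSE)
  if (anyDuplicated(name)) {
    stop("duplicate region names in ", path, ": ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  # GRanges is 1-based inclusive for both formats once imported
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(start0 >= end0) || any(start0 < 0L)) {
    bad <- name[start0 >= end0 | start0 < 0L]
    stop("empty or negative interval for region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seq_length) && any(end0 > seq_length)) {
    bad <- name[end0 > seq_length]
    stop("region(s) exceed sequence length ", seq_length, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  type <- if (format == "gff" && "type" %in% colnames(meta)) {
    as.character(meta$type)
  } else {
    rep(NA_character_, length(name))
  }
  category <- mapply(function(nm, ty) {
    if (!is.null(categories) && nm %in% names(categories)) {
      return(match.arg(categories[[nm]], c("coding", "ribosomal", "other")))
    }
    infer_region_category(nm, ty)
  }, name, type, USE.NAMES = FALSE)
  data.frame(name = name, start = as.integer(start0), end = as.integer(end0),
             category = category, stringsAsFactors = FALSE)
}

infer_region_category <- function(name, type = NA_character_) {
  if (!is.na(type)) {
    if (type %in% c("CDS", "gene", "mRNA", "protein_coding_gene")) return("coding")
    if (grepl("rRNA", type, ignore.case = TRUE)) return("ribosomal")
  }
  n <- tolower(name)
  if (grepl("^(rnl|rns|rrn|12s|16s)", n)) return("ribosomal")
  if (grepl("^(co[x1-3i]+|cyb|cob|nad|nd[0-9]|atp)", n)) return("coding")
  "other"
}

#' Write region annotations
#'
#' Inverse of [read_regions()]: converts internal 0-based half-open
#' intervals back to the file convention (BED half-open, GFF3 1-based
#' inclusive), so read-write round-trips reproduce the original fields.
#'
#' @param regions a regions `data.frame` (`name`, `start`, `end`,
#'   `category`).
#' @param path output path.
#' @param format `"bed"` or `"gff"`.
#' @param seqname sequence name for the first column.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("bed", "gff"),
                          seqname = "chrM") {
  format <- match.arg(format)
  if (format == "bed") {
    df <- data.frame(seqname, regions$start, regions$end, regions$name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    type <- c(coding = "gene", ribosomal = "rRNA", other = "region")[regions$category]
    df <- data.frame(seqname, "barcodegap", type,
                     regions$start + 1L, regions$end, ".", "+", ".",
                     sprintf("ID=%s;Name=%s", regions$name, regions$name))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
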