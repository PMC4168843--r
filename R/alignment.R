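#' Construct a sequence alignment
#'
#' A `seq_alignment` is the package's container for an ordered set of
#' equal-length gapped sequences with unique labels. Sequences are stored
#' uppercased with `U` mapped to `T`, over the IUPAC nucleotide alphabet
#' plus the gap (`-`) and missing (`?`) characters.
#'
#' @param labels character vector of unique, non-empty labels.
#' @param seqs character vector of sequences, same length as `labels`.
#' @param check validate invariants (equal lengths, alphabet, unique labels).
#' @return an object of class `seq_alignment`: a list with elements
#'   `labels`, `seqs`, `n` (number of records) and `width` (columns).
#' @export
seq_alignment <- function(labels, seqs, check = TRUE) {
  labels <- as.character(labels)
  seqs <- normalize_sequence(seqs)
  if (check) {
    if (length(labels) != length(seqs)) {
      stop("labels and seqs must have the same length", call. = FALSE)
    }
    if (length(seqs) < 1L || any(!nzchar(seqs))) {
      stop("alignment requires non-empty sequences", call. = FALSE)
    }
    if (any(!nzchar(labels))) stop("labels must be non-empty", call. = FALSE)
    if (anyDuplicated(labels)) {
      stop("duplicate labels in alignment: ",
           paste(unique(labels[duplicated(labels)]), collapse = ", "),
           call. = FALSE)
    }
    w <- nchar(seqs)
    if (length(unique(w)) != 1L) {
      bad <- labels[w != w[1L]][1L]
      stop("alignment records differ in length (first offender: '",
           bad, "')", call. = FALSE)
    }
    bad_chars <- gsub(sprintf("[%s]", ALPHABET_RE), "", paste(seqs, collapse = ""))
    if (nzchar(bad_chars)) {
      stop("invalid characters in sequences: ",
           paste(unique(strsplit(bad_chars, "")[[1L]]), collapse = " "),
           call. = FALSE)
    }
  }
  structure(
    list(labels = labels, seqs = seqs, n = length(seqs),
         width = nchar(seqs[1L])),
    class = "seq_alignment"
  )
}

# IUPAC nucleotides + gap + missing; U is normalized away before validation
ALPHABET_RE <- "ACGTRYSWKMBDHVN?-"

normalize_sequence <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(as.character(x))))
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d records x %d columns\n", x$n, x$width))
  show <- utils::head(seq_len(x$n), 6L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 50L) s <- paste0(substr(s, 1L, 50L), "...")
    cat(sprintf("  %-30s %s\n", x$labels[i], s))
  }
  if (x$n > 6L) cat(sprintf("  ... and %d more\n", x$n - 6L))
  invisible(x)
}

#' @method as.matrix seq_alignment
#' @export
as.matrix.seq_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$labels
  m
}

#' Integer encoding of an alignment
#'
#' Encodes A, C, G, T as 1..4 and every other character (gaps, `?`, `N`,
#' IUPAC ambiguity codes) as 0, the "not comparable" state used by
#' pairwise deletion.
#'
#' @param x a `seq_alignment`, or a character vector of sequences.
#' @return integer matrix, one row per record.
#' @keywords internal
encode_alignment <- function(x) {
  seqs <- if (inherits(x, "seq_alignment")) x$seqs else normalize_sequence(x)
  m <- do.call(rbind, lapply(seqs, encode_sequence))
  if (inherits(x, "seq_alignment")) rownames(m) <- x$labels
  m
}

encode_sequence <- function(s) {
  map <- integer(256)
  map[utf8ToInt("A")] <- 1L
  map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L
  map[utf8ToInt("T")] <- 4L
  map[utf8ToInt(s)]
}

decode_sequence <- function(v) {
  paste(c("-", "A", "C", "G", "T")[v + 1L], collapse = "")
}

#' Read a FASTA file
#'
#' Records are returned in file order, sequences uppercased with U mapped
#' to T. When an alignment is requested (the default), equal record
#' lengths are enforced.
#'
#' @param path path to a FASTA file.
#' @param as_alignment require equal lengths and return a `seq_alignment`;
#'   if `FALSE`, returns a named character vector of sequences.
#' @return a `seq_alignment` (or named character vector).
#' @export
read_fasta <- function(path, as_alignment = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- as.character(set)
  labels <- names(set)
  if (!as_alignment) {
    return(stats::setNames(normalize_sequence(seqs), labels))
  }
  seq_alignment(labels, seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln a `seq_alignment`.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70L) {
  stopifnot(inherits(aln, "seq_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(aln$n)) {
    writeLines(paste0(">", aln$labels[i]), con)
    s <- aln$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a NEXUS alignment
#'
#' Parses the matrix of a `DATA` or `CHARACTERS` block, accepting both
#' sequential and interleaved layouts. Quoted taxon labels are preserved
#' verbatim minus the quotes (so labels such as `'Agaricia fragilis'`
#' keep their internal spaces).
#'
#' @param path path to a NEXUS file.
#' @return a `seq_alignment`.
#' @export
read_nexus_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("#NEXUS", lines[1L], ignore.case = TRUE)) {
    stop("not a NEXUS file (missing #NEXUS header): ", path, call. = FALSE)
  }
  txt <- paste(lines, collapse = "\n")
  # strip [...] comments (non-nested, the common case)
  txt <- gsub("\\[[^]]*\\]", "", txt)
  block <- regmatches(
    txt,
    regexpr("(?is)begin\\s+(data|characters)\\s*;.*?\\bend\\s*;", txt, perl = TRUE)
  )
  if (length(block) == 0L) {
    stop("no DATA or CHARACTERS block found in ", path, call. = FALSE)
  }
  mat <- regmatches(
    block,
    regexpr("(?is)\\bmatrix\\b(.*?);", block, perl = TRUE)
  )
  if (length(mat) == 0L) stop("no MATRIX found in ", path, call. = FALSE)
  body <- sub("(?is)^\\s*matrix\\b", "", mat, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n", fixed = TRUE)[[1L]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]

  labels <- character(0)
  chunks <- list()
  for (row in rows) {
    if (grepl("^'", row)) {
      close_q <- regexpr("'", substring(row, 2L), fixed = TRUE)
      if (close_q < 0L) stop("unterminated quoted label in ", path, call. = FALSE)
      lab <- substr(row, 2L, close_q)
      rest <- substring(row, close_q + 2L)
    } else {
      sp <- regexpr("\\s", row)
      if (sp < 0L) stop("matrix row without sequence: '", row, "'", call. = FALSE)
      lab <- substr(row, 1L, sp - 1L)
      rest <- substring(row, sp + 1L)
    }
    seqpart <- gsub("\\s+", "", rest)
    if (!nzchar(seqpart)) next
    if (lab %in% labels) {
      chunks[[lab]] <- c(chunks[[lab]], seqpart)
    } else {
      labels <- c(labels, lab)
      chunks[[lab]] <- seqpart
    }
  }
  if (length(labels) == 0L) stop("empty MATRIX in ", path, call. = FALSE)
  seqs <- vapply(chunks[labels], paste, character(1L), collapse = "")
  seq_alignment(labels, unname(seqs))
}
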