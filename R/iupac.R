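#' @useDynLib tagtrimr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC nucleotide ambiguity codes -> the set of concrete bases each accepts.
# U is normalized to T on ingest, so it does not appear here.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

READ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate and normalize an IUPAC tag sequence
#'
#' Upper-cases the sequence, converts U to T and checks every letter against
#' the IUPAC nucleotide alphabet.
#'
#' @param sequence Tag sequence (character scalar).
#' @return Normalized upper-case sequence.
#' @keywords internal
normalize_tag <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("tag sequence must be a non-empty character scalar", call. = FALSE)
  }
  s <- chartr("u", "t", sequence)
  s <- toupper(chartr("U", "T", s))
  letters <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!letters %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC letter '%s' at tag position %d",
                 letters[bad[1L]], bad[1L]), call. = FALSE)
  }
  s
}

#' Define a tag sequence bound to a read end
#'
#' A tag is any artificial sequence introduced at a read end by library
#' preparation (amplification primer, adaptor, MID barcode).  IUPAC
#' ambiguity codes act as wildcards: Y matches C or T, N matches any base.
#'
#' @param sequence Tag sequence over the IUPAC nucleotide alphabet
#'   (case-insensitive; U is converted to T).
#' @param end Which read end the tag belongs to: `"5"` or `"3"`.
#' @return A `tag_spec` object with elements `sequence`, `end` and length `m`.
#' @examples
#' tag_spec("GTGGTGTGTTGGGTGTGTTTGGNNNNNNNNN", "5")
#' @export
tag_spec <- function(sequence, end = c("5", "3")) {
  end <- match.arg(as.character(end), c("5", "3"))
  s <- normalize_tag(sequence)
  structure(list(sequence = s, end = end, m = nchar(s)), class = "tag_spec")
}

#' @export
print.tag_spec <- function(x, ...) {
  cat(sprintf("<tag_spec> %s'-end, %d bp: %s\n", x$end, x$m, x$sequence))
  invisible(x)
}

#' Build per-letter acceptance masks for a tag
#'
#' Expands the IUPAC codes of a tag into a position-by-letter acceptance
#' matrix: entry (i, c) is TRUE iff tag position i accepts read letter c.
#' This is the one-time pattern pre-processing of the matcher; it never
#' touches read data.  A read N is treated as a low-quality signal, not a
#' wildcard: it is accepted only where the tag itself has N.
#'
#' @param tag A [tag_spec()] (or a raw IUPAC string).
#' @return Logical matrix with one row per tag position and columns
#'   A, C, G, T, N.
#' @examples
#' build_masks("AYG")
#' @export
build_masks <- function(tag) {
  if (!inherits(tag, "tag_spec")) tag <- tag_spec(tag, "5")
  letters <- strsplit(tag$sequence, "", fixed = TRUE)[[1L]]
  m <- matrix(FALSE, nrow = length(letters), ncol = 5L,
              dimnames = list(NULL, READ_ALPHABET))
  for (i in seq_along(letters)) {
    m[i, IUPAC_SETS[[letters[i]]]] <- TRUE
    if (letters[i] == "N") m[i, "N"] <- TRUE
  }
  m
}

# Validate a read sequence: non-empty, A/C/G/T/N only (after normalization).
check_read_text <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("read sequence must be a character scalar", call. = FALSE)
  }
  if (!nzchar(text)) stop("read sequence is empty", call. = FALSE)
  if (grepl("[^ACGTN]", text)) {
    bad <- regmatches(text, regexpr("[^ACGTN]", text))
    stop(sprintf("invalid read letter '%s' (reads must be A/C/G/T/N)", bad),
         call. = FALSE)
  }
  invisible(text)
}

# Normalize read sequences on ingest: upper-case, U->T, IUPAC wildcards
# other than N -> N.  Letters outside the IUPAC nucleotide alphabet (e.g.
# protein data) are reported, not converted.  Returns the vector plus a
# count of converted wildcard letters and the index of the first bad
# record (NA when clean).
normalize_reads <- function(seqs) {
  s <- toupper(seqs)
  s <- chartr("U", "T", s)
  bad <- grep("[^ACGTNRYSWKMBDHV]", s)
  wild <- "[RYSWKMBDHV]"
  n_before <- sum(nchar(s) - nchar(gsub(wild, "", s)))
  if (n_before > 0) s <- gsub(wild, "N", s)
  list(seq = s, n_converted = n_before,
       first_bad = if (length(bad)) bad[1L] else NA_integer_)
}

reverse_string <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
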