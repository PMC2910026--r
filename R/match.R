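#' Semi-global edit distance of a tag against a read
#'
#' Computes, for every read position, the minimum unit-cost edit distance
#' (insertions, deletions, substitutions) between the tag and any read
#' substring ending there; gaps flanking the tag in the read are free, so
#' the tag is matched against a substring of the read.  The computation
#' uses a bit-parallel encoding of the dynamic-programming column
#' differences, blocked into 64-bit words so tags of any length are
#' supported.  IUPAC wildcards in the tag match their base sets at cost 0.
#'
#' @param tag A [tag_spec()] or IUPAC string.
#' @param text Read sequence over A/C/G/T/N.
#' @return List with `distance` (the minimum over all end positions),
#'   `end_positions` (0-based read indices of the last matched base
#'   achieving it) and `columns` (per-position minima, one per read base).
#' @examples
#' semiglobal_distance("GTGGTGTGTTGGGTGTGTTTGG", "GTGGTGTGTTGGTGTGTTGG")$distance
#' @export
semiglobal_distance <- function(tag, text) {
  if (!inherits(tag, "tag_spec")) tag <- tag_spec(tag, "5")
  check_read_text(text)
  cols <- myers_column_minima(build_masks(tag), text)
  d <- min(cols)
  list(distance = d, end_positions = which(cols == d) - 1L, columns = cols)
}

#' Default end-search window length
#'
#' The window searched for a tag of length `m` at a read end spans the
#' first (or last) `max(10, floor(3 m / 2))` bases: half a tag length of
#' slack beyond the tag itself, with a floor of 10 for very short tags.
#'
#' @param m Tag length (positive integer).
#' @return Window length in bases.
#' @examples
#' default_search_range(31)  # 46
#' @export
default_search_range <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("tag length m must be a positive integer", call. = FALSE)
  }
  max(10L, as.integer(floor(3 * m / 2)))
}

# Interpret a mismatch threshold that may be an absolute count ("3", 3) or
# a percentage of the tag length ("10%" -> floor(0.10 * m)).
resolve_mismatches <- function(x, m) {
  if (is.character(x) && grepl("%$", x)) {
    p <- suppressWarnings(as.numeric(sub("%$", "", x)))
    if (is.na(p) || p < 0) stop("invalid mismatch percentage: ", x, call. = FALSE)
    return(as.integer(floor(p * m / 100)))
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v < 0) stop("invalid mismatch threshold: ", x, call. = FALSE)
  as.integer(v)
}

# Recover the start of a match with chosen 0-based exclusive end `e` and
# distance d: run the matcher on the reversed tag against the reversed
# prefix text[1..e]; the largest reversed end position achieving d gives
# the smallest start, i.e. the longest consistent extent.
match_start <- function(masks, text, e, d) {
  rev_masks <- masks[rev(seq_len(nrow(masks))), , drop = FALSE]
  rtext <- reverse_string(substr(text, 1L, e))
  cols <- myers_column_minima(rev_masks, rtext)
  jr <- max(which(cols == d))
  e - jr
}

# Selection rule shared by all searches: a perfect match is taken at its
# first end position (the matcher stops there); otherwise the minimum
# distance wins, ties broken toward the larger trimmed extent (later end).
select_end <- function(cols, max_mm, early_exit = TRUE) {
  if (early_exit) {
    z <- which(cols == 0L)
    if (length(z)) return(list(j = z[1L], d = 0L))
  }
  ok <- which(cols <= max_mm)
  if (!length(ok)) return(NULL)
  d <- min(cols[ok])
  if (d == 0L) return(list(j = which(cols == 0L)[1L], d = 0L))
  list(j = max(which(cols == d)), d = d)
}

#' Locate a tag at one read end
#'
#' Searches the 5'-end window (read prefix) or 3'-end window (read suffix,
#' handled by matching the reversed tag against the reversed suffix and
#' mapping coordinates back) for the best tag occurrence within the
#' mismatch budget.  The search stops at the first perfect match;
#' otherwise the lowest-distance match is returned, ties resolved toward
#' trimming more of the read, since residual tag bases are worse for
#' downstream analysis than one extra trimmed base.
#'
#' @param sequence Read sequence.
#' @param tag A [tag_spec()]; its `end` selects the window.
#' @param max_mismatches Maximum edit operations allowed (integer, or
#'   percentage string such as `"10%"` of the tag length).
#' @param search_range Window length in bases, or `"auto"` for
#'   [default_search_range()] of the tag length.
#' @param early_exit Stop at the first perfect match (the default); kept
#'   switchable so the optimization can be verified not to change results.
#' @return A `tag_match` list (`start`, `end` 0-based half-open on the
#'   read, `distance`, `category`) or `NULL` when no match qualifies.
#' @export
find_tag_at_end <- function(sequence, tag, max_mismatches,
                            search_range = "auto", early_exit = TRUE) {
  stopifnot(inherits(tag, "tag_spec"))
  if (identical(search_range, "auto")) search_range <- default_search_range(tag$m)
  if (search_range < 1) stop("search_range must be >= 1", call. = FALSE)
  max_mismatches <- resolve_mismatches(max_mismatches, tag$m)
  len <- nchar(sequence)
  if (len == 0L) return(NULL)
  L <- min(search_range, len)
  masks <- build_masks(tag)
  if (tag$end == "5") {
    window <- substr(sequence, 1L, L)
    cols <- myers_column_minima(masks, window)
    sel <- select_end(cols, max_mismatches, early_exit)
    if (is.null(sel)) return(NULL)
    s <- match_start(masks, window, sel$j, sel$d)
    tag_match(s, sel$j, sel$d, "END5")
  } else {
    window <- reverse_string(substr(sequence, len - L + 1L, len))
    rmasks <- masks[rev(seq_len(nrow(masks))), , drop = FALSE]
    cols <- myers_column_minima(rmasks, window)
    sel <- select_end(cols, max_mismatches, early_exit)
    if (is.null(sel)) return(NULL)
    s <- match_start(rmasks, window, sel$j, sel$d)
    # interval [s, j) in the reversed suffix maps to [len-j, len-s)
    tag_match(len - sel$j, len - s, sel$d, "END3")
  }
}

tag_match <- function(start, end, distance, category, read_id = NA_character_) {
  structure(list(read_id = read_id, start = as.integer(start),
                 end = as.integer(end), distance = as.integer(distance),
                 category = category),
            class = "tag_match")
}

#' @export
print.tag_match <- function(x, ...) {
  cat(sprintf("<tag_match> %s [%d, %d) distance %d\n",
              x$category, x$start, x$end, x$distance))
  invisible(x)
}

#' Repeatedly trim a tag from one read end
#'
#' Concatenated tag copies at a read end (tag repeats) are removed by
#' re-running the end search after each trim until no further match is
#' found.  A read consumed entirely is flagged as a tag repeat; its empty
#' residue is later removed by the length filter.
#'
#' @inheritParams find_tag_at_end
#' @return List with `sequence` (the residue), `matches` (each with
#'   coordinates on the original read) and `tag_repeat` flag.
#' @export
continuous_trim <- function(sequence, tag, max_mismatches,
                            search_range = "auto") {
  matches <- list()
  residue <- sequence
  offset <- 0L
  repeat {
    if (!nzchar(residue)) break
    m <- find_tag_at_end(residue, tag, max_mismatches, search_range)
    if (is.null(m)) break
    if (tag$end == "5") {
      m$start <- m$start + offset
      m$end <- m$end + offset
      offset <- offset + (m$end - offset)  # advance by trimmed extent
      matches[[length(matches) + 1L]] <- m
      residue <- substr(sequence, offset + 1L, nchar(sequence))
    } else {
      matches[[length(matches) + 1L]] <- m
      residue <- substr(residue, 1L, m$start)
    }
  }
  list(sequence = residue, matches = matches,
       tag_repeat = !nzchar(residue) && length(matches) > 0L)
}

#' Find internal tag occurrences
#'
#' After the read ends are trimmed, remaining tag (or junction) copies
#' inside the read indicate tag repeats or fragment-to-fragment
#' concatenations.  All qualifying occurrences are located and selected
#' greedily by lowest distance, then leftmost end position; candidates
#' overlapping already-selected occurrences or the excluded end intervals
#' are dropped.
#'
#' @inheritParams find_tag_at_end
#' @param pattern A [tag_spec()] to search for anywhere in the read.
#' @param exclude List of 0-based half-open intervals (already-matched end
#'   regions) that occurrences must not overlap.
#' @return List of `tag_match` objects (category `"INTERNAL"`), possibly
#'   empty.
#' @export
find_internal <- function(sequence, pattern, max_mismatches, exclude = list()) {
  stopifnot(inherits(pattern, "tag_spec"))
  max_mismatches <- resolve_mismatches(max_mismatches, pattern$m)
  if (!nzchar(sequence)) return(list())
  masks <- build_masks(pattern)
  cols <- myers_column_minima(masks, sequence)
  cand <- which(cols <= max_mismatches)
  if (!length(cand)) return(list())
  ord <- cand[order(cols[cand], cand)]
  overlaps <- function(s1, e1, iv) s1 < iv[[2L]] && iv[[1L]] < e1
  accepted <- list()
  taken <- exclude
  for (j in ord) {
    d <- cols[j]
    s <- match_start(masks, sequence, j, d)
    if (any(vapply(taken, function(iv) overlaps(s, j, iv), logical(1L)))) next
    accepted[[length(accepted) + 1L]] <- tag_match(s, j, d, "INTERNAL")
    taken[[length(taken) + 1L]] <- c(s, j)
  }
  accepted
}
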