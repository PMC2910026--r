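#' Junction pattern for concatenation detection
#'
#' Two blunt-end ligated fragments leave the 3'-end tag of the first
#' immediately followed by the 5'-end tag of the second inside the read;
#' the concatenated pattern tag3.tag5 is searched as a single IUPAC tag
#' (quasi-random N segments stay N).
#'
#' @param tag5,tag3 [tag_spec()] objects for the two ends, or `NULL`.
#' @return A [tag_spec()] (bound to the 5' end for matching purposes), or
#'   `NULL` when either tag is missing (splitting disabled).
#' @export
junction_pattern <- function(tag5, tag3) {
  if (is.null(tag5) || is.null(tag3)) {
    message("junction splitting disabled: both tags must be defined")
    return(NULL)
  }
  stopifnot(inherits(tag5, "tag_spec"), inherits(tag3, "tag_spec"))
  tag_spec(paste0(tag3$sequence, tag5$sequence), "5")
}

#' Detect tag-to-tag junctions inside a read
#'
#' Searches the (already end-trimmed) read for internal occurrences of the
#' concatenated tag pattern.  With `max_mismatches = 0` only exact
#' junctions are reported, the conservative setting that avoids false
#' splits.
#'
#' @param sequence Read sequence (end-trimmed).
#' @param pattern Junction pattern from [junction_pattern()].
#' @param max_mismatches Edit-operation budget for the junction.
#' @param exclude 0-based half-open intervals to avoid (already-matched
#'   end regions, when searching untrimmed reads).
#' @return List of `tag_match` objects (category `"INTERNAL"`).
#' @export
detect_junctions <- function(sequence, pattern, max_mismatches = 0L,
                             exclude = list()) {
  if (is.null(pattern)) return(list())
  find_internal(sequence, pattern, max_mismatches, exclude)
}

#' Split a read at its junctions
#'
#' Removes the junction intervals and returns the flanking fragments in
#' read order; n junctions give n + 1 fragments.  Fragment ids append a
#' 1-based ordinal (`"readid.1"`, `"readid.2"`, ...) so FASTA output keeps
#' unique ids; a read without junctions keeps its id unchanged.
#'
#' @param id Read id.
#' @param sequence Read sequence.
#' @param junctions Non-overlapping `tag_match` list, any order.
#' @param quality Optional quality string of the same length.
#' @return Data frame with columns id, parent_id, ordinal, seq, qual.
#' @export
split_read <- function(id, sequence, junctions, quality = NA_character_) {
  if (!length(junctions)) {
    return(data.frame(id = id, parent_id = id, ordinal = NA_integer_,
                      seq = sequence, qual = quality, stringsAsFactors = FALSE))
  }
  ord <- order(vapply(junctions, `[[`, integer(1L), "start"))
  junctions <- junctions[ord]
  starts <- vapply(junctions, `[[`, integer(1L), "start")
  ends <- vapply(junctions, `[[`, integer(1L), "end")
  cut_from <- c(0L, ends)
  cut_to <- c(starts, nchar(sequence))
  frag <- substring(sequence, cut_from + 1L, cut_to)
  qual <- if (!is.na(quality)) substring(quality, cut_from + 1L, cut_to) else
    rep(NA_character_, length(frag))
  data.frame(id = paste0(id, ".", seq_along(frag)), parent_id = id,
             ordinal = seq_along(frag), seq = frag, qual = qual,
             stringsAsFactors = FALSE)
}
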