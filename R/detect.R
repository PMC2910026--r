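#' Terminal k-mers of a read set
#'
#' Extracts the first (5') or last (3') `k` bases of every read; reads
#' shorter than `k` are skipped.  These terminal k-mers drive the shift
#' correction of the frequency profile: a read whose tag lost or gained
#' bases at the end carries a shifted variant of the dominant k-mer.
#'
#' @param seqs Character vector of read sequences.
#' @param k k-mer length (default 5).
#' @param end `"5"` or `"3"`.
#' @return Named integer vector of k-mer counts.
#' @export
extract_end_kmers <- function(seqs, k = 5L, end = c("5", "3")) {
  end <- match.arg(as.character(end), c("5", "3"))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (!length(seqs)) stop("empty read set", call. = FALSE)
  len <- nchar(seqs)
  seqs <- seqs[len >= k]
  len <- len[nchar(seqs) >= k]
  if (!length(seqs)) stop("no read is at least k bases long", call. = FALSE)
  km <- if (end == "5") substr(seqs, 1L, k) else
    substr(seqs, nchar(seqs) - k + 1L, nchar(seqs))
  tab <- table(km)
  stats::setNames(as.integer(tab), names(tab))
}

#' Retain and rank frequent terminal k-mers
#'
#' Keeps k-mers present in at least `min_fraction` of the reads (default
#' 10\%) and orders them by decreasing count; equal counts are ordered
#' lexicographically so the ranking is deterministic.
#'
#' @param counts Named count vector from [extract_end_kmers()].
#' @param n_reads Number of reads the counts were drawn from.
#' @param min_fraction Minimum fraction of reads a k-mer must reach.
#' @return Named integer vector, ranked; error with class
#'   `"tagtrimr_no_signal"` when nothing passes (tag-free data).
#' @export
filter_and_rank_kmers <- function(counts, n_reads, min_fraction = 0.10) {
  stopifnot(n_reads >= 1)
  keep <- counts[counts >= min_fraction * n_reads]
  if (!length(keep)) {
    stop(structure(class = c("tagtrimr_no_signal", "error", "condition"),
                   list(message = "no conserved end signal: no k-mer reaches the frequency threshold",
                        call = NULL)))
  }
  keep[order(-keep, names(keep))]
}

# Gapless alignment of `candidate` against `anchor` by shifting candidate
# left (negative l) or right (positive l).  Offset s means candidate[i]
# faces anchor[i + s]; all overlapping positions must agree.  Returns the
# smallest |l| <= max_shift, "+l"/"-l" signed, 0, or the ambiguous marker
# when both directions tie; NULL when nothing aligns.
#' Shift alignment of two k-mers
#'
#' @param anchor Higher-frequency k-mer (or the growing consensus).
#' @param candidate k-mer to align.
#' @param max_shift Maximum shift operations allowed (default 2).
#' @return List with `shift` (signed integer) and `ambiguous` (TRUE when
#'   both directions tie, the plus-or-minus case), or `NULL` when no
#'   shift within the budget aligns the k-mers.
#' @examples
#' align_shift("ACACA", "CACAC")  # ambiguous shift of 1
#' @export
align_shift <- function(anchor, candidate, max_shift = 2L) {
  a <- strsplit(anchor, "", fixed = TRUE)[[1L]]
  c_ <- strsplit(candidate, "", fixed = TRUE)[[1L]]
  la <- length(a); lc <- length(c_)
  fits <- function(s) {
    i <- seq_len(lc)
    j <- i + s
    ok <- j >= 1L & j <= la
    if (!any(ok)) return(FALSE)
    all(c_[i[ok]] == a[j[ok]])
  }
  if (fits(0L)) return(list(shift = 0L, ambiguous = FALSE))
  for (l in seq_len(max_shift)) {
    right <- fits(l)
    left <- fits(-l)
    if (right && left) return(list(shift = l, ambiguous = TRUE))
    if (right) return(list(shift = l, ambiguous = FALSE))
    if (left) return(list(shift = -l, ambiguous = FALSE))
  }
  NULL
}

#' Agglomerate ranked k-mers into a consensus
#'
#' Starting from the most frequent k-mer, each further k-mer is aligned
#' (without gaps, within the shift budget) against the current consensus;
#' on success it is joined, extending the consensus by its overhang, and
#' its shift relative to the top k-mer is recorded.  Unalignable k-mers
#' are deferred to the end of the list and retried until a full pass joins
#' nothing.  Ambiguously alignable k-mers (both directions tie) receive
#' the absolute shift with an ambiguity flag and do not extend the
#' consensus.
#'
#' @param ranked Named count vector from [filter_and_rank_kmers()].
#' @param max_shift Maximum shift operations (default 2).
#' @return List with `consensus` (string) and `assignments` (data frame:
#'   kmer, count, shift, ambiguous).
#' @export
merge_kmers <- function(ranked, max_shift = 2L) {
  kmers <- names(ranked)
  consensus <- kmers[1L]
  cons_off <- 0L  # offset of consensus[1] relative to the top k-mer's start
  asg <- data.frame(kmer = kmers[1L], count = unname(ranked[1L]),
                    shift = 0L, ambiguous = FALSE, stringsAsFactors = FALSE)
  queue <- kmers[-1L]
  counts <- ranked[-1L]
  repeat {
    if (!length(queue)) break
    joined_any <- FALSE
    deferred <- character(0)
    dcounts <- integer(0)
    for (i in seq_along(queue)) {
      km <- queue[i]
      al <- align_shift(consensus, km, max_shift)
      if (is.null(al)) {
        deferred <- c(deferred, km)
        dcounts <- c(dcounts, counts[i])
        next
      }
      shift_anchor <- al$shift + cons_off
      asg <- rbind(asg, data.frame(kmer = km, count = unname(counts[i]),
                                   shift = if (al$ambiguous) abs(al$shift) else shift_anchor,
                                   ambiguous = al$ambiguous,
                                   stringsAsFactors = FALSE))
      joined_any <- TRUE
      if (!al$ambiguous) {
        # extend consensus by the candidate's overhang
        s <- al$shift
        cc <- strsplit(consensus, "", fixed = TRUE)[[1L]]
        kk <- strsplit(km, "", fixed = TRUE)[[1L]]
        lo <- min(1L, 1L + s); hi <- max(length(cc), length(kk) + s)
        new <- character(hi - lo + 1L)
        for (p in seq_along(cc)) new[p - lo + 1L] <- cc[p]
        for (p in seq_along(kk)) {
          q <- p + s - lo + 1L
          if (!nzchar(new[q]) || is.na(new[q])) new[q] <- kk[p]
        }
        consensus <- paste(new, collapse = "")
        if (s < 0L) cons_off <- cons_off + s
      }
    }
    queue <- deferred
    counts <- dcounts
    if (!joined_any) break
  }
  list(consensus = consensus, assignments = asg)
}

#' Adjust k-mer shifts to a common end anchor
#'
#' Shifts are re-anchored so the most-shifted variant defines the read
#' end: every 5'-end shift becomes non-negative (adding `a = |min shift|`)
#' and every 3'-end shift non-positive (adding `a = -max shift`).  The
#' top k-mer's adjusted shift equals `a`.  Ambiguous shifts are excluded
#' from the min/max and keep an effective shift of zero.
#'
#' @param assignments Data frame from [merge_kmers()].
#' @param end `"5"` or `"3"`.
#' @return The data frame with an `adjusted` column.
#' @export
adjust_shifts <- function(assignments, end = c("5", "3")) {
  end <- match.arg(as.character(end), c("5", "3"))
  sh <- assignments$shift[!assignments$ambiguous]
  a <- if (end == "5") abs(min(sh)) else -max(sh)
  assignments$adjusted <- ifelse(assignments$ambiguous, 0L,
                                 assignments$shift + a)
  assignments
}

#' Shift-corrected positional nucleotide frequencies
#'
#' Builds the per-position A/C/G/T frequency profile from one read end,
#' positions counted from that end.  Reads whose terminal k-mer carries an
#' adjusted shift contribute their bases displaced away from the end by
#' the shift magnitude, aligning truncated or extended tag variants with
#' the intact ones; unassigned reads contribute unshifted.  Reads with N
#' at a position are excluded from that position's normalization.
#'
#' @param seqs Read sequences.
#' @param assignments `NULL` (raw profile) or the adjusted data frame from
#'   [adjust_shifts()].
#' @param end `"5"` or `"3"`.
#' @param k k-mer length used for the assignments.
#' @param profile_len Number of positions to profile (default 60).
#' @return A `frequency_profile`: list with `end`, `freq` (L x 4 matrix),
#'   `range`, `median`, `support` (reads contributing per position).
#' @export
corrected_frequencies <- function(seqs, assignments = NULL, end = c("5", "3"),
                                  k = 5L, profile_len = 60L) {
  end <- match.arg(as.character(end), c("5", "3"))
  L <- as.integer(profile_len)
  counts <- matrix(0, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  shift_of <- integer(0)
  if (!is.null(assignments)) {
    shift_of <- stats::setNames(abs(assignments$adjusted), assignments$kmer)
  }
  len <- nchar(seqs)
  km <- rep(NA_character_, length(seqs))
  ok <- len >= k
  km[ok] <- if (end == "5") substr(seqs[ok], 1L, k) else
    substr(seqs[ok], len[ok] - k + 1L, len[ok])
  s_read <- ifelse(!is.na(km) & km %in% names(shift_of), shift_of[km], 0L)
  for (r in seq_along(seqs)) {
    n <- len[r]
    if (n == 0L) next
    depth <- min(n, L - s_read[r])
    if (depth < 1L) next
    idx <- seq_len(depth)
    bases <- if (end == "5") {
      strsplit(substr(seqs[r], 1L, depth), "", fixed = TRUE)[[1L]]
    } else {
      rev(strsplit(substr(seqs[r], n - depth + 1L, n), "", fixed = TRUE)[[1L]])
    }
    rows <- idx + s_read[r]
    keep <- bases %in% c("A", "C", "G", "T")
    if (any(keep)) {
      for (b in c("A", "C", "G", "T")) {
        hit <- rows[keep & bases == b]
        if (length(hit)) counts[hit, b] <- counts[hit, b] + 1
      }
    }
  }
  support <- rowSums(counts)
  freq <- counts / ifelse(support > 0, support, 1)
  structure(list(end = end, freq = freq,
                 range = apply(freq, 1L, function(x) max(x) - min(x)),
                 median = apply(freq, 1L, stats::median),
                 support = support),
            class = "frequency_profile")
}

#' Classify profiled positions
#'
#' Applies the range/median rule position by position: a range greater
#' than three times the median marks a specific (fixed) tag base; a range
#' below the median plus the allowed variation (default 0.05 on the
#' frequency scale) marks background sequence; everything between marks a
#' quasi-random (preferred-base) tag position.  Positions supported by
#' fewer than `min_support` reads are classified as background.
#'
#' @param profile A `frequency_profile`.
#' @param variation Allowed absolute frequency variation (default 0.05).
#' @param min_support Minimum contributing reads per position (default 50).
#' @return Character vector of `"SPECIFIC"`, `"QUASI_RANDOM"`,
#'   `"BACKGROUND"` per position.
#' @export
classify_positions <- function(profile, variation = 0.05, min_support = 50L) {
  r <- profile$range
  med <- profile$median
  cls <- ifelse(r > 3 * med, "SPECIFIC",
                ifelse(r < med + variation, "BACKGROUND", "QUASI_RANDOM"))
  cls[profile$support < min_support] <- "BACKGROUND"
  cls
}

#' Predict the tag from classified positions
#'
#' The tag is the maximal run of specific/quasi-random positions starting
#' at the profiled end: specific positions emit their majority base,
#' quasi-random positions emit N.  For the 3' end the run is reversed so
#' the returned tag reads 5'-to-3'.
#'
#' @param classes From [classify_positions()].
#' @param profile The matching `frequency_profile`.
#' @param end `"5"` or `"3"`.
#' @return A [tag_spec()] or `NULL` when the first position is background.
#' @export
predict_tag <- function(classes, profile, end = c("5", "3")) {
  end <- match.arg(as.character(end), c("5", "3"))
  in_tag <- classes %in% c("SPECIFIC", "QUASI_RANDOM")
  if (!length(in_tag) || !in_tag[1L]) return(NULL)
  run_len <- which(!in_tag)[1L] - 1L
  if (is.na(run_len)) run_len <- length(in_tag)
  bases <- vapply(seq_len(run_len), function(i) {
    if (classes[i] == "SPECIFIC") {
      colnames(profile$freq)[which.max(profile$freq[i, ])]
    } else "N"
  }, character(1L))
  if (end == "3") bases <- rev(bases)
  tag_spec(paste(bases, collapse = ""), end)
}

#' Automatic tag detection at one read end
#'
#' Full frequency-based prediction: terminal k-mers are counted, frequent
#' ones ranked and agglomerated into a consensus with shift assignments,
#' shifts are re-anchored at the end, the positional frequency profile is
#' rebuilt with shifted contributions, and positions are classified by the
#' range/median rule to emit the tag.  Reliable recovery of the
#' quasi-random segment of WTA-style tags needs datasets of at least
#' about 1,000 reads.
#'
#' @param seqs Read sequences (character vector).
#' @param end `"5"` or `"3"`.
#' @param k k-mer length (default 5).
#' @param min_fraction Minimum k-mer frequency (default 0.10).
#' @param max_shift Shift budget (default 2).
#' @param variation Classification variation (default 0.05).
#' @param profile_len Profiled positions (default 60).
#' @param min_support Minimum reads per classified position (default 50).
#' @return List with `tag` ([tag_spec()] or `NULL`), `profile`,
#'   `raw_profile`, `classes` and `assignments`.
#' @export
detect_tag <- function(seqs, end = c("5", "3"), k = 5L, min_fraction = 0.10,
                       max_shift = 2L, variation = 0.05, profile_len = 60L,
                       min_support = 50L) {
  end <- match.arg(as.character(end), c("5", "3"))
  raw <- corrected_frequencies(seqs, NULL, end, k, profile_len)
  counts <- extract_end_kmers(seqs, k, end)
  asg <- NULL
  tag <- NULL
  prof <- raw
  ranked <- tryCatch(filter_and_rank_kmers(counts, length(seqs), min_fraction),
                     tagtrimr_no_signal = function(e) NULL)
  if (!is.null(ranked)) {
    merged <- merge_kmers(ranked, max_shift)
    asg <- adjust_shifts(merged$assignments, end)
    prof <- corrected_frequencies(seqs, asg, end, k, profile_len)
    classes <- classify_positions(prof, variation, min_support)
    tag <- predict_tag(classes, prof, end)
  } else {
    classes <- rep("BACKGROUND", profile_len)
  }
  list(tag = tag, profile = prof, raw_profile = raw, classes = classes,
       assignments = asg)
}

#' Frequency profile as a review table
#'
#' @param profile A `frequency_profile`.
#' @param classes Optional classification vector.
#' @return Data frame with position, A/C/G/T frequencies, range, median,
#'   support and class, suitable for writing as TSV for user review.
#' @export
profile_table <- function(profile, classes = NULL) {
  d <- data.frame(position = seq_len(nrow(profile$freq)),
                  round(profile$freq, 4L),
                  range = round(profile$range, 4L),
                  median = round(profile$median, 4L),
                  support = profile$support)
  if (!is.null(classes)) d$class <- classes
  d
}
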