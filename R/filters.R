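#' Filter configuration
#'
#' Bundles the full trimming/filtering parameter set.  Defaults mirror a
#' typical WTA clean-up: up to 3 mismatches per end, automatic search
#' windows, continuous end trimming, no occurrence-based removal, minimum
#' length 50 bp, at most 5\% ambiguous bases, dereplication and junction
#' splitting (up to 3 mismatches) enabled.
#'
#' @param max_mm5,max_mm3 Mismatch budgets per end: integer counts or
#'   percentage strings (`"10%"` of the tag length).
#' @param search_range5,search_range3 Window lengths in bp or `"auto"`
#'   (`max(10, floor(3m/2))`).
#' @param occurrence_mode Which reads to keep by tag occurrence: `"5"`,
#'   `"3"`, `"both"`, `"either"`, `"none"`, or `"keep"` (don't remove).
#' @param continuous Repeatedly trim tag copies from the ends.
#' @param min_len,max_len Length bounds after trimming (inclusive).
#' @param max_n_percent Maximum percentage of N bases (strictly above is
#'   removed).
#' @param dereplicate Remove exact duplicate sequences (after trimming).
#' @param split Split fragment-to-fragment concatenations.
#' @param split_max_mm Mismatch budget for the junction pattern.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_mm5 = 3L, max_mm3 = 3L,
                          search_range5 = "auto", search_range3 = "auto",
                          occurrence_mode = c("keep", "5", "3", "both",
                                              "either", "none"),
                          continuous = TRUE, min_len = 50L, max_len = Inf,
                          max_n_percent = 5, dereplicate = TRUE,
                          split = TRUE, split_max_mm = 3L) {
  occurrence_mode <- match.arg(as.character(occurrence_mode[1L]),
                               c("keep", "5", "3", "both", "either", "none"))
  cfg <- list(max_mm5 = max_mm5, max_mm3 = max_mm3,
              search_range5 = search_range5, search_range3 = search_range3,
              occurrence_mode = occurrence_mode,
              continuous = isTRUE(continuous),
              min_len = as.numeric(min_len), max_len = as.numeric(max_len),
              max_n_percent = as.numeric(max_n_percent),
              dereplicate = isTRUE(dereplicate), split = isTRUE(split),
              split_max_mm = split_max_mm)
  validate_filter_config(cfg)
}

validate_filter_config <- function(cfg) {
  if (cfg$min_len > cfg$max_len) stop("min_len must be <= max_len", call. = FALSE)
  if (cfg$max_n_percent < 0 || cfg$max_n_percent > 100) {
    stop("max_n_percent must be in [0, 100]", call. = FALSE)
  }
  if (cfg$min_len < 0) stop("lengths must be non-negative", call. = FALSE)
  structure(cfg, class = "filter_config")
}

#' Remove exact duplicate sequences
#'
#' Keeps the first occurrence of every distinct sequence string, in input
#' order.  Dereplication runs after trimming: duplicates hidden by
#' variable tag copies only become exact copies once the tags are gone.
#'
#' @param seqs Character vector of sequences.
#' @return List with `keep` (logical vector) and `removed` (count).
#' @export
dereplicate <- function(seqs) {
  keep <- !duplicated(seqs)
  list(keep = keep, removed = sum(!keep))
}

#' Length filter
#' @param seqs Sequences.
#' @param min_len,max_len Inclusive bounds.
#' @return Logical vector: TRUE passes.
#' @export
filter_length <- function(seqs, min_len, max_len = Inf) {
  n <- nchar(seqs)
  n >= min_len & n <= max_len
}

#' Ambiguous-base filter
#'
#' A read fails when its percentage of N bases is strictly above the
#' threshold.  Zero-length reads fail (they are removed by the length
#' filter in the pipeline).
#'
#' @param seqs Sequences.
#' @param max_n_percent Threshold in percent.
#' @return Logical vector: TRUE passes.
#' @export
filter_ambiguous <- function(seqs, max_n_percent) {
  len <- nchar(seqs)
  nN <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  len > 0L & 100 * nN / pmax(len, 1L) <= max_n_percent
}

#' Tag-occurrence filter
#'
#' @param has5,has3 Logical: was a tag matched at the 5'/3' end.
#' @param mode One of `"5"`, `"3"`, `"both"`, `"either"`, `"none"`,
#'   `"keep"`.
#' @return Logical: TRUE passes.
#' @export
filter_occurrence <- function(has5, has3, mode) {
  switch(mode,
         "keep" = rep(TRUE, length(has5)),
         "5" = has5,
         "3" = has3,
         "both" = has5 & has3,
         "either" = has5 | has3,
         "none" = !has5 & !has3,
         stop("unknown occurrence mode: ", mode, call. = FALSE))
}

trim_one_end <- function(sequence, tag, max_mm, range, continuous) {
  if (continuous) {
    ct <- continuous_trim(sequence, tag, max_mm, range)
    list(sequence = ct$sequence, matches = ct$matches,
         tag_repeat = ct$tag_repeat)
  } else {
    m <- find_tag_at_end(sequence, tag, max_mm, range)
    if (is.null(m)) return(list(sequence = sequence, matches = list(),
                                tag_repeat = FALSE))
    res <- if (tag$end == "5") substr(sequence, m$end + 1L, nchar(sequence))
    else substr(sequence, 1L, m$start)
    list(sequence = res, matches = list(m), tag_repeat = !nzchar(res))
  }
}

#' Run the full trim/split/filter pipeline
#'
#' Stage order: 5'-end trimming (continuous if configured), 3'-end
#' trimming on the already 5'-trimmed read, junction detection and
#' splitting on the residue, then per-record length, ambiguous-base and
#' tag-occurrence filters, and finally dereplication of the passing
#' records (after trimming, so duplicates masked by variable tag copies
#' are caught).  Failing reads are emitted unchanged (untrimmed) so both
#' streams can be inspected; every input read is accounted for in exactly
#' one output stream per record.
#'
#' @param reads Data frame with columns `id`, `seq` and optionally `qual`,
#'   `desc` (as returned by [read_sequences()]).
#' @param tag5,tag3 [tag_spec()] objects or `NULL`.
#' @param config A [filter_config()].
#' @return List with `passing`, `failing` (data frames in `reads` layout
#'   plus `fate`) and `report` (one row per output record: id, parent_id,
#'   init_len, trim_len, trim5, trim3, mm5, mm3, frags, junction_mm,
#'   fate).
#' @export
run_pipeline <- function(reads, tag5 = NULL, tag3 = NULL,
                         config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (!nrow(reads)) {
    empty <- reads[0, , drop = FALSE]
    empty$fate <- character(0)
    return(list(passing = empty, failing = empty,
                report = data.frame()))
  }
  if (is.null(reads$qual)) reads$qual <- NA_character_
  if (is.null(reads$desc)) reads$desc <- NA_character_
  jpat <- if (config$split && !is.null(tag5) && !is.null(tag3)) {
    junction_pattern(tag5, tag3)
  } else NULL

  rows <- vector("list", nrow(reads))
  for (r in seq_len(nrow(reads))) {
    id <- reads$id[r]; s0 <- reads$seq[r]; q0 <- reads$qual[r]
    init_len <- nchar(s0)
    s <- s0; q <- q0
    off5 <- 0L
    m5 <- list(); m3 <- list()
    tag_repeat <- FALSE
    if (!is.null(tag5) && nzchar(s)) {
      t5 <- trim_one_end(s, tag5, config$max_mm5, config$search_range5,
                         config$continuous)
      m5 <- t5$matches
      tag_repeat <- tag_repeat || t5$tag_repeat
      if (length(m5)) {
        off5 <- max(vapply(m5, `[[`, integer(1L), "end"))
        s <- t5$sequence
        if (!is.na(q)) q <- substr(q0, off5 + 1L, init_len)
      }
    }
    trim3_start <- init_len  # on the original read, first trimmed 3' base
    if (!is.null(tag3) && nzchar(s)) {
      t3 <- trim_one_end(s, tag3, config$max_mm3, config$search_range3,
                         config$continuous)
      m3 <- t3$matches
      tag_repeat <- tag_repeat || t3$tag_repeat
      if (length(m3)) {
        trim3_start <- off5 + min(vapply(m3, `[[`, integer(1L), "start"))
        s <- t3$sequence
        if (!is.na(q)) q <- substr(q, 1L, nchar(s))
      }
    }
    mm5 <- if (length(m5)) min(vapply(m5, `[[`, integer(1L), "distance")) else NA_integer_
    mm3 <- if (length(m3)) min(vapply(m3, `[[`, integer(1L), "distance")) else NA_integer_

    juncs <- if (!is.null(jpat) && nzchar(s)) {
      detect_junctions(s, jpat, config$split_max_mm)
    } else list()
    frags <- split_read(id, s, juncs, q)
    jmm <- if (length(juncs)) min(vapply(juncs, `[[`, integer(1L), "distance")) else NA_integer_

    occ_pass <- filter_occurrence(length(m5) > 0L, length(m3) > 0L,
                                  config$occurrence_mode)
    frows <- vector("list", nrow(frags))
    for (f in seq_len(nrow(frags))) {
      fs <- frags$seq[f]
      fate <- "PASS"
      if (!filter_length(fs, config$min_len, config$max_len)) {
        fate <- if (tag_repeat && !nzchar(fs)) "FILTERED_tag_repeat" else
          "FILTERED_length"
      } else if (!filter_ambiguous(fs, config$max_n_percent)) {
        fate <- "FILTERED_ambiguous"
      } else if (!occ_pass) {
        fate <- "FILTERED_occurrence"
      }
      frows[[f]] <- data.frame(
        id = frags$id[f], parent_id = id, init_len = init_len,
        trim_len = nchar(fs), trim5 = off5, trim3 = trim3_start,
        mm5 = mm5, mm3 = mm3, frags = nrow(frags), junction_mm = jmm,
        seq = fs, qual = frags$qual[f], desc = reads$desc[r],
        orig_seq = s0, orig_qual = q0, fate = fate,
        stringsAsFactors = FALSE)
    }
    rows[[r]] <- do.call(rbind, frows)
  }
  rep_all <- do.call(rbind, rows)

  # dereplication last, on the records that survived everything else
  if (config$dereplicate) {
    idx <- which(rep_all$fate == "PASS")
    if (length(idx)) {
      dr <- dereplicate(rep_all$seq[idx])
      rep_all$fate[idx[!dr$keep]] <- "FILTERED_duplicate"
    }
  }

  pass <- rep_all$fate == "PASS"
  passing <- data.frame(id = rep_all$id[pass], seq = rep_all$seq[pass],
                        qual = rep_all$qual[pass], desc = rep_all$desc[pass],
                        fate = rep_all$fate[pass], stringsAsFactors = FALSE)
  # failing reads are written without any changes (original sequence for
  # unsplit reads; the fragment itself for a failing split product)
  fail_seq <- ifelse(rep_all$frags[!pass] > 1L, rep_all$seq[!pass],
                     rep_all$orig_seq[!pass])
  fail_qual <- ifelse(rep_all$frags[!pass] > 1L, rep_all$qual[!pass],
                      rep_all$orig_qual[!pass])
  failing <- data.frame(id = rep_all$id[!pass], seq = fail_seq,
                        qual = fail_qual, desc = rep_all$desc[!pass],
                        fate = rep_all$fate[!pass], stringsAsFactors = FALSE)
  report <- rep_all[, c("id", "parent_id", "init_len", "trim_len", "trim5",
                        "trim3", "mm5", "mm3", "frags", "junction_mm",
                        "fate")]
  rownames(report) <- NULL
  list(passing = passing, failing = failing, report = report)
}

#' Mismatch-bucket summary of a pipeline report
#'
#' Tallies reads by their best end-match distance into buckets 0-5 and
#' ">5" (unmatched reads count as ">5") for the 5' end, the 3' end and
#' detected junctions, mirroring how tag-matching results are commonly
#' summarized.
#'
#' @param report Report data frame from [run_pipeline()].
#' @return Matrix of counts, rows `end5`/`end3`/`concatenated`, columns
#'   `0`..`5`, `>5`.
#' @export
mismatch_summary <- function(report) {
  per_parent <- report[!duplicated(report$parent_id), ]
  bucket <- function(x) {
    b <- ifelse(is.na(x) | x > 5L, ">5", as.character(x))
    factor(b, levels = c(as.character(0:5), ">5"))
  }
  jn <- per_parent$junction_mm[!is.na(per_parent$junction_mm)]
  rbind(end5 = table(bucket(per_parent$mm5)),
        end3 = table(bucket(per_parent$mm3)),
        concatenated = table(bucket(jn)))
}
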