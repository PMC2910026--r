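#' Built-in WTA tag sequences
#'
#' The Whole Transcriptome Amplification primer pair used as the package's
#' reference tags: a 31 bp 5'-end tag (22 fixed bases followed by 9
#' quasi-random N positions) and a 30 bp 3'-end tag (9 N positions
#' followed by 21 fixed bases).
#'
#' @return List with elements `tag5` and `tag3` ([tag_spec()] objects).
#' @export
wta_tags <- function() {
  list(tag5 = tag_spec("GTGGTGTGTTGGGTGTGTTTGGNNNNNNNNN", "5"),
       tag3 = tag_spec("NNNNNNNNNCCAAACACACCCAACACACCA", "3"))
}

#' Synthetic tagged-read generator configuration
#'
#' The generator emulates the read structure of a WTA-amplified,
#' pyrosequenced metagenome: each read is a noisy 5' tag copy, an insert
#' of i.i.d. uniform bases, and (read length permitting) a noisy 3' tag
#' copy, truncated at the instrument read-length cap so long inserts lose
#' part or all of their 3' tag.  Quasi-random (N) tag positions are
#' instantiated from a fixed per-position base preference, as WTA primers
#' show preferred rather than uniform bases there.  Indels follow the
#' homopolymer bias of pyrosequencing: two thirds are placed adjacent to
#' a repeated base of the tag.  Blunt-end concatenation events join two
#' fragments around an internal tag3.tag5 junction.
#'
#' @param n_reads Number of reads.
#' @param tag5,tag3 [tag_spec()] objects (default [wta_tags()]).
#' @param insert_min,insert_max Insert length bounds (uniform), default
#'   100-1000 bp as for WTA fragments.
#' @param indel_rate Probability that a tag copy carries one indel.
#' @param substitution_rate Per-base substitution probability within tag
#'   copies.
#' @param concat_rate Probability that a read is a fragment-to-fragment
#'   concatenation.
#' @param duplicate_rate Probability that a read is an exact copy of an
#'   earlier read.
#' @param n_rate Per-base probability of an ambiguous N call in the
#'   insert.
#' @param read_cap Maximum read length (default 500 bp, pyrosequencing
#'   average).
#' @param seed Random seed; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads = 1000L, tag5 = wta_tags()$tag5,
                       tag3 = wta_tags()$tag3, insert_min = 100L,
                       insert_max = 1000L, indel_rate = 0.05,
                       substitution_rate = 0, concat_rate = 0,
                       duplicate_rate = 0, n_rate = 0, read_cap = 500L,
                       seed = 1L) {
  rates <- c(indel_rate, substitution_rate, concat_rate, duplicate_rate, n_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  if (insert_min > insert_max) stop("insert_min must be <= insert_max",
                                    call. = FALSE)
  if (insert_min > read_cap) stop("minimum insert exceeds the read cap",
                                  call. = FALSE)
  structure(list(n_reads = as.integer(n_reads), tag5 = tag5, tag3 = tag3,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 indel_rate = indel_rate,
                 substitution_rate = substitution_rate,
                 concat_rate = concat_rate, duplicate_rate = duplicate_rate,
                 n_rate = n_rate, read_cap = as.integer(read_cap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
# preference of a quasi-random tag position for its four candidate bases
QUASI_PREF <- c(0.5, 0.25, 0.15, 0.10)

random_string <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# fixed per-position base preference for the N positions of a tag:
# one permutation of A/C/G/T per position, weighted by QUASI_PREF
quasi_prefs <- function(tag) {
  letters <- strsplit(tag$sequence, "", fixed = TRUE)[[1L]]
  lapply(seq_along(letters), function(i) {
    if (letters[i] == "N") sample(BASES) else letters[i]
  })
}

# instantiate one tag copy: N positions drawn from their preference,
# then optional substitutions and at most one indel, biased (2/3) toward
# positions adjacent to a repeated base (homopolymer noise)
instantiate_tag <- function(prefs, indel_rate, substitution_rate) {
  bases <- vapply(prefs, function(p) {
    if (length(p) == 4L) sample(p, 1L, prob = QUASI_PREF) else p
  }, character(1L))
  nops <- 0L
  if (substitution_rate > 0) {
    hit <- which(stats::runif(length(bases)) < substitution_rate)
    for (i in hit) bases[i] <- sample(setdiff(BASES, bases[i]), 1L)
    nops <- nops + length(hit)
  }
  if (stats::runif(1L) < indel_rate) {
    homo <- which(bases[-1L] == bases[-length(bases)])  # i and i+1 equal
    pos <- if (length(homo) && stats::runif(1L) < 2 / 3) {
      sample(homo, 1L) + 1L
    } else sample(seq_along(bases), 1L)
    if (stats::runif(1L) < 0.5) {
      bases <- bases[-pos]                      # deletion
    } else {
      bases <- append(bases, bases[pos], after = pos)  # insertion (copy)
    }
    nops <- nops + 1L
  }
  list(seq = paste(bases, collapse = ""), ops = nops)
}

#' Generate ground-truthed synthetic tagged reads
#'
#' @param config A [sim_config()].
#' @return List with `reads` (data frame: id, desc, seq, qual) and `truth`
#'   (data frame: id, trim5 — 0-based end of the 5' tag region, trim3 —
#'   0-based start of the 3' tag region or NA when truncated away, ops5,
#'   ops3 — edit operations planted per end, junction_start,
#'   junction_end — 0-based half-open internal junction interval or NA,
#'   is_duplicate).
#' @examples
#' sim <- simulate_reads(sim_config(n_reads = 5, seed = 42))
#' sim$truth
#' @export
simulate_reads <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  prefs5 <- quasi_prefs(config$tag5)
  prefs3 <- quasi_prefs(config$tag3)
  n <- config$n_reads
  reads <- vector("list", n)
  truth <- vector("list", n)
  for (r in seq_len(n)) {
    id <- sprintf("read%05d", r)
    if (r > 1L && stats::runif(1L) < config$duplicate_rate) {
      src <- sample(r - 1L, 1L)
      reads[[r]] <- reads[[src]]
      reads[[r]]$id <- id
      tr <- truth[[src]]
      tr$id <- id
      tr$is_duplicate <- TRUE
      truth[[r]] <- tr
      next
    }
    t5 <- instantiate_tag(prefs5, config$indel_rate, config$substitution_rate)
    insert1 <- random_string(sample(config$insert_min:config$insert_max, 1L))
    concat <- stats::runif(1L) < config$concat_rate
    j_start <- NA_integer_; j_end <- NA_integer_
    if (concat) {
      # junction: exact 3' tag of fragment 1 + exact 5' tag of fragment 2
      jt3 <- instantiate_tag(prefs3, 0, 0)$seq
      jt5 <- instantiate_tag(prefs5, 0, 0)$seq
      insert2 <- random_string(sample(config$insert_min:config$insert_max, 1L))
      body <- paste0(insert1, jt3, jt5, insert2)
      j_start <- nchar(t5$seq) + nchar(insert1)
      j_end <- j_start + nchar(jt3) + nchar(jt5)
    } else {
      body <- insert1
    }
    t3 <- instantiate_tag(prefs3, config$indel_rate, config$substitution_rate)
    full <- paste0(t5$seq, body, t3$seq)
    seq <- substr(full, 1L, config$read_cap)
    len <- nchar(seq)
    if (config$n_rate > 0) {
      ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(len) < config$n_rate)
      # keep the planted tag copies N-free so truth distances stay exact
      hit <- hit[hit > nchar(t5$seq)]
      if (!is.na(j_start)) hit <- hit[hit <= j_start | hit > j_end]
      if (len > nchar(full) - nchar(t3$seq)) {
        hit <- hit[hit <= nchar(full) - nchar(t3$seq)]
      }
      if (length(hit)) {
        ch[hit] <- "N"
        seq <- paste(ch, collapse = "")
      }
    }
    trim3 <- if (len == config$read_cap && nchar(full) > config$read_cap) {
      # 3' tag partially or fully truncated
      start3 <- nchar(full) - nchar(t3$seq)  # 0-based start of the 3' tag
      if (start3 >= len) NA_integer_ else as.integer(start3)
    } else as.integer(len - nchar(t3$seq))
    if (!is.na(j_start) && j_start >= len) { j_start <- NA_integer_; j_end <- NA_integer_ }
    if (!is.na(j_end)) j_end <- min(j_end, len)
    reads[[r]] <- data.frame(id = id, desc = NA_character_, seq = seq,
                             qual = NA_character_, stringsAsFactors = FALSE)
    truth[[r]] <- data.frame(id = id, trim5 = nchar(t5$seq),
                             trim3 = trim3, ops5 = t5$ops, ops3 = t3$ops,
                             junction_start = j_start, junction_end = j_end,
                             is_duplicate = FALSE, stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
}
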