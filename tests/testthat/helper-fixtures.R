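# Hand-enumerated 9-record toy dataset for the pipeline: every read is
# built from the WTA tags with fixed quasi-random instantiations, so the
# planted fate of each read is known by construction.
#
#   clean1  tagged, 150 bp insert              -> PASS (trimmed)
#   clean2  tagged, 120 bp insert              -> PASS (trimmed)
#   dup     exact copy of clean1               -> FILTERED_duplicate
#   short   tagged, 20 bp insert               -> FILTERED_length
#   nrich   tagged, 100 bp insert with 10 Ns   -> FILTERED_ambiguous
#   tagrep  three exact 5' tag copies, nothing else -> FILTERED_tag_repeat
#   concat  two fragments around a tag3.tag5 junction -> split, both PASS
#   untag   40 bp untagged read                -> FILTERED_length
toy_dataset <- function() {
  tags <- wta_tags()
  inst <- function(tag, seed) {
    set.seed(seed)
    ch <- strsplit(tag$sequence, "", fixed = TRUE)[[1L]]
    ch[ch == "N"] <- sample(c("A", "C", "G", "T"), sum(ch == "N"),
                            replace = TRUE)
    paste(ch, collapse = "")
  }
  t5a <- inst(tags$tag5, 1); t5b <- inst(tags$tag5, 2)
  t3a <- inst(tags$tag3, 3); t3b <- inst(tags$tag3, 4)
  set.seed(99)
  i150 <- random_dna(150); i120 <- random_dna(120)
  i20 <- random_dna(20)
  i100 <- random_dna(100)
  substr(i100, 41, 50) <- "NNNNNNNNNN"   # 10% ambiguous
  iA <- random_dna(100); iB <- random_dna(120)
  i40 <- random_dna(40)
  reads <- data.frame(
    id = c("clean1", "clean2", "dup", "short", "nrich", "tagrep", "concat",
           "untag"),
    seq = c(paste0(t5a, i150, t3a),
            paste0(t5b, i120, t3b),
            paste0(t5a, i150, t3a),
            paste0(t5a, i20, t3a),
            paste0(t5a, i100, t3a),
            paste0(t5a, t5a, t5a),
            paste0(t5a, iA, t3b, t5b, iB, t3a),
            i40),
    stringsAsFactors = FALSE)
  list(reads = reads, tags = tags,
       inserts = list(i150 = i150, i120 = i120, iA = iA, iB = iB))
}
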