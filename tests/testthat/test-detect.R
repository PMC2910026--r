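test_that("terminal k-mers are counted per end and partition the reads", {
  seqs <- c(rep("GTGGTACGT", 10L))
  expect_identical(extract_end_kmers(seqs, 5, "5"), c(GTGGT = 10L))
  mixed <- c("AAAAATTT", "AAAAAGGG", "CCCCCTTT", "GT")  # last one too short
  k5 <- extract_end_kmers(mixed, 5, "5")
  expect_identical(sum(k5), 3L)
  k3 <- extract_end_kmers(mixed, 5, "3")
  expect_identical(sort(names(k3)), sort(c("AATTT", "AAGGG", "CCTTT")))
  expect_error(extract_end_kmers(character(0)), "empty")
})

test_that("k-mer ranking applies the 10% threshold and aborts without signal", {
  counts <- c(AAAAA = 60L, AAAAT = 20L, CCCCC = 5L)
  expect_identical(names(filter_and_rank_kmers(counts, 100L)),
                   c("AAAAA", "AAAAT"))
  uniq <- stats::setNames(rep(1L, 50L), replicate(50, random_dna(5)))
  expect_error(filter_and_rank_kmers(uniq, 1000L),
               class = "tagtrimr_no_signal")
})

test_that("shift alignment finds minimal gapless shifts with directions", {
  both <- align_shift("ACACA", "CACAC")
  expect_identical(both$shift, 1L)
  expect_true(both$ambiguous)

  same <- align_shift("GTGGT", "GTGGT")
  expect_identical(same$shift, 0L)
  expect_false(same$ambiguous)

  expect_null(align_shift("GTGTT", "TTTGG", max_shift = 2))

  left <- align_shift("AACCA", "TAACC")   # candidate extends one to the left
  expect_identical(left$shift, -1L)
  right <- align_shift("AACCA", "ACCAG")  # candidate extends one to the right
  expect_identical(right$shift, 1L)
})

test_that("k-mer agglomeration joins shifted variants into a consensus", {
  ranked <- c(AACCA = 60L, TAACC = 30L, ACCAG = 20L)
  merged <- merge_kmers(ranked)
  expect_identical(merged$consensus, "TAACCAG")  # length k + |−1| + |+1|
  expect_identical(merged$assignments$shift, c(0L, -1L, 1L))

  single <- merge_kmers(c(GTGGT = 10L))
  expect_identical(single$consensus, "GTGGT")
  expect_identical(single$assignments$shift, 0L)

  stub <- merge_kmers(c(AAAAA = 60L, GGGGG = 30L))
  expect_identical(stub$consensus, "AAAAA")  # unalignable k-mer not joined
  expect_identical(nrow(stub$assignments), 1L)
})

test_that("agglomeration terminates with bounded consensus length", {
  set.seed(20)
  for (i in 1:25) {
    core <- random_dna(5)
    variants <- unique(c(core,
                         paste0(random_dna(1), substr(core, 1, 4)),
                         paste0(substr(core, 2, 5), random_dna(1)),
                         random_dna(5)))
    ranked <- stats::setNames(rev(seq_along(variants)) * 10L, variants)
    merged <- merge_kmers(ranked)
    shifts <- merged$assignments$shift[!merged$assignments$ambiguous]
    expect_lte(nchar(merged$consensus), 5L + sum(abs(shifts)))
  }
})

test_that("shift adjustment anchors every end at its extreme variant", {
  asg3 <- data.frame(kmer = c("a", "b", "c"), count = c(3L, 2L, 1L),
                     shift = c(0L, -1L, 1L), ambiguous = FALSE)
  adj3 <- adjust_shifts(asg3, "3")$adjusted
  expect_identical(adj3, c(-1L, -2L, 0L))
  # the anchor (raw shift 0) receives a = -max{-1, 1} = -1
  expect_identical(adj3[1L], -1L)

  asg0 <- data.frame(kmer = "a", count = 1L, shift = 0L, ambiguous = FALSE)
  expect_identical(adjust_shifts(asg0, "5")$adjusted, 0L)

  asg5 <- data.frame(kmer = c("a", "b"), count = c(2L, 1L),
                     shift = c(0L, -2L), ambiguous = FALSE)
  adj5 <- adjust_shifts(asg5, "5")$adjusted
  expect_identical(adj5, c(2L, 0L))
  # the anchor's adjusted shift equals a = |min shift| and none is negative
  expect_identical(adj5[1L], 2L)
  expect_true(all(adj5 >= 0L))
})

test_that("frequency profiles shift assigned reads and renormalize", {
  set.seed(8)
  seqs <- replicate(80, paste0("ACGTA", random_dna(30)))
  raw <- corrected_frequencies(seqs, NULL, "5", profile_len = 20)
  expect_true(all(abs(rowSums(raw$freq)[raw$support > 0] - 1) < 1e-12))
  expect_identical(unname(raw$freq[1, "A"]), 1)

  # shifting every read by +1 translates the profile by one position
  asg <- data.frame(kmer = "ACGTA", count = 80L, shift = 1L,
                    ambiguous = FALSE, adjusted = 1L)
  shifted <- corrected_frequencies(seqs, asg, "5", profile_len = 20)
  expect_equal(shifted$freq[2:20, ], raw$freq[1:19, ])
  expect_identical(unname(shifted$support[1]), 0)

  # reads with N at a position drop out of that position's normalization
  seqN <- c("ANGT", "ACGT", "ACGT")
  pN <- corrected_frequencies(seqN, NULL, "5", profile_len = 4)
  expect_identical(unname(pN$support[2]), 2)
  expect_identical(unname(pN$freq[2, "C"]), 1)
})

test_that("shift correction sharpens tag positions on indel-noised data", {
  sim <- simulate_reads(sim_config(n_reads = 600, insert_min = 80,
                                   insert_max = 120, indel_rate = 0.2,
                                   read_cap = 300, seed = 21))
  det <- detect_tag(sim$reads$seq, "5")
  tagpos <- 1:31
  raw_max <- mean(apply(det$raw_profile$freq[tagpos, ], 1, max))
  cor_max <- mean(apply(det$profile$freq[tagpos, ], 1, max))
  expect_gte(cor_max, raw_max)
})

test_that("position classification follows the range/median rule", {
  mk <- function(freqs) {
    f <- matrix(freqs, ncol = 4, byrow = TRUE,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    structure(list(end = "5", freq = f,
                   range = apply(f, 1, function(x) max(x) - min(x)),
                   median = apply(f, 1, stats::median),
                   support = rep(100, nrow(f))),
              class = "frequency_profile")
  }
  expect_identical(classify_positions(mk(c(1, 0, 0, 0))), "SPECIFIC")
  expect_identical(classify_positions(mk(c(0.25, 0.25, 0.25, 0.25))),
                   "BACKGROUND")
  expect_identical(classify_positions(mk(c(0.45, 0.30, 0.15, 0.10))),
                   "QUASI_RANDOM")
  # under-supported positions fall back to background
  p <- mk(c(1, 0, 0, 0)); p$support <- 10
  expect_identical(classify_positions(p), "BACKGROUND")
  # scale-free: classification depends on frequencies, not counts
  p2 <- mk(c(0.45, 0.30, 0.15, 0.10) * 4 / 4)
  expect_identical(classify_positions(p2), "QUASI_RANDOM")
})

test_that("predicted tags emit argmax bases, N for quasi-random, in 5'->3' order", {
  f <- matrix(0.25, nrow = 6, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  f[1, ] <- c(0.96, 0.02, 0.01, 0.01)
  f[2, ] <- c(0.01, 0.96, 0.02, 0.01)
  f[3, ] <- c(0.45, 0.30, 0.15, 0.10)
  prof <- structure(list(end = "5", freq = f,
                         range = apply(f, 1, function(x) max(x) - min(x)),
                         median = apply(f, 1, stats::median),
                         support = rep(100, 6)),
                    class = "frequency_profile")
  cls <- classify_positions(prof)
  expect_identical(cls[1:4], c("SPECIFIC", "SPECIFIC", "QUASI_RANDOM",
                               "BACKGROUND"))
  tag5 <- predict_tag(cls, prof, "5")
  expect_identical(tag5$sequence, "ACN")
  prof$end <- "3"
  tag3 <- predict_tag(cls, prof, "3")
  expect_identical(tag3$sequence, "NCA")  # reversed to read 5'->3'

  expect_null(predict_tag(rep("BACKGROUND", 6), prof, "5"))
})

test_that("full detection recovers both WTA tags from a simulated dataset", {
  sim <- simulate_reads(sim_config(n_reads = 1200, insert_min = 100,
                                   insert_max = 300, indel_rate = 0.05,
                                   seed = 17))
  tags <- wta_tags()
  d5 <- detect_tag(sim$reads$seq, "5")
  d3 <- detect_tag(sim$reads$seq, "3")
  expect_identical(d5$tag$sequence, tags$tag5$sequence)
  expect_identical(d3$tag$sequence, tags$tag3$sequence)
  # tag-free data yields no prediction
  set.seed(5)
  free <- replicate(300, random_dna(120))
  expect_null(detect_tag(free, "5")$tag)
})
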