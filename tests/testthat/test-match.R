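test_that("pattern masks encode the IUPAC expansion", {
  m1 <- build_masks("N")
  expect_true(all(m1[1, c("A", "C", "G", "T", "N")]))

  m2 <- build_masks("ACGT")
  expect_equal(unname(m2[, "A"]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(m2[, "C"]), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(unname(m2[, "G"]), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(unname(m2[, "T"]), c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(m2[, "N"]))  # read N mismatches concrete tag letters

  m3 <- build_masks("AYG")
  expect_true(m3[2, "C"] && m3[2, "T"])
  expect_false(m3[2, "A"] || m3[2, "G"])

  expect_error(tag_spec("ACXG", "5"), "invalid IUPAC letter 'X' at tag position 3")
})

test_that("semi-global distance matches the worked two-deletion example", {
  d <- semiglobal_distance("GTGGTGTGTTGGGTGTGTTTGG", "GTGGTGTGTTGGTGTGTTGG")
  expect_identical(d$distance, 2L)
})

test_that("identical tag and text give distance zero; bad input errors", {
  expect_identical(semiglobal_distance("ACGTACGT", "ACGTACGT")$distance, 0L)
  expect_error(semiglobal_distance("ACGT", ""), "empty")
  expect_error(semiglobal_distance("ACGT", "ACGU"), "invalid read letter")
})

test_that("bit-parallel columns equal the naive DP oracle, wildcards included", {
  set.seed(4242)
  iupac <- names(tagtrimr:::IUPAC_SETS)
  for (i in 1:400) {
    m <- sample(4:20, 1L)
    n <- sample(10:80, 1L)
    wild <- i %% 3 == 0
    tag <- if (wild) random_dna(m, iupac) else random_dna(m)
    text <- random_dna(n, c("A", "C", "G", "T", "N"))
    got <- semiglobal_distance(tag, text)
    expect_identical(got$columns, dp_semiglobal_columns(tag, text),
                     info = paste(tag, text))
    if (!wild && !grepl("N", text)) {
      expect_identical(got$distance,
                       as.integer(utils::adist(tag, text, partial = TRUE)[1, 1]))
    }
  }
})

test_that("long tags (beyond one machine word) still match the oracle", {
  set.seed(7)
  for (i in 1:20) {
    m <- sample(70:150, 1L)
    tag <- random_dna(m)
    text <- random_dna(sample(150:250, 1L))
    expect_identical(semiglobal_distance(tag, text)$columns,
                     dp_semiglobal_columns(tag, text))
  }
  # exact embedded occurrence of a 130-mer
  tag <- random_dna(130)
  text <- paste0(random_dna(40), tag, random_dna(40))
  expect_identical(semiglobal_distance(tag, text)$distance, 0L)
})

test_that("distance is bounded by m, zero iff exact, symmetric under reversal, monotone", {
  set.seed(91)
  for (i in 1:150) {
    tag <- random_dna(sample(4:15, 1L),
                      c("A", "C", "G", "T", if (i %% 4 == 0) "N"))
    text <- random_dna(sample(8:60, 1L))
    d <- semiglobal_distance(tag, text)$distance
    expect_lte(d, nchar(tag))
    expect_identical(d == 0L, grepl(iupac_regex(tag), text))
    rd <- semiglobal_distance(tagtrimr:::reverse_string(tag),
                              tagtrimr:::reverse_string(text))$distance
    expect_identical(d, rd)
    ext <- paste0(text, random_dna(10))
    expect_lte(semiglobal_distance(tag, ext)$distance, d)
  }
})

test_that("default search window follows max(10, floor(3m/2))", {
  expect_identical(default_search_range(31), 46L)
  expect_identical(default_search_range(4), 10L)
  expect_identical(default_search_range(20), 30L)
  expect_error(default_search_range(0))
})

test_that("percentage mismatch thresholds floor against the tag length", {
  expect_identical(tagtrimr:::resolve_mismatches("10%", 31), 3L)
  expect_identical(tagtrimr:::resolve_mismatches("10%", 9), 0L)
  expect_identical(tagtrimr:::resolve_mismatches(2, 31), 2L)
  expect_error(tagtrimr:::resolve_mismatches("x%", 31), "percentage")
})

test_that("find_tag_at_end locates exact and noisy tags and maps 3' coordinates", {
  set.seed(12)
  tag5 <- tag_spec("ACGTACGT", "5")
  read <- paste0("ACGTACGT", random_dna(80))
  m <- find_tag_at_end(read, tag5, 0)
  expect_identical(m$start, 0L)
  expect_identical(m$end, 8L)
  expect_identical(m$distance, 0L)

  # tag with one deletion at the 5' end still trims the residual tag
  sim <- simulate_reads(sim_config(n_reads = 60, insert_min = 60,
                                   insert_max = 80, indel_rate = 1,
                                   read_cap = 200, seed = 3))
  tags <- wta_tags()
  hits <- 0L
  for (r in seq_len(nrow(sim$reads))) {
    if (sim$truth$ops5[r] != 1L) next
    m <- find_tag_at_end(sim$reads$seq[r], tags$tag5, 1)
    expect_false(is.null(m))
    # an indel in the quasi-random N segment is absorbed at distance 0;
    # one in the fixed segment costs exactly one edit
    expect_lte(m$distance, 1L)
    # all true tag bases removed, at most one extra insert base taken
    expect_gte(m$end, sim$truth$trim5[r] - 1L)
    expect_lte(m$end, sim$truth$trim5[r] + 1L)
    hits <- hits + 1L
  }
  expect_gte(hits, 20L)

  # 3'-end match is computed on the reversed window and mapped back
  tag3 <- tag_spec("TTGGCCAA", "3")
  read3 <- paste0(random_dna(50), "TTGGCCAA")
  m3 <- find_tag_at_end(read3, tag3, 0)
  expect_identical(m3$start, 50L)
  expect_identical(m3$end, 58L)
  expect_identical(m3$category, "END3")

  # read shorter than the tag with no tag content
  expect_null(find_tag_at_end("ACG", tag_spec("TTTTTTTTTT", "5"), 1))
})

test_that("early exit never changes the returned match", {
  set.seed(65)
  tag <- tag_spec("ACGTAC", "5")
  for (i in 1:80) {
    read <- paste0(if (i %% 2) "ACGTAC" else "", random_dna(40),
                   if (i %% 3 == 0) "ACGTACACGTAC" else "")
    a <- find_tag_at_end(read, tag, 2, early_exit = TRUE)
    b <- find_tag_at_end(read, tag, 2, early_exit = FALSE)
    expect_identical(a, b)
  }
})

test_that("continuous trimming removes stacked tag copies and flags tag repeats", {
  set.seed(31)
  tag <- tag_spec("GATTACAGAT", "5")
  insert <- random_dna(70)
  two <- continuous_trim(paste0("GATTACAGAT", "GATTACAGAT", insert), tag, 0)
  expect_identical(two$sequence, insert)
  expect_length(two$matches, 2L)
  expect_identical(vapply(two$matches, `[[`, integer(1L), "end"), c(10L, 20L))

  none <- continuous_trim(insert, tag, 0)
  expect_identical(none$sequence, insert)
  expect_length(none$matches, 0L)
  expect_false(none$tag_repeat)

  rep3 <- continuous_trim(strrep("GATTACAGAT", 3L), tag, 0)
  expect_identical(rep3$sequence, "")
  expect_true(rep3$tag_repeat)
})

test_that("internal occurrences are found greedily and respect exclusions", {
  set.seed(77)
  a <- random_dna(60); b <- random_dna(70)
  junction <- "TTAACCGGTTAA"
  pat <- tag_spec(junction, "5")
  read <- paste0(a, junction, b)
  hits <- find_internal(read, pat, 0)
  expect_length(hits, 1L)
  expect_identical(hits[[1L]]$start, 60L)
  expect_identical(hits[[1L]]$end, 72L)
  expect_identical(hits[[1L]]$category, "INTERNAL")

  expect_length(find_internal(paste0(a, b), pat, 0), 0L)

  # two substitutions, budget 3
  jmut <- junction
  substr(jmut, 3, 3) <- "G"; substr(jmut, 9, 9) <- "C"
  read2 <- paste0(a, jmut, b)
  hits2 <- find_internal(read2, pat, 3)
  expect_length(hits2, 1L)
  expect_identical(hits2[[1L]]$distance, dp_semiglobal(junction, jmut))
  expect_identical(hits2[[1L]]$distance, 2L)

  # occurrences overlapping the excluded end regions are dropped
  ex <- find_internal(read, pat, 0, exclude = list(c(55L, 75L)))
  expect_length(ex, 0L)
})
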