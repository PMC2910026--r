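# Independent full-matrix dynamic-programming oracle for semi-global
# matching: row 0 is all zeros (free gaps before the tag in the read),
# costs are unit, IUPAC wildcards in the tag match their base sets at
# cost 0.  Returns the vector of last-row values (one per text position);
# its minimum is the semi-global distance.  Deliberately naive: this is
# the reference the bit-parallel implementation is checked against.
dp_semiglobal_columns <- function(tag, text) {
  masks <- build_masks(tag)
  m <- nrow(masks)
  letters <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(letters)
  prev <- 0:m           # column for j = 0: D[i,0] = i
  out <- integer(n)
  for (j in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- 0L       # first row free
    match_cost <- ifelse(masks[, letters[j]], 0L, 1L)
    for (i in seq_len(m)) {
      cur[i + 1L] <- min(prev[i] + match_cost[i],   # diagonal
                         prev[i + 1L] + 1L,          # insertion in tag
                         cur[i] + 1L)                # deletion from tag
    }
    out[j] <- cur[m + 1L]
    prev <- cur
  }
  out
}

dp_semiglobal <- function(tag, text) min(dp_semiglobal_columns(tag, text))

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exact-presence oracle: does the IUPAC tag match some substring exactly?
iupac_regex <- function(tag) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
               D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGTN]")
  paste(vapply(strsplit(tag, "", fixed = TRUE)[[1L]],
               function(ch) sets[[ch]], character(1L)), collapse = "")
}
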