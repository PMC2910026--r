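---
title: "Methods: tag detection, trimming and splitting in tagtrimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag detection, trimming and splitting in tagtrimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagtrimr)
```

## The problem

Reads from primer-amplified libraries — Whole Transcriptome Amplification
(WTA) viral metagenomes being the motivating case — carry artificial *tag
sequences* at their ends: the amplification primer at the 5' end and its
reverse complement at the 3' end.  WTA primers have a fixed universal
segment and a quasi-random segment (written as N positions), and
pyrosequencing adds homopolymer-driven insertions and deletions, so the
observed tag copies vary from read to read.  Blunt-end ligation during
library preparation can additionally join two fragments into one read,
leaving a 3'-tag/5'-tag junction in the middle.  All of this must be
removed before assembly or taxonomic analysis; `tagtrimr` locates tags by
approximate matching, predicts unknown tags from positional nucleotide
frequencies, splits concatenated reads, and filters the residue.

## Approximate matching model

A tag of length $m$ is matched against a read of length $n$ under the
unit-cost edit distance (insertions, deletions, substitutions), with the
gaps flanking the tag in the read free — semi-global matching, so the tag
aligns to a *substring* of the read.  The per-column minima of the
dynamic-programming matrix are maintained with Myers' bit-parallel
column-difference encoding: two bit vectors of width $m$ carry the +1/−1
vertical differences and each read base is processed in a constant number
of word operations.  We block the vectors into 64-bit words with explicit
carry propagation, so tags of any length are supported; native single-word
execution is an optimization, not a semantic limit.  The naive
$O(nm)$ matrix is kept in the test suite as an independent oracle, with
base R's `adist(partial = TRUE)` as a second, wildcard-free cross-check.

IUPAC ambiguity codes in the tag are expanded once, during pattern
pre-processing, into per-letter acceptance masks (`build_masks()`), so
wildcards cost nothing at match time.  An N in a *read* is treated as a
low-quality signal, not a wildcard: it is accepted only by a tag N.

### End search

A tag is expected at the read end, so the search is restricted to a window
of `max(10, floor(3m/2))` bases (46 bp for the 31 bp WTA tag) unless the
user overrides it.  The search stops at the first perfect match.  When
only imperfect matches exist, the lowest distance wins and ties are broken
toward the *larger* trimmed extent: residual tag bases are more harmful
downstream than one extra trimmed base.  Because the bit vector only
yields match end positions, the start is recovered by running the reversed
pattern over the reversed matched prefix, taking the longest consistent
extent on ties — the same tie direction as above.  The 3' end reuses the
5' machinery on the reversed suffix and maps coordinates back.  Mismatch
limits may be given as percentages of the tag length, floored
(`"10%"` of 31 → 3).

Continuous trimming re-runs the end search after each trim, removing
stacked tag copies; a read consumed entirely is flagged as a tag repeat
and removed by the length filter.

## Automatic tag prediction

With frequencies $f_i(b)$ of base $b$ at position $i$ (counted from the
profiled end, normalized over A/C/G/T; reads with N at $i$ are excluded
from that position's denominator), a fixed tag position shows one
frequency near 1, background sequence shows all four near 0.25, and
quasi-random tag positions sit in between.  Writing $r_i$ for the range
and $m_i$ for the median of the four frequencies, a position is classified
as

* **specific** when $r_i > 3 m_i$,
* **background** when $r_i < m_i + v$ with allowed variation $v = 0.05$
  (absolute, on the frequency scale),
* **quasi-random** otherwise,

and the predicted tag is the maximal specific/quasi-random run starting at
the end — specific positions emit their majority base, quasi-random ones
emit N.  Equal base composition of the background is assumed; no G/C
correction is applied.

Indels shift tag copies relative to each other and blur the profile, so
frequencies are first corrected with terminal k-mers (default $k = 5$):
k-mers carried by at least 10% of reads are ranked by count (ties
lexicographic), then agglomerated — each k-mer is aligned to the current
consensus without gaps; if it fits within 2 shift operations it is joined
and its signed shift recorded, otherwise deferred and retried until a full
pass joins nothing.  A k-mer alignable in both directions with equal shift
(the `ACACA`/`CACAC` case) is marked ambiguous and contributes unshifted —
the conservative reading, since the true direction is unknowable from the
k-mer alone.  Shifts are then re-anchored (`a = |min shift|` at the 5'
end, `a = −max shift` at the 3' end) so the most-shifted, longest variant
defines position 1, and each read contributes its base at end-position $i$
to profile position $i + |s|$ where $s$ is its k-mer's adjusted shift.
The re-anchoring makes displacement point away from the profiled end for
both ends; this is the coordinate system in which the intact and truncated
tag variants align.

Choices the classification rule needed but the rule itself does not fix:
profiles cover 60 positions (about twice the WTA tag length) and a
position needs at least 50 contributing reads to be classified at all —
below that, sampling noise in $r_i$ and $m_i$ makes any call meaningless,
so such positions are background.  Reliable recovery of the quasi-random
segment needs datasets of roughly 1,000 reads and up; `cmd_predict()`
warns below that size.

## Concatenation splitting

A fragment-to-fragment concatenation leaves `tag3 · tag5` inside the read
(only this orientation is searched; the reverse would imply an inverted
insert).  The junction is searched with the same matcher after end
trimming, all qualifying internal occurrences are selected greedily by
lowest distance then leftmost position, and the read is cut around the
junction intervals: $n$ junctions give $n + 1$ fragments, ids suffixed
`.1`, `.2`, … only when a split actually happened.  Fragments re-enter
the length and ambiguity filters like ordinary reads.  Exact-only junction
matching (`split_max_mm = 0`) is the conservative default in the examples
here; with the 61 bp WTA junction pattern the chance of a spurious exact
match in random sequence is negligible.

## Filtering

Stage order is fixed: end trimming → junction splitting → length filter
(inclusive bounds) → ambiguity filter (reads with strictly more than the
allowed percentage of N are removed) → tag-occurrence filter (keep / 5' /
3' / both / either / none) → dereplication.  Dereplication runs last
because duplicates may only become exact copies once variable tag copies
are trimmed off.  Failing reads are written unchanged so both streams can
be inspected.

## The synthetic generator

`simulate_reads()` produces ground-truthed datasets: each read is a noisy
5'-tag copy, an insert of i.i.d. uniform A/C/G/T (matching the equal-base
assumption of the classifier), and a 3'-tag copy, truncated at a 500 bp
read cap — so long inserts lose part or all of their 3' tag, reproducing
the heavy 3' incompleteness seen in real pyrosequencing data.  Indels are
placed with probability 2/3 adjacent to a repeated tag base, emulating
homopolymer miscalls; concatenation events insert an exact
`tag3 · tag5` junction between two inserts; duplicates are exact copies
of earlier reads.

Quasi-random tag positions are instantiated from a fixed per-position
preference (0.5/0.25/0.15/0.10 over a per-position permutation of the four
bases).  This is a modelling decision, not a convenience: positions drawn
uniformly would be statistically indistinguishable from background under
the range/median rule, and the preference structure is exactly what makes
real WTA quasi-random segments detectable.

What the generator does *not* emulate: quality scores, flowgram-level
noise, non-uniform genome composition, chimeras other than blunt-end
concatenation, and partial tag synthesis errors.  Passing tests therefore
demonstrate the mechanisms — matching, shift correction, classification,
splitting, filtering — under the stated noise model, not performance on
any particular real instrument run.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally; the annotated FASTA headers
convert to 1-based positions.  Empty reads and empty inputs are normal
outcomes, not errors; absence of a tag match is `NULL`, absence of any
frequent k-mer aborts detection with a typed condition ("no conserved end
signal"), which the caller reports as "no tag detected".  Problem sizes in
the test suite (hundreds to a few thousand simulated reads per case,
10,000 for the concatenation-rate check, 20 replicates of 1,000 reads for
detection reliability) were chosen as the smallest sizes at which the
statistical checks have comfortable margins.

## Worked example

```{r example, eval = FALSE}
tags <- wta_tags()
sim <- simulate_reads(sim_config(n_reads = 1500, insert_min = 100,
                                 insert_max = 300, indel_rate = 0.05,
                                 concat_rate = 0.02, seed = 42))
det5 <- detect_tag(sim$reads$seq, "5")
det5$tag$sequence            # the 31 bp WTA tag, Ns included
res <- run_pipeline(sim$reads, tags$tag5, tags$tag3, filter_config())
mismatch_summary(res$report)
```

## Known limitations

Tag prediction on non-random backgrounds (16S amplicons, low-complexity
genomes) will over-predict: conserved biological positions look
"specific" to the classifier.  The prediction should then be reviewed via
`profile_table()` and corrected by hand.  Quality-aware trimming is out of
scope and recommended to run after tag removal, since clipping low-quality
ends first can destroy the very tag bases that need to be recognized.
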