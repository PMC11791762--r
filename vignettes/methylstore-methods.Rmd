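---
title: "Storing digital data in methylation-expanded DNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing digital data in methylation-expanded DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylstore)
```

## The problem and the model

Standard DNA data storage writes information over the four natural bases,
capping the information density at log2(4) = 2 bits per base.
5-methylcytosine (5mC, written `M` throughout this package) is a modified
cytosine that nanopore sequencers can distinguish from plain C, so it can
serve as a fifth information-bearing letter. With a five-letter alphabet
the ceiling rises to log2(5) ≈ 2.32 bits/base (`density_limit()`).

methylstore implements the full write/read stack around this idea:

1. **Rotational transcoding.** Bytes are expanded to base-4 digits (four
   digits per byte, most significant first) and each digit selects the
   next letter from a rotational table: with previous letter at alphabet
   index *p* and digit *d*, the next letter is index
   *(p + 1 + d) mod 5* in the order A, T, C, G, M. The table skips the
   previous letter by construction, so the radix is alphabet size − 1 and
   raw output never repeats a letter in adjacent positions. The first
   position uses a *virtual* previous letter, A. A letter equal to its
   predecessor therefore has no preimage, which the decoder exploits as a
   built-in corruption detector.
2. **Packetisation with XOR erasure redundancy.** Files are split into
   22-byte segments with consecutive integer addresses; every pair of
   data segments contributes one XOR parity segment, so any one member of
   a (X, Y, X⊕Y) triple is recoverable from the other two. Each segment
   becomes a 100-letter oligo: a 12-letter (24-bit) address field followed
   by 88 payload letters, transcoded as one digit stream.
3. **Channel simulation** (substitutions, insertions, deletions at a
   per-position Bernoulli rate) with replicated recovery-rate statistics.
4. **Assembly planning**: 8-nt ligation adaptors appended to each oligo
   (108-nt units), groups of 27 units split 15 + 12 into two staged
   subfragments.
5. **Read decoding**: methylation calling, identity screening, trimming,
   per-oligo star-MSA consensus, rotational decoding and XOR-aware
   reassembly.

## Choices the design left open, and what this package does

**Alphabet order and table rule.** The cyclic rule over the order
(A, T, C, G, M) is the unique simple rotation consistent with the worked
example 150 → "2112" → "GACA" (both are asserted in the test suite). The
order is configurable in `expanded_alphabet()`; any ordered set of K ≥ 2
distinct letters yields a radix-(K−1) codec with the digit width per byte
adjusting automatically.

**Per-byte digit expansion.** Each byte is expanded independently into
⌈log_N 256⌉ digits rather than converting the whole file as one big
integer. This preserves byte boundaries, so any segment decodes in
isolation — the property the addressed-oligo design depends on.

**Virtual letter reset.** The virtual previous letter A is reset at the
start of every oligo, making each oligo independently decodable; nothing
is carried across oligo boundaries.

**Address field width.** A 12-letter address field (24 bits, 16.7M
segments) plus 88 payload letters makes the oligo exactly 100 nt for a
22-byte segment. The manifest (file length, segment geometry, checksum)
travels as a JSON sidecar rather than as extra header oligos, keeping the
oligo count at exactly data + parity.

**XOR pairing.** Consecutive segments (2k, 2k+1) are paired and parity
segments are appended after the data block; an odd trailing segment pairs
with an implicit all-zero phantom so the recovery algebra stays uniform.
Unrecoverable data segments decode as zero bytes, which keeps the
recovery-rate denominator equal to the full file size.

**Terminal adaptor convention.** A 27-unit group of 108-nt units totals
2,916 nt, but the assembled products are 1,620 bp (15 × 108) and 1,288 bp
(12 × 108 − 8): the second subfragment's final unit does not carry its
trailing adaptor into the assembled product. 12 × 108 − 8 is the unique
simple arithmetic consistent with those lengths; the convention is
exposed via `omit_terminal_adaptor`.

**Adaptor selection.** All 4^8 candidate 8-mers are filtered to GC in
[40%, 60%] (for 8-mers this forces exactly four G/C letters) and maximum
homopolymer 2, leaving 14,696 survivors. Requiring Hamming distance
"greater than 4" — read literally as ≥ 5 against *every other survivor* —
annihilates the set (every survivor has a near neighbour), so the default
is deterministic greedy code construction in lexicographic order, which
keeps 48 mutually ≥ 5-distant adaptors; the literal all-pairs mode is
retained for comparison. Both numbers are pinned in the tests against an
independent exhaustive enumeration.

**Methylation probability scale.** Methylation probabilities ride on the
0–255 integer scale standard for per-base modification tags, with the
calling threshold at 128, inclusive (`call_methylation()`); probabilities
of exactly 128 are called methylated.

**Identity.** Read identity is matches / alignment length under a
semi-global (overlap) pairwise alignment, so barcodes flanking a read are
not penalised; the retention threshold 0.85 is inclusive. When assigning
trimmed *pieces* to reference oligos, however, the package uses *global*
identity: pieces and oligos have the same design length, and an overlap
alignment would score a shared 12-letter address prefix as a perfect
(but meaningless) short match.

**Trimming.** Reads are split at exact adaptor occurrences; a
mismatch-tolerant search (one edit, indels allowed) is applied only
inside pieces still longer than the 120-nt window. An unrestricted
one-mismatch search would chop intact oligos at stray near-matches —
with five adaptors active, roughly a third of noise-free reads lost a
piece that way during development — while the restricted form is exact on
clean reads and still rescues corrupted junctions. Pieces outside the
inclusive 80–120 nt window are discarded.

**Consensus.** `msa_consensus()` builds a star multiple alignment: the
piece whose length is closest to the median is the centre, every other
piece is aligned to it globally, and columns are keyed to centre
positions (insertions key to the preceding centre position). Each column
emits its majority letter; a column where gaps are at least as frequent
as the best letter emits nothing, and letter ties break by the fixed
precedence A < T < C < G < M, making the consensus deterministic. An
alignment-based consensus is required rather than an off-the-shelf
nucleotide MSA tool because `M` must remain a fifth letter; nucleotide
aligners treat `M` as the IUPAC A/C ambiguity code and would silently
erase the methylation signal. Alignments run on plain `BString`s with an
explicit five-letter substitution matrix (match +2, mismatch −2, gap
opening 4, extension 1).

**Reference-free grouping.** Without a reference, pieces are grouped by
their decoded 12-letter address prefix; pieces whose prefix contains an
invalid transition are dropped. This is a pragmatic stand-in for a
procedure the original experiment did not describe.

## What the read simulator emulates — and what it does not

`simulate_reads()` emulates nanopore-style output for an assembled
fragment: M renders as C, per-base substitution/insertion/deletion errors
are applied (defaults 0.2% each), barcodes are attached, and every
basecalled C receives a methylation probability drawn uniformly from the
called half of the 0–255 scale, with confusion rates `m_miscall` and
`c_miscall` (default 5%) flipping true-5mC and true-C calls. This
reproduces the *structure* of real data — indel-bearing reads, C/M
confusion as the dominant substitution class, depth-dependent consensus
accuracy — but not nanopore's sequence-context error correlations, its
CpG-biased methylation model, homopolymer-length miscalls, or quality
scores. Passing tests therefore demonstrate the pipeline's correctness
and its qualitative behaviour under noise, not a quantitative forecast of
recovery rates on real PromethION data.

## Numerical and scale choices

* Simulations derive one sub-seed per (rate, replicate) cell from the
  user seed, so experiments are reproducible cell-by-cell.
* The default acceptance-scale experiments use a 5,929-byte fixture
  (270 data + 135 XOR segments = 405 oligos — the reference file size),
  ten replicates per error rate, and a 1 MB fixture for GC profiling
  (71,495 oligos, ~2 s to encode via the vectorised cumulative-sum core).
  The synthetic read scenarios in the tests use 220-byte stores (15
  oligos, 3 assembly groups of 5) at depths 1–10, which keeps the full
  suite under two minutes while still exercising every pipeline stage
  end to end.
* Encoding is exact integer arithmetic throughout; the only tolerances in
  the package are alignment-score parameters and test-side stochastic
  margins.
* Degenerate inputs: empty files encode to zero oligos and decode to zero
  bytes; empty digit strings encode to empty sequences; single-piece
  consensus returns the piece; oligos failing any structural check
  (length, transition, symbol, address range) are flagged for erasure
  rather than raising.

## Known limitations

* The rotational code cannot constrain GC content or homopolymers in its
  output (on random bytes, per-oligo GC sits near 60%, between roughly
  50% and 70%, because G, C and M are three of the five letters);
  sequence-constrained transcoding is out of scope.
* XOR parity recovers erasures, not silent substitutions: a corrupted
  oligo that still decodes validly (possible, since only transitions
  into the same letter are detectable) passes its wrong bytes through.
* The greedy adaptor set is maximal but not proven maximum; 48 ≥ 27
  suffices for the staged-assembly layout.
* `decode_read_store()`'s with-reference mode is quadratic in pieces ×
  reference oligos (one alignment each); it is intended for the small
  per-fragment stores of the validation design, not genome-scale input.
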