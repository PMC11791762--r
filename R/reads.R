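#' Configuration for the synthetic nanopore-like read generator
#'
#' The generator emulates what a methylation-aware nanopore basecaller
#' emits for an assembled fragment: base sequences over {A, C, G, T}
#' (5mC reads as C) plus, for every basecalled C, an integer 0-255
#' methylation probability. Methylation-call fidelity is controlled by
#' two confusion rates: `m_miscall` is the chance a true 5mC site gets a
#' sub-threshold probability (read as C), `c_miscall` the chance a plain
#' C gets a super-threshold one (read as M). Base-level errors use
#' separate substitution/insertion/deletion rates.
#'
#' @param depth Reads per fragment (default 10, the design sequencing
#'   depth).
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities.
#' @param m_miscall,c_miscall Methylation confusion probabilities.
#' @param barcode_5p,barcode_3p Flanking barcode sequences (may be "").
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(depth = 10L, sub_rate = 0.002, ins_rate = 0.002,
                            del_rate = 0.002, m_miscall = 0.05,
                            c_miscall = 0.05,
                            barcode_5p = "TTACGGTCAAGGCTAA",
                            barcode_3p = "TTAGCCTTGACCGTAA") {
  stopifnot(
    depth >= 1,
    all(c(sub_rate, ins_rate, del_rate, m_miscall, c_miscall) >= 0),
    sub_rate + ins_rate + del_rate <= 1, m_miscall <= 1, c_miscall <= 1
  )
  structure(
    list(
      depth = as.integer(depth), sub_rate = sub_rate, ins_rate = ins_rate,
      del_rate = del_rate, m_miscall = m_miscall, c_miscall = c_miscall,
      barcode_5p = barcode_5p, barcode_3p = barcode_3p
    ),
    class = "read_sim_config"
  )
}

sample_meth_prob <- function(n, methylated) {
  # uniform within the called half of the 0-255 scale; threshold is 128
  if (methylated) {
    sample(128:255, n, replace = TRUE)
  } else {
    sample(0:127, n, replace = TRUE)
  }
}

simulate_one_read <- function(template_chars, is_m, cfg) {
  bases <- ifelse(is_m, "C", template_chars)
  n <- length(bases)
  natural <- c("A", "C", "G", "T")
  u <- stats::runif(n)
  p1 <- cfg$sub_rate
  p2 <- p1 + cfg$ins_rate
  p3 <- p2 + cfg$del_rate
  out_base <- as.list(bases)
  out_m <- as.list(is_m)
  for (i in which(u < p3)) {
    if (u[i] < p1) {                       # substitution
      cur <- match(bases[i], natural)
      pick <- sample.int(3L, 1L)
      if (!is.na(cur) && pick >= cur) pick <- pick + 1L
      out_base[[i]] <- natural[pick]
      out_m[[i]] <- FALSE
    } else if (u[i] < p2) {                # insertion after position
      out_base[[i]] <- c(bases[i], natural[sample.int(4L, 1L)])
      out_m[[i]] <- c(is_m[i], FALSE)
    } else {                               # deletion
      out_base[[i]] <- character(0)
      out_m[[i]] <- logical(0)
    }
  }
  bases <- unlist(out_base, use.names = FALSE)
  is_m <- unlist(out_m, use.names = FALSE)

  bc5 <- chars(cfg$barcode_5p)
  bc3 <- chars(cfg$barcode_3p)
  bases <- c(bc5, bases, bc3)
  is_m <- c(rep(FALSE, length(bc5)), is_m, rep(FALSE, length(bc3)))

  meth <- rep(NA_integer_, length(bases))
  at_c <- which(bases == "C")
  for (i in at_c) {
    called_m <- if (is_m[i]) {
      stats::runif(1) >= cfg$m_miscall
    } else {
      stats::runif(1) < cfg$c_miscall
    }
    meth[i] <- sample_meth_prob(1L, called_m)
  }
  list(bases = paste(bases, collapse = ""), meth = meth)
}

#' Simulate methylation-aware reads of a fragment
#'
#' Generates `cfg$depth` noisy reads of a fragment over {A, T, C, G, M}.
#' Each read renders M as C, applies per-base substitution / insertion /
#' deletion errors, attaches the configured barcodes at both ends, and
#' assigns a 0-255 methylation probability to every basecalled C: high
#' (>= 128) at faithfully called 5mC sites, low (< 128) at plain C, with
#' the configured confusion rates flipping calls. Reproducible under
#' `set.seed()`.
#'
#' @param fragment Fragment sequence over {A, T, C, G, M}.
#' @param cfg A [read_sim_config()].
#' @param source Optional label stored with each read (e.g. a fragment
#'   id, useful as a truth label for synthetic benchmarking).
#' @return A tibble with `read` (integer id), `source`, `bases`
#'   (character) and `meth` (list of integer vectors, NA away from C).
#' @examples
#' set.seed(1)
#' simulate_reads("GACAMTGCA", read_sim_config(depth = 2))
#' @export
simulate_reads <- function(fragment, cfg = read_sim_config(), source = NA_character_) {
  stopifnot(nchar(fragment) > 0)
  tc <- chars(fragment)
  is_m <- tc == "M"
  out <- lapply(seq_len(cfg$depth), function(i) {
    simulate_one_read(tc, is_m, cfg)
  })
  tibble::tibble(
    read = seq_len(cfg$depth),
    source = source,
    bases = vapply(out, `[[`, character(1), "bases"),
    meth = lapply(out, `[[`, "meth")
  )
}

#' Simulate a read set for many fragments
#'
#' @param fragments Character vector of fragment sequences (names, if
#'   present, become the `source` labels).
#' @inheritParams simulate_reads
#' @return One tibble of reads across all fragments.
#' @export
simulate_read_set <- function(fragments, cfg = read_sim_config()) {
  labels <- names(fragments)
  if (is.null(labels)) labels <- as.character(seq_along(fragments))
  dplyr::bind_rows(lapply(seq_along(fragments), function(i) {
    simulate_reads(fragments[i], cfg, source = labels[i])
  }))
}

#' Call methylation on a basecalled read
#'
#' Rewrites every basecalled C whose methylation probability is at or
#' above the threshold as M. The 0-1 probabilities are carried on the
#' 0-255 integer scale; the default threshold 128 is inclusive, so a
#' probability of exactly 128 is called methylated.
#'
#' @param bases Base string over {A, C, G, T} (an already-extended string
#'   is tolerated).
#' @param meth Integer vector of per-position methylation probabilities
#'   (NA away from C), same length as `bases`.
#' @param threshold Inclusive methylation threshold (default 128).
#' @return A letter string over {A, T, C, G, M}.
#' @examples
#' call_methylation("ACGC", c(NA, 200L, NA, 10L))  # "AMGC"
#' @export
call_methylation <- function(bases, meth, threshold = 128L) {
  cc <- chars(bases)
  stopifnot(length(meth) == length(cc))
  hit <- which(cc == "C" & !is.na(meth) & meth >= threshold)
  cc[hit] <- "M"
  paste(cc, collapse = "")
}

#' Filter reads by alignment identity to a reference
#'
#' Keeps reads whose best semi-global identity against any of the
#' supplied reference fragments meets the threshold (inclusive at the
#' default 0.85 boundary).
#'
#' @param reads Read tibble from [simulate_reads()] (or any data frame
#'   with a `bases` column), or a character vector of sequences.
#' @param references Character vector of reference fragment sequences.
#' @param min_identity Inclusive identity threshold (default 0.85).
#' @return The surviving subset, with `identity` and `best_reference`
#'   (index) columns added when the input is a data frame.
#' @export
filter_reads <- function(reads, references, min_identity = 0.85) {
  seqs <- if (is.data.frame(reads)) reads$bases else reads
  best <- t(vapply(seqs, function(s) {
    ids <- vapply(references, alignment_identity, numeric(1), read = s,
      USE.NAMES = FALSE
    )
    c(which.max(ids), max(ids))
  }, numeric(2), USE.NAMES = FALSE))
  keep <- best[, 2] >= min_identity
  if (is.data.frame(reads)) {
    out <- reads[keep, , drop = FALSE]
    out$best_reference <- as.integer(best[keep, 1])
    out$identity <- best[keep, 2]
    out
  } else {
    seqs[keep]
  }
}

find_motif_ranges <- function(subject_collapsed, motif, max_mismatch = 1L) {
  # exact matches first; fall back to allowing one mismatch
  hits <- Biostrings::matchPattern(motif, Biostrings::BString(subject_collapsed))
  if (length(hits) == 0 && max_mismatch > 0) {
    hits <- Biostrings::matchPattern(
      motif, Biostrings::BString(subject_collapsed),
      max.mismatch = max_mismatch, with.indels = FALSE
    )
  }
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  tibble::tibble(
    start = BiocGenerics::start(hits),
    end = BiocGenerics::end(hits)
  )
}

#' Trim barcodes, split at adaptors, and size-filter
#'
#' Reproduces the read post-processing stage: flanking barcodes are
#' located (exact match, then a one-mismatch fallback) and removed,
#' the read is split at every assembly-adaptor occurrence, and only
#' pieces between 80 and 120 nt (inclusive) survive -- the window around
#' the 100-nt design length that tolerates moderate indels. Matching is
#' done on an M-to-C collapsed copy, since barcodes and adaptors are
#' unmethylated, but the returned pieces keep their M letters.
#'
#' @param seq A called read string over {A, T, C, G, M}.
#' @param barcodes Character vector of barcode sequences to strip from
#'   the ends (empty strings are ignored).
#' @param adaptors Character vector of adaptor sequences (or an
#'   `adaptor_set` tibble).
#' @param min_length,max_length Inclusive piece-length window (defaults
#'   80 and 120).
#' @param max_mismatch Mismatch tolerance of the fallback motif search.
#' @return Character vector of retained pieces.
#' @export
trim_and_size_filter <- function(seq, barcodes = character(0), adaptors,
                                 min_length = 80L, max_length = 120L,
                                 max_mismatch = 1L) {
  if (is.data.frame(adaptors)) adaptors <- adaptors$adaptor
  collapsed <- gsub("M", "C", seq, fixed = TRUE)
  n <- nchar(seq)

  cut <- tibble::tibble(start = integer(0), end = integer(0))
  for (bc in barcodes[nzchar(barcodes)]) {
    r <- find_motif_ranges(collapsed, bc, max_mismatch)
    # barcodes flank the read: trim everything outside the innermost hits
    near5 <- r[r$start <= nchar(bc) + 5L, , drop = FALSE]
    near3 <- r[r$end >= n - nchar(bc) - 4L, , drop = FALSE]
    if (nrow(near5) > 0) {
      cut <- dplyr::bind_rows(cut, tibble::tibble(start = 1L, end = max(near5$end)))
    }
    if (nrow(near3) > 0) {
      cut <- dplyr::bind_rows(cut, tibble::tibble(start = min(near3$start), end = n))
    }
  }
  # exact adaptor occurrences split the read into oligo-sized pieces;
  # the mismatch-tolerant fallback is applied only inside pieces still
  # longer than the window, so a stray near-match cannot chop a good oligo
  for (ad in adaptors) {
    cut <- dplyr::bind_rows(cut, find_motif_ranges(collapsed, ad, 0L))
  }
  if (max_mismatch > 0) {
    repeat {
      gaps <- gaps_from_cuts(n, cut)
      long <- gaps[gaps$end - gaps$start + 1L > max_length, , drop = FALSE]
      added <- 0L
      for (g in seq_len(nrow(long))) {
        sub <- substr(collapsed, long$start[g], long$end[g])
        for (ad in adaptors) {
          hits <- suppressWarnings(Biostrings::matchPattern(
            ad, Biostrings::BString(sub),
            max.mismatch = max_mismatch, with.indels = TRUE
          ))
          if (length(hits) > 0) {
            cut <- dplyr::bind_rows(cut, tibble::tibble(
              start = BiocGenerics::start(hits) + long$start[g] - 1L,
              end = BiocGenerics::end(hits) + long$start[g] - 1L
            ))
            added <- added + length(hits)
          }
        }
      }
      if (added == 0L) break
    }
  }
  pieces_from_cuts(seq, cut, min_length, max_length)
}

# uncut intervals (1-based, inclusive) left between merged cut ranges
gaps_from_cuts <- function(n, cut) {
  if (nrow(cut) == 0) return(tibble::tibble(start = 1L, end = n))
  bounds <- merge_ranges(cut)
  starts <- c(1L, bounds[, 2] + 1L)
  ends <- c(bounds[, 1] - 1L, n)
  keep <- starts <= ends
  tibble::tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

merge_ranges <- function(cut) {
  cut <- cut[order(cut$start, cut$end), , drop = FALSE]
  merged <- list()
  cur <- c(cut$start[1], cut$end[1])
  for (i in seq_len(nrow(cut))[-1]) {
    if (cut$start[i] <= cur[2] + 1L) {
      cur[2] <- max(cur[2], cut$end[i])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- c(cut$start[i], cut$end[i])
    }
  }
  merged[[length(merged) + 1L]] <- cur
  do.call(rbind, merged)
}

pieces_from_cuts <- function(seq, cut, min_length, max_length) {
  gaps <- gaps_from_cuts(nchar(seq), cut)
  pieces <- substring(seq, gaps$start, gaps$end)
  pieces[nchar(pieces) >= min_length & nchar(pieces) <= max_length]
}

#' Majority consensus from a star multiple sequence alignment
#'
#' Aligns every piece globally to a centre piece (the one whose length is
#' closest to the median), stacks the alignments into common columns
#' (centre positions plus insertion columns keyed to the preceding
#' centre position), and emits the per-column majority letter. A column
#' emits nothing when gaps are at least as frequent as the best letter;
#' letter ties break by the fixed precedence A < T < C < G < M.
#'
#' @param pieces Character vector of letter strings covering the same
#'   oligo (at least one).
#' @return The consensus letter string.
#' @examples
#' msa_consensus(c("GACA", "GACA", "GTCA"))  # "GACA"
#' @export
msa_consensus <- function(pieces) {
  if (length(pieces) == 0) stop("no pieces to align", call. = FALSE)
  pieces <- pieces[nchar(pieces) > 0]
  if (length(pieces) == 0) stop("all pieces empty", call. = FALSE)
  if (length(pieces) == 1) return(pieces)

  lens <- nchar(pieces)
  centre_i <- which.min(abs(lens - stats::median(lens)))
  centre <- pieces[centre_i]
  clen <- nchar(centre)
  n <- length(pieces)
  offset_base <- 1e6  # column key = centre_pos * offset_base + insert_offset

  keys <- list()
  letters_v <- list()
  # the centre votes for itself
  keys[[1]] <- seq_len(clen) * offset_base
  letters_v[[1]] <- chars(centre)
  idx <- 2L
  for (i in seq_len(n)[-centre_i]) {
    aln <- align_pair(pieces[i], centre, type = "global")
    s <- aligned_strings(aln)
    pa <- chars(s$pattern)
    sa <- chars(s$subject)
    j <- 0L
    off <- 0L
    kk <- numeric(length(pa))
    for (c_i in seq_along(pa)) {
      if (sa[c_i] != "-") {
        j <- j + 1L
        off <- 0L
      } else {
        off <- off + 1L
      }
      kk[c_i] <- j * offset_base + off
    }
    keys[[idx]] <- kk
    letters_v[[idx]] <- pa
    idx <- idx + 1L
  }
  key <- unlist(keys)
  letter <- unlist(letters_v)

  precedence <- c("A", "T", "C", "G", "M")
  ord <- order(key)
  key <- key[ord]
  letter <- letter[ord]
  out <- character(0)
  for (k in unique(key)) {
    sel <- letter[key == k]
    is_insert <- (k %% offset_base) != 0
    gap_votes <- if (is_insert) n - length(sel) + sum(sel == "-") else sum(sel == "-")
    counts <- table(factor(sel[sel != "-"], levels = precedence))
    extra <- table(sel[!(sel %in% c(precedence, "-"))])
    if (length(extra)) counts <- c(counts, extra)
    if (sum(counts) == 0) next
    best <- which.max(counts)  # which.max takes the first maximum: precedence
    if (counts[best] > gap_votes) out <- c(out, names(counts)[best])
  }
  paste(out, collapse = "")
}
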