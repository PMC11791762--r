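#' Enumerate candidate adaptor sequences
#'
#' All `4^length` sequences over {A, C, G, T} in lexicographic order
#' (A < C < G < T). Ligation adaptors are unmethylated, so candidates are
#' drawn from the four natural bases only.
#'
#' @param length Adaptor length in nt (default 8).
#' @return Character vector of `4^length` sequences.
#' @export
enumerate_candidates <- function(length = 8L) {
  stopifnot(length >= 1)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(
    rep(list(bases), length),
    stringsAsFactors = FALSE
  ))
  # expand.grid varies the first column fastest; reverse for lexicographic
  do.call(paste0, rev(grid))
}

#' Composition filter for adaptor candidates
#'
#' Retains sequences with GC content between 40% and 60% (inclusive) and
#' no homopolymer longer than 2 nt. For 8-mers the GC window admits only
#' sequences with exactly four G/C letters, since 3/8 and 5/8 fall
#' outside [0.4, 0.6].
#'
#' @param candidates Character vector of equal-length sequences.
#' @param gc_min,gc_max GC bounds, inclusive.
#' @param max_run Longest allowed homopolymer.
#' @return The surviving subset, in input order.
#' @export
composition_filter <- function(candidates, gc_min = 0.4, gc_max = 0.6,
                               max_run = 2L) {
  if (length(candidates) == 0) return(character(0))
  len <- nchar(candidates[1])
  stopifnot(all(nchar(candidates) == len))
  m <- matrix(unlist(strsplit(candidates, "", fixed = TRUE)), nrow = len)
  gc <- colMeans(m == "G" | m == "C")
  runs <- if (len >= 2) {
    im <- matrix(match(m, c("A", "C", "G", "T", "M")), nrow = len)
    max_run_by_col(im)
  } else rep(1L, length(candidates))
  candidates[gc >= gc_min & gc <= gc_max & runs <= max_run]
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Strings of equal length.
#' @return Count of mismatching positions.
#' @examples
#' hamming("AAAAAAAA", "TTTTTTTT")  # 8
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length", call. = FALSE)
  sum(chars(a) != chars(b))
}

# n x len character matrix from equal-length strings
seq_matrix <- function(seqs) {
  t(matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = length(seqs)))
}

#' Select mutually distant adaptors
#'
#' Two selection modes over the composition-filtered survivors, both
#' requiring Hamming distance strictly greater than `min_distance - 1`
#' (i.e. >= `min_distance`) between retained adaptors:
#'
#' * `"greedy"` (default): scan survivors in lexicographic order and keep
#'   a sequence iff it is at distance >= `min_distance` from everything
#'   already kept. This is deterministic greedy code construction and
#'   always yields a usable set.
#' * `"literal"`: keep a sequence iff it is at distance >= `min_distance`
#'   from *every other survivor*. Read literally this all-pairs filter
#'   can annihilate the set (for the default 8-mer parameters it keeps
#'   nothing, since every survivor has some near neighbour), so it is
#'   retained for comparison rather than use.
#'
#' @param survivors Character vector from [composition_filter()].
#' @param min_distance Minimum pairwise Hamming distance (default 5,
#'   i.e. distance strictly greater than 4).
#' @param mode `"greedy"` or `"literal"`.
#' @return An object of class `adaptor_set`: tibble of `adaptor`
#'   sequences with attributes `min_distance` and `mode`.
#' @export
select_adaptors <- function(survivors, min_distance = 5L,
                            mode = c("greedy", "literal")) {
  mode <- match.arg(mode)
  if (length(survivors) == 0) {
    return(new_adaptor_set(character(0), min_distance, mode))
  }
  m <- seq_matrix(survivors)
  len <- ncol(m)
  if (mode == "greedy") {
    kept <- matrix(character(0), ncol = len)
    kept_idx <- integer(0)
    for (i in seq_along(survivors)) {
      if (nrow(kept) == 0) {
        ok <- TRUE
      } else {
        d <- rowSums(kept != matrix(m[i, ], nrow(kept), len, byrow = TRUE))
        ok <- all(d >= min_distance)
      }
      if (ok) {
        kept <- rbind(kept, m[i, ])
        kept_idx <- c(kept_idx, i)
      }
    }
    new_adaptor_set(survivors[kept_idx], min_distance, mode)
  } else {
    # one-hot encode: matches(a, b) = x_a . x_b, so the all-pairs Hamming
    # minimum comes from a blockwise crossproduct instead of a double loop
    bases <- c("A", "C", "G", "T")
    x <- matrix(0, length(survivors), len * 4L)
    for (p in seq_len(len)) {
      x[cbind(seq_along(survivors), (p - 1L) * 4L + match(m[, p], bases))] <- 1
    }
    keep <- rep(TRUE, length(survivors))
    block <- 1024L
    for (start in seq(1L, length(survivors), by = block)) {
      idx <- start:min(start + block - 1L, length(survivors))
      matches <- tcrossprod(x[idx, , drop = FALSE], x)
      matches[cbind(seq_along(idx), idx)] <- -1  # ignore self
      # distance = len - matches; require all distances >= min_distance
      keep[idx] <- apply(matches, 1, max) <= len - min_distance
    }
    new_adaptor_set(survivors[keep], min_distance, mode)
  }
}

new_adaptor_set <- function(adaptors, min_distance, mode) {
  structure(
    tibble::tibble(adaptor = adaptors),
    min_distance = min_distance, mode = mode,
    class = c("adaptor_set", class(tibble::tibble()))
  )
}

#' Full adaptor design pipeline
#'
#' Enumerates all candidates, applies the composition filter and selects
#' a distance-separated set.
#'
#' @inheritParams enumerate_candidates
#' @inheritParams select_adaptors
#' @param check_revcomp Also drop adaptors equal to the reverse
#'   complement of an earlier-kept adaptor (greedy mode only).
#' @return An `adaptor_set`.
#' @examples
#' \donttest{
#' ad <- design_adaptors()
#' nrow(ad)
#' }
#' @export
design_adaptors <- function(length = 8L, min_distance = 5L,
                            mode = c("greedy", "literal"),
                            check_revcomp = FALSE) {
  mode <- match.arg(mode)
  survivors <- composition_filter(enumerate_candidates(length))
  set <- select_adaptors(survivors, min_distance, mode)
  if (check_revcomp && nrow(set) > 0) {
    rc <- reverse_complement(set$adaptor)
    drop <- logical(nrow(set))
    for (i in seq_len(nrow(set))) {
      drop[i] <- rc[i] %in% set$adaptor[seq_len(i - 1L)]
    }
    set <- new_adaptor_set(
      set$adaptor[!drop], attr(set, "min_distance"), attr(set, "mode")
    )
  }
  set
}

reverse_complement <- function(seqs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(seqs, function(s) {
    paste(rev(comp[chars(s)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
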