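#' GC content of a letter sequence
#'
#' M is 5-methylcytosine, chemically a cytosine, so by default it counts
#' toward GC alongside G and C. With G, C and M making up three of the
#' five letters, encoded output from uniform random bytes sits around 60%
#' GC, fluctuating between roughly 50% and 70% per oligo.
#'
#' @param seq A non-empty letter string.
#' @param count_m Count M as GC (default TRUE).
#' @return GC fraction in [0, 1].
#' @examples
#' gc_content("GACA")  # 0.5
#' gc_content("MMMM")  # 1
#' @export
gc_content <- function(seq, count_m = TRUE) {
  cc <- chars(seq)
  if (length(cc) == 0) stop("empty sequence", call. = FALSE)
  set <- if (count_m) c("G", "C", "M") else c("G", "C")
  mean(cc %in% set)
}

#' Longest homopolymer run
#'
#' The rotational table never emits the same letter twice in a row, so
#' raw encoded output has a maximum run of 1 over the five-letter
#' alphabet. Chemically, however, M is a cytosine: collapsing M to C
#' (the default) measures the homopolymers the synthesis and sequencing
#' chemistry actually sees, where C/M alternations become real runs.
#'
#' @param seq A non-empty letter string.
#' @param collapse_m_to_c Rewrite M as C before measuring (default TRUE).
#' @return Length of the longest run of identical symbols (>= 1).
#' @examples
#' max_homopolymer("CMCM")                        # 4
#' max_homopolymer("CMCM", collapse_m_to_c = FALSE)  # 1
#' @export
max_homopolymer <- function(seq, collapse_m_to_c = TRUE) {
  if (nchar(seq) == 0) stop("empty sequence", call. = FALSE)
  if (collapse_m_to_c) seq <- gsub("M", "C", seq, fixed = TRUE)
  max(rle(chars(seq))$lengths)
}

# column-wise longest run of equal values in an index matrix
max_run_by_col <- function(imat) {
  nr <- nrow(imat)
  nc <- ncol(imat)
  best <- rep(1L, nc)
  if (nr < 2) return(best)
  run <- rep(1L, nc)
  for (i in 2:nr) {
    eq <- imat[i, ] == imat[i - 1L, ]
    run <- ifelse(eq, run + 1L, 1L)
    best <- pmax(best, run)
  }
  best
}

#' Profile the sequence properties of an encoding
#'
#' Encodes a byte stream into oligos (with XOR redundancy, matching the
#' stored product) and reports per-oligo GC fraction and longest
#' homopolymer (after collapsing M to C), together with aggregate
#' summaries. Larger files explore more of the byte space, so the range
#' of per-oligo GC and the overall maximum homopolymer tend to grow with
#' file size.
#'
#' @param data Raw vector.
#' @param config A [store_config()].
#' @param redundancy Include XOR segments (default TRUE).
#' @param count_m Count M as GC (default TRUE).
#' @return An object of class `encoding_profile` with `per_oligo`
#'   (tibble: address, role, gc, max_homopolymer) and `summary`.
#'   `tidy()` returns the per-oligo tibble, `glance()` the one-row
#'   summary, `autoplot()` the GC histogram.
#' @examples
#' prof <- profile_encoding(as.raw(sample(0:255, 500, replace = TRUE)))
#' glance(prof)
#' @export
profile_encoding <- function(data, config = store_config(), redundancy = TRUE,
                             count_m = TRUE) {
  segments <- segment_file(data, config$segment_length)
  if (redundancy) segments <- add_redundancy(segments)
  if (nrow(segments) == 0) stop("no segments: empty input", call. = FALSE)
  imat <- segments_to_index_matrix(segments, config)

  gc_set <- match(if (count_m) c("G", "C", "M") else c("G", "C"),
                  config$alphabet$letters) - 1L
  gc <- colMeans(matrix(imat %in% gc_set, nrow = nrow(imat)))

  # collapse M to C before measuring chemically real homopolymer runs
  collapse <- seq_len(config$alphabet$size) - 1L
  m_i <- match("M", config$alphabet$letters) - 1L
  c_i <- match("C", config$alphabet$letters) - 1L
  if (!is.na(m_i) && !is.na(c_i)) collapse[m_i + 1L] <- c_i
  cmat <- matrix(collapse[imat + 1L], nrow = nrow(imat))
  hp <- max_run_by_col(cmat)

  per_oligo <- tibble::tibble(
    address = segments$address, role = segments$role,
    gc = gc, max_homopolymer = hp
  )
  summary <- tibble::tibble(
    n_oligos = nrow(per_oligo),
    oligo_length = nrow(imat),
    gc_mean = mean(gc), gc_min = min(gc), gc_max = max(gc),
    gc_range = max(gc) - min(gc),
    hp_mean = mean(hp), hp_max = max(hp)
  )
  structure(
    list(per_oligo = per_oligo, summary = summary, n_bytes = length(data)),
    class = "encoding_profile"
  )
}

#' @export
print.encoding_profile <- function(x, ...) {
  cat("<encoding_profile> ", x$n_bytes, " bytes -> ", x$summary$n_oligos,
    " oligos\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' @rdname profile_encoding
#' @param x An `encoding_profile`.
#' @param ... Unused.
#' @method tidy encoding_profile
#' @export
tidy.encoding_profile <- function(x, ...) x$per_oligo

#' @rdname profile_encoding
#' @method glance encoding_profile
#' @export
glance.encoding_profile <- function(x, ...) x$summary

#' @rdname profile_encoding
#' @param object An `encoding_profile`.
#' @param bins Histogram bin count.
#' @method autoplot encoding_profile
#' @export
autoplot.encoding_profile <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$per_oligo, ggplot2::aes(x = gc)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(
      x = "per-oligo GC fraction (G + C + M)", y = "oligos",
      title = "GC distribution of encoded oligos"
    )
}
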