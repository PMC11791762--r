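#' Decode an oligo store from noisy methylation-aware reads
#'
#' End-to-end read-decoding pipeline: methylation calling at the 128
#' threshold, optional identity screening against reference fragments,
#' barcode/adaptor trimming with the 80-120 nt piece window, per-oligo
#' majority consensus over the aligned pieces, rotational decoding and
#' XOR-aware reassembly.
#'
#' Two modes mirror the two ways a store can be read back:
#'
#' * `"with_reference"`: reads are first screened by semi-global identity
#'   (>= `min_identity`) against the known fragment sequences, and every
#'   trimmed piece is assigned to the reference oligo it matches best.
#'   This is the analysis mode available when the stored design is at
#'   hand.
#' * `"without_reference"`: nothing but the manifest is assumed. Pieces
#'   are grouped by their decoded 12-letter address field (pieces whose
#'   address prefix is corrupt are dropped), so decoding is driven purely
#'   by the data embedded in the oligos themselves.
#'
#' In both modes unrecoverable segments fall back on XOR recovery and
#' then on zero-fill, so a recovery rate against the original (when
#' supplied) is always defined over the whole file.
#'
#' @param reads Read tibble from [simulate_reads()] /
#'   [simulate_read_set()] (columns `bases`, `meth`).
#' @param manifest A [store_manifest()].
#' @param mode `"without_reference"` (default) or `"with_reference"`.
#' @param adaptors Character vector (or `adaptor_set`) of assembly
#'   adaptors used in the layout.
#' @param barcodes Character vector of flanking barcodes to strip.
#' @param reference For `"with_reference"`: a list with `fragments`
#'   (character vector of fragment sequences) and `oligos` (tibble of
#'   `address`, `sequence`).
#' @param original Optional raw vector of the true file, for the
#'   recovery rate.
#' @param min_identity Inclusive identity threshold (default 0.85).
#' @param threshold Methylation-call threshold (default 128).
#' @param min_length,max_length Piece-length window (defaults 80, 120).
#' @return An object of class `read_decode_result`: `bytes`,
#'   `recovery_rate`, `report` (per-segment status), `consensus`
#'   (tibble: address, n_pieces, consensus), and stage counts.
#' @export
decode_read_store <- function(reads, manifest,
                              mode = c("without_reference", "with_reference"),
                              adaptors, barcodes = character(0),
                              reference = NULL, original = NULL,
                              min_identity = 0.85, threshold = 128L,
                              min_length = 80L, max_length = 120L) {
  mode <- match.arg(mode)
  config <- config_from_manifest(manifest)
  n_total <- manifest$n_data + manifest$n_xor
  if (is.data.frame(adaptors)) adaptors <- adaptors$adaptor

  called <- vapply(seq_len(nrow(reads)), function(i) {
    call_methylation(reads$bases[i], reads$meth[[i]], threshold)
  }, character(1))

  n_reads <- length(called)
  if (mode == "with_reference") {
    if (is.null(reference) || is.null(reference$fragments) ||
      is.null(reference$oligos)) {
      stop("with_reference mode needs reference$fragments and reference$oligos",
        call. = FALSE
      )
    }
    ids <- vapply(called, function(s) {
      max(vapply(reference$fragments, alignment_identity, numeric(1), read = s,
        USE.NAMES = FALSE
      ))
    }, numeric(1), USE.NAMES = FALSE)
    called <- called[ids >= min_identity]
  }
  n_kept <- length(called)

  pieces <- unlist(lapply(called, trim_and_size_filter,
    barcodes = barcodes, adaptors = adaptors,
    min_length = min_length, max_length = max_length
  ), use.names = FALSE)
  if (is.null(pieces)) pieces <- character(0)

  if (mode == "with_reference") {
    # global identity here: pieces and oligos are the same design length,
    # and an overlap alignment would score a short shared prefix as a
    # perfect (but meaningless) match
    address <- vapply(pieces, function(p) {
      ids <- vapply(reference$oligos$sequence, alignment_identity, numeric(1),
        read = p, type = "global", USE.NAMES = FALSE
      )
      if (max(ids) >= min_identity) {
        reference$oligos$address[which.max(ids)]
      } else {
        NA_integer_
      }
    }, integer(1), USE.NAMES = FALSE)
  } else {
    address <- vapply(pieces, decode_address_prefix, integer(1),
      config = config, n_expected = n_total, USE.NAMES = FALSE
    )
  }
  keep <- !is.na(address)
  pieces <- pieces[keep]
  address <- address[keep]

  consensus <- if (length(pieces)) {
    tibble::tibble(address = address, piece = pieces) |>
      dplyr::group_by(address) |>
      dplyr::summarise(
        n_pieces = dplyr::n(),
        consensus = msa_consensus(piece),
        .groups = "drop"
      )
  } else {
    tibble::tibble(
      address = integer(0), n_pieces = integer(0), consensus = character(0)
    )
  }

  recovery <- reassemble_file(consensus$consensus, manifest, original = original)
  structure(
    list(
      bytes = recovery$bytes,
      recovery_rate = recovery$recovery_rate,
      report = recovery$report,
      consensus = consensus,
      mode = mode,
      n_reads = n_reads,
      n_reads_kept = n_kept,
      n_pieces = length(pieces)
    ),
    class = "read_decode_result"
  )
}

#' @export
print.read_decode_result <- function(x, ...) {
  cat(
    "<read_decode_result> mode=", x$mode, "; reads ", x$n_reads_kept, "/",
    x$n_reads, " kept, ", x$n_pieces, " pieces, ", nrow(x$consensus),
    " consensus oligos",
    if (!is.na(x$recovery_rate)) {
      sprintf("; bit recovery %.4f", x$recovery_rate)
    } else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

# decode the address field of a (possibly indel-shifted) piece; NA when
# the prefix is corrupt or out of range
decode_address_prefix <- function(piece, config, n_expected = NULL) {
  al <- config$address_length
  if (nchar(piece) < al) return(NA_integer_)
  cc <- chars(substr(piece, 1L, al))
  idx <- letter_index(cc, config$alphabet)
  if (anyNA(idx)) return(NA_integer_)
  k <- config$alphabet$size
  p0 <- match(config$initial_prev, config$alphabet$letters) - 1L
  d <- (idx - c(p0, idx[-al]) - 1L) %% k
  if (any(d == k - 1L)) return(NA_integer_)
  address <- sum(d * config$alphabet$radix^((al - 1L):0))
  if (!is.null(n_expected) && address >= n_expected) return(NA_integer_)
  as.integer(address)
}
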