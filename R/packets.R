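#' Store configuration
#'
#' Collects the constants that shape an oligo store. The defaults
#' reproduce the reference design: 22-byte segments, a 12-letter (24-bit)
#' address field, and 100-letter oligos under the quinary alphabet
#' (12 address digits + 22 bytes x 4 digits = 100 digits = 100 letters).
#'
#' @param segment_length Payload bytes per segment (default 22).
#' @param address_length Letters of the address field (default 12).
#' @param alphabet An [expanded_alphabet()].
#' @param initial_prev Virtual previous letter restarted at the top of
#'   every oligo, so each oligo decodes independently.
#' @return A list of class `store_config`, including the derived
#'   `oligo_length`.
#' @export
store_config <- function(segment_length = 22L, address_length = 12L,
                         alphabet = expanded_alphabet(), initial_prev = "A") {
  stopifnot(segment_length >= 1, address_length >= 1)
  table <- rotation_table(alphabet)
  dpb <- digits_per_byte(alphabet$radix)
  structure(
    list(
      segment_length = as.integer(segment_length),
      address_length = as.integer(address_length),
      alphabet = alphabet,
      table = table,
      digits_per_byte = dpb,
      initial_prev = initial_prev,
      oligo_length = as.integer(address_length + segment_length * dpb),
      address_capacity = alphabet$radix^address_length
    ),
    class = "store_config"
  )
}

#' Split a byte stream into addressed fixed-size segments
#'
#' @param data Raw vector (file contents).
#' @param segment_length Bytes per segment; the last segment is padded
#'   with zero bytes.
#' @return A tibble with columns `address` (0-based integer), `role`
#'   (`"data"`) and `payload` (list of raw vectors of equal length).
#' @examples
#' segment_file(as.raw(1:45))  # 3 segments of 22 bytes, last one padded
#' @export
segment_file <- function(data, segment_length = 22L) {
  stopifnot(is.raw(data), segment_length >= 1)
  n_seg <- ceiling(length(data) / segment_length)
  if (n_seg == 0) {
    return(tibble::tibble(
      address = integer(0), role = character(0), payload = list()
    ))
  }
  padded <- c(data, raw(n_seg * segment_length - length(data)))
  payloads <- split(padded, rep(seq_len(n_seg), each = segment_length))
  tibble::tibble(
    address = seq_len(n_seg) - 1L,
    role = "data",
    payload = unname(payloads)
  )
}

#' XOR redundancy over segment pairs
#'
#' `xor_segment()` combines two equal-length payloads bytewise with
#' exclusive-or; `recover_segment()` is the same operation, named for its
#' use: within a triple (X, Y, Z = X xor Y), any member is the XOR of the
#' other two. `add_redundancy()` appends one XOR segment per pair of
#' consecutive data segments (2k, 2k+1); an odd trailing segment is paired
#' with an implicit all-zero segment so the recovery algebra stays
#' uniform. For D data segments the store then holds D + ceiling(D/2)
#' oligos, i.e. one third redundancy when D is even.
#'
#' @param x,y Raw vectors of equal length.
#' @return `xor_segment()`/`recover_segment()`: a raw vector.
#' @examples
#' x <- as.raw(1:4); y <- as.raw(9:12)
#' z <- xor_segment(x, y)
#' identical(recover_segment(y, z), x)
#' @export
xor_segment <- function(x, y) {
  if (length(x) != length(y)) {
    stop("payload lengths differ: ", length(x), " vs ", length(y), call. = FALSE)
  }
  as.raw(bitwXor(as.integer(x), as.integer(y)))
}

#' @rdname xor_segment
#' @export
recover_segment <- function(x, y) xor_segment(x, y)

#' @rdname xor_segment
#' @param segments A data-segment tibble from [segment_file()].
#' @return `add_redundancy()`: the input tibble with XOR segments
#'   appended, addressed consecutively after the data block.
#' @export
add_redundancy <- function(segments) {
  n_data <- nrow(segments)
  if (n_data == 0) return(segments)
  stopifnot(identical(segments$address, seq_len(n_data) - 1L))
  seg_len <- length(segments$payload[[1]])
  n_xor <- ceiling(n_data / 2)
  xor_payloads <- lapply(seq_len(n_xor) - 1L, function(k) {
    a <- segments$payload[[2L * k + 1L]]
    b <- if (2L * k + 2L <= n_data) segments$payload[[2L * k + 2L]] else raw(seg_len)
    xor_segment(a, b)
  })
  dplyr::bind_rows(
    segments,
    tibble::tibble(
      address = n_data + seq_len(n_xor) - 1L,
      role = "xor",
      payload = xor_payloads
    )
  )
}

# digits of an address, MSB first, over address_length positions
address_to_digits <- function(address, config) {
  n <- config$alphabet$radix
  pow <- n^((config$address_length - 1L):0)
  if (any(address >= config$address_capacity)) {
    stop("address exceeds the ", config$address_length,
      "-letter field capacity", call. = FALSE
    )
  }
  outer(pow, address, function(p, a) (a %/% p) %% n)
}

#' Build and decode 100-letter oligos
#'
#' An oligo carries the segment address (12 base-4 digits, most
#' significant first) followed by the payload digits, transcoded as one
#' digit stream through the rotational table with the virtual previous
#' letter restarted at the first position. `decode_oligo()` inverts this
#' and never throws on corrupt input: an oligo of the wrong length, with
#' an impossible letter transition, or with an out-of-range address is
#' returned flagged invalid so the store can fall back on XOR recovery.
#'
#' @param payload Raw vector of `segment_length` bytes.
#' @param address Non-negative integer segment address.
#' @param config A [store_config()].
#' @return `build_oligo()`: a single letter string of `oligo_length`
#'   characters.
#' @examples
#' cfg <- store_config()
#' o <- build_oligo(as.raw(1:22), address = 0, config = cfg)
#' nchar(o)  # 100
#' decode_oligo(o, config = cfg)$address
#' @export
build_oligo <- function(payload, address, config = store_config()) {
  stopifnot(length(payload) == config$segment_length)
  digits <- c(
    as.integer(address_to_digits(address, config)),
    bytes_to_digits(payload, config$alphabet$radix)
  )
  encode_digits(digits, config$table, config$initial_prev)
}

# Letter-index matrix (0-based, one oligo per column) for a segment tibble.
segments_to_index_matrix <- function(segments, config = store_config()) {
  addr_digits <- address_to_digits(segments$address, config)
  payload_digits <- matrix(
    bytes_to_digits(
      unlist(segments$payload, use.names = FALSE),
      config$alphabet$radix
    ),
    ncol = nrow(segments)
  )
  dmat <- rbind(addr_digits, payload_digits)
  encode_digit_matrix(dmat, config$table, config$initial_prev)
}

# Vectorised builder: segments tibble -> oligo sequence per row.
build_oligos <- function(segments, config = store_config()) {
  if (nrow(segments) == 0) {
    return(tibble::tibble(
      address = integer(0), role = character(0), sequence = character(0)
    ))
  }
  imat <- segments_to_index_matrix(segments, config)
  tibble::tibble(
    address = segments$address,
    role = segments$role,
    sequence = index_matrix_to_strings(imat, config$alphabet)
  )
}

#' @rdname build_oligo
#' @param sequence A letter string (possibly corrupted).
#' @param n_expected Optional total segment count; decoded addresses at or
#'   beyond it are flagged invalid.
#' @return `decode_oligo()`: a list with `address`, `payload`, `valid`
#'   and `reason` (`NA`, `"length"`, `"transition"`, `"symbol"` or
#'   `"address"`).
#' @export
decode_oligo <- function(sequence, config = store_config(), n_expected = NULL) {
  invalid <- function(reason) {
    list(address = NA_integer_, payload = NULL, valid = FALSE, reason = reason)
  }
  if (nchar(sequence) != config$oligo_length) return(invalid("length"))
  cc <- chars(sequence)
  idx <- letter_index(cc, config$alphabet)
  if (anyNA(idx)) return(invalid("symbol"))
  k <- config$alphabet$size
  p0 <- match(config$initial_prev, config$alphabet$letters) - 1L
  d <- (idx - c(p0, idx[-length(idx)]) - 1L) %% k
  if (any(d == k - 1L)) return(invalid("transition"))
  al <- config$address_length
  address <- sum(d[seq_len(al)] * config$alphabet$radix^((al - 1L):0))
  if (!is.null(n_expected) && address >= n_expected) return(invalid("address"))
  payload <- digits_to_bytes(d[-seq_len(al)], config$alphabet$radix)
  list(address = as.integer(address), payload = payload, valid = TRUE,
       reason = NA_character_)
}

# Decode many (possibly corrupted) oligo sequences into a segment tibble.
decode_oligos <- function(sequences, config = store_config(), n_expected = NULL) {
  res <- lapply(sequences, decode_oligo, config = config, n_expected = n_expected)
  tibble::tibble(
    address = vapply(res, `[[`, integer(1), "address"),
    payload = lapply(res, `[[`, "payload"),
    valid = vapply(res, `[[`, logical(1), "valid"),
    reason = vapply(res, `[[`, character(1), "reason")
  )
}
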