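#' Convert bytes to base-N digits and back
#'
#' Each byte is expanded independently into the fixed number of base-N
#' digits needed to represent 255 (four digits for N = 4), most-significant
#' digit first, so byte boundaries are preserved and any segment of the
#' stream can be decoded in isolation. `digits_to_bytes()` is the exact
#' inverse.
#'
#' @param data A raw vector (or integer vector of values 0..255).
#' @param radix Base N, at least 2. Default 4, the quinary-alphabet radix.
#' @return `bytes_to_digits()`: integer vector of digits in 0..N-1 with
#'   length `length(data) * digits_per_byte(radix)`. `digits_to_bytes()`:
#'   a raw vector.
#' @examples
#' bytes_to_digits(as.raw(150))        # 2 1 1 2
#' digits_to_bytes(c(2L, 1L, 1L, 2L))  # 96 (hex) == byte 150
#' @export
bytes_to_digits <- function(data, radix = 4L) {
  if (radix < 2) stop("radix must be >= 2", call. = FALSE)
  b <- as.integer(data)
  if (any(b < 0 | b > 255)) stop("byte values must be in 0..255", call. = FALSE)
  dpb <- digits_per_byte(radix)
  pow <- radix^((dpb - 1L):0)
  # outer() expands every byte into its dpb digits, MSB first
  out <- t(outer(b, pow, function(x, p) (x %/% p) %% radix))
  as.integer(out)
}

#' @rdname bytes_to_digits
#' @param digits Integer vector of base-N digits, length divisible by
#'   `digits_per_byte(radix)`.
#' @export
digits_to_bytes <- function(digits, radix = 4L) {
  if (radix < 2) stop("radix must be >= 2", call. = FALSE)
  digits <- as.integer(digits)
  if (any(digits < 0 | digits >= radix)) {
    stop("digit out of range for radix ", radix, call. = FALSE)
  }
  dpb <- digits_per_byte(radix)
  if (length(digits) %% dpb != 0) {
    stop("digit count not divisible by ", dpb, " digits per byte", call. = FALSE)
  }
  pow <- radix^((dpb - 1L):0)
  m <- matrix(digits, nrow = dpb)
  vals <- as.integer(colSums(m * pow))
  if (any(vals > 255)) stop("digit group exceeds byte range", call. = FALSE)
  as.raw(vals)
}

#' @rdname bytes_to_digits
#' @export
digits_per_byte <- function(radix = 4L) {
  if (radix < 2) stop("radix must be >= 2", call. = FALSE)
  as.integer(ceiling(log(256) / log(radix) - 1e-9))
}

#' Rotational transcoding between digit strings and letter sequences
#'
#' `encode_digits()` walks the digit string through the rotational table:
#' letter i is `forward(letter[i - 1], digit[i])`, with the virtual letter
#' (default `A`) standing in as the previous letter of the first position.
#' Because the cyclic table construction reduces to index arithmetic, the
#' whole sequence is computed with one cumulative sum. `decode_letters()`
#' inverts the walk and signals corruption: a letter equal to its
#' predecessor (or a first letter equal to the virtual letter) has no
#' preimage under the table.
#'
#' @param digits Integer vector of digits in 0..N-1.
#' @param table A [rotation_table()].
#' @param initial_prev The virtual previous letter for position 1.
#' @return `encode_digits()`: a single string over the alphabet, same
#'   length as `digits`. `decode_letters()`: an integer vector of digits.
#' @examples
#' tab <- rotation_table()
#' encode_digits(c(2L, 1L, 1L, 2L), tab)  # "GACA"
#' decode_letters("GACA", tab)            # 2 1 1 2
#' @export
encode_digits <- function(digits, table = rotation_table(), initial_prev = "A") {
  digits <- as.integer(digits)
  k <- table$alphabet$size
  if (length(digits) == 0) return("")
  if (any(digits < 0 | digits >= table$alphabet$radix)) {
    stop("digit out of range for radix ", table$alphabet$radix, call. = FALSE)
  }
  p0 <- match(initial_prev, table$alphabet$letters) - 1L
  if (is.na(p0)) stop("initial_prev not in alphabet", call. = FALSE)
  idx <- (p0 + cumsum(1L + digits)) %% k
  paste(table$alphabet$letters[idx + 1L], collapse = "")
}

#' @rdname encode_digits
#' @param seq A string over the alphabet.
#' @export
decode_letters <- function(seq, table = rotation_table(), initial_prev = "A") {
  k <- table$alphabet$size
  cc <- chars(seq)
  if (length(cc) == 0) return(integer(0))
  idx <- letter_index(cc, table$alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("symbol '", cc[bad], "' at position ", bad, " not in alphabet",
      call. = FALSE
    )
  }
  p0 <- match(initial_prev, table$alphabet$letters) - 1L
  if (is.na(p0)) stop("initial_prev not in alphabet", call. = FALSE)
  prev <- c(p0, idx[-length(idx)])
  d <- (idx - prev - 1L) %% k
  if (any(d == k - 1L)) {
    pos <- which(d == k - 1L)[1]
    stop(invalid_transition_error(pos))
  }
  d
}

invalid_transition_error <- function(position) {
  structure(
    class = c("methylstore_invalid_transition", "error", "condition"),
    list(
      message = paste0(
        "invalid transition at position ", position,
        ": letter equals its previous letter"
      ),
      call = NULL, position = position
    )
  )
}

# Vectorised core used by the packetizer: encode a digit matrix (one oligo
# per column, all the same length) into letter-index matrix, each column
# restarted at the virtual letter.
encode_digit_matrix <- function(dmat, table, initial_prev = "A") {
  k <- table$alphabet$size
  p0 <- match(initial_prev, table$alphabet$letters) - 1L
  steps <- dmat + 1L
  (p0 + apply_cumsum(steps)) %% k
}

# column-wise cumsum without apply() copies
apply_cumsum <- function(m) {
  if (is.null(dim(m))) return(cumsum(m))
  matrix(cumsum_by_col(m), nrow = nrow(m))
}

cumsum_by_col <- function(m) {
  total <- cumsum(as.numeric(m))
  nr <- nrow(m)
  nc <- ncol(m)
  if (nc <= 1) return(as.integer(total))
  offsets <- c(0, total[seq_len(nc - 1) * nr])
  as.integer(total - rep(offsets, each = nr))
}

# letter-index matrix (0-based) -> character vector of sequences, one per column
index_matrix_to_strings <- function(imat, alphabet) {
  lmat <- matrix(alphabet$letters[imat + 1L], nrow = nrow(imat))
  apply(lmat, 2, paste, collapse = "")
}

#' Information-density limit of an alphabet
#'
#' The per-base information ceiling of DNA storage over an alphabet of K
#' letters is log2(K) bits per base: 2 bits for the four natural bases,
#' about 2.32 bits once 5-methylcytosine joins as a fifth letter, and 3
#' bits for an eight-letter alphabet.
#'
#' @param alphabet_size Number of letters K, at least 2.
#' @return Bits per base, `log2(alphabet_size)`.
#' @examples
#' density_limit(4)  # 2
#' density_limit(5)  # 2.32...
#' @export
density_limit <- function(alphabet_size) {
  if (any(alphabet_size < 2)) stop("alphabet size must be >= 2", call. = FALSE)
  log2(alphabet_size)
}
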