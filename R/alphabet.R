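#' Expanded molecular alphabets
#'
#' An expanded molecular alphabet is an ordered set of K distinct
#' single-character letters used to carry information in synthetic DNA. The
#' default quinary alphabet appends 5-methylcytosine, written `M`, to the
#' four natural bases, in the order A, T, C, G, M. Under rotational
#' transcoding the usable radix is N = K - 1 because the previous letter is
#' always excluded from the choice for the next position.
#'
#' @param letters Character vector of distinct single-character symbols,
#'   length at least 2. Order matters: it fixes the rotational table.
#' @return An object of class `expanded_alphabet` with elements `letters`
#'   (character vector), `size` (K) and `radix` (K - 1).
#' @examples
#' expanded_alphabet()              # quinary A, T, C, G, M
#' expanded_alphabet(c("A", "C", "G", "T"))  # standard DNA, radix 3
#' @export
expanded_alphabet <- function(letters = c("A", "T", "C", "G", "M")) {
  letters <- as.character(letters)
  if (length(letters) < 2) {
    stop("an alphabet needs at least 2 letters", call. = FALSE)
  }
  if (anyDuplicated(letters)) {
    stop("alphabet letters must be distinct", call. = FALSE)
  }
  if (any(nchar(letters) != 1L)) {
    stop("alphabet letters must be single characters", call. = FALSE)
  }
  structure(
    list(letters = letters, size = length(letters), radix = length(letters) - 1L),
    class = "expanded_alphabet"
  )
}

#' @export
print.expanded_alphabet <- function(x, ...) {
  cat(
    "<expanded_alphabet> ", paste(x$letters, collapse = ""),
    "  (K = ", x$size, ", radix N = ", x$radix, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Build the rotational transcoding table for an alphabet
#'
#' The rotational table maps a (previous letter, digit) pair to the next
#' letter. The rule is a cyclic rotation: the digit d (0..N-1) selects the
#' letter `(index(prev) + 1 + d) mod K` in alphabet order, so the previous
#' letter itself is always skipped. Consequently every column of the table
#' is a bijection from the N digits onto the N letters other than the
#' previous one, and raw encoded output never repeats a letter in two
#' adjacent positions. With the default quinary alphabet this reproduces
#' the worked encoding of byte 150: quaternary digits 2,1,1,2 with virtual
#' previous letter A give the sequence GACA.
#'
#' @param alphabet An [expanded_alphabet()].
#' @return An object of class `rotation_table` with `alphabet`, a
#'   `forward` K x N integer matrix (`forward[prev, d + 1]` = letter index)
#'   and an `inverse` K x K matrix (`inverse[prev, letter]` = digit, or NA
#'   on the forbidden diagonal).
#' @examples
#' tab <- rotation_table()
#' rotate_forward(tab, "A", 2)  # "G"
#' @export
rotation_table <- function(alphabet = expanded_alphabet()) {
  stopifnot(inherits(alphabet, "expanded_alphabet"))
  k <- alphabet$size
  n <- alphabet$radix
  # forward[p, d] for 1-based prev index p and digit column d = digit + 1
  forward <- outer(seq_len(k) - 1L, seq_len(n), function(p, d) (p + d) %% k) + 1L
  inverse <- matrix(NA_integer_, k, k)
  for (p in seq_len(k)) {
    inverse[p, forward[p, ]] <- seq_len(n) - 1L
  }
  dimnames(forward) <- list(alphabet$letters, as.character(seq_len(n) - 1L))
  dimnames(inverse) <- list(alphabet$letters, alphabet$letters)
  structure(
    list(alphabet = alphabet, forward = forward, inverse = inverse),
    class = "rotation_table"
  )
}

#' @export
print.rotation_table <- function(x, ...) {
  cat("<rotation_table> over", paste(x$alphabet$letters, collapse = ""), "\n")
  disp <- matrix(x$alphabet$letters[x$forward],
    nrow = nrow(x$forward), dimnames = dimnames(x$forward)
  )
  print(t(disp))  # rows = digit, columns = previous letter
  invisible(x)
}

#' @rdname rotation_table
#' @param table A `rotation_table`.
#' @param prev Previous letter (single character in the alphabet).
#' @param digit Digit in 0..N-1.
#' @export
rotate_forward <- function(table, prev, digit) {
  p <- match(prev, table$alphabet$letters)
  if (is.na(p)) stop("unknown letter: ", prev, call. = FALSE)
  if (digit < 0 || digit >= table$alphabet$radix) {
    stop("digit out of range for radix ", table$alphabet$radix, call. = FALSE)
  }
  table$alphabet$letters[table$forward[p, digit + 1L]]
}

# letter characters -> 0-based alphabet indices; NA for foreign symbols
letter_index <- function(letters_chr, alphabet) {
  match(letters_chr, alphabet$letters) - 1L
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
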