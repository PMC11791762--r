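test_that("the quinary table reproduces the worked byte-150 example", {
  tab <- rotation_table()
  expect_identical(bytes_to_digits(as.raw(150)), c(2L, 1L, 1L, 2L))
  expect_identical(rotate_forward(tab, "A", 2), "G")
  expect_identical(rotate_forward(tab, "G", 1), "A")
  expect_identical(encode_digits(c(2L, 1L, 1L, 2L), tab), "GACA")
  expect_identical(decode_letters("GACA", tab), c(2L, 1L, 1L, 2L))
})

test_that("every rotation-table column is a bijection that skips the previous letter", {
  set.seed(42)
  pool <- c(LETTERS, letters)
  sizes <- c(5L, sample(3:8, 5, replace = TRUE))
  for (k in sizes) {
    ab <- if (k == 5L) expanded_alphabet() else expanded_alphabet(sample(pool, k))
    tab <- rotation_table(ab)
    for (p in seq_len(k)) {
      row <- tab$forward[p, ]
      expect_setequal(row, setdiff(seq_len(k), p))
      expect_identical(tab$inverse[p, row], seq_len(k - 1L) - 1L,
        ignore_attr = TRUE
      )
    }
  }
  expect_error(expanded_alphabet(c("A", "A", "T")), "distinct")
})

test_that("byte <-> digit expansion is fixed-width, MSB first, and invertible", {
  expect_identical(bytes_to_digits(as.raw(0)), c(0L, 0L, 0L, 0L))
  expect_identical(bytes_to_digits(as.raw(255)), c(3L, 3L, 3L, 3L))
  expect_identical(digits_per_byte(4L), 4L)
  expect_identical(digits_per_byte(7L), 3L)
  # exhaustive over all single bytes
  all_bytes <- as.raw(0:255)
  expect_identical(digits_to_bytes(bytes_to_digits(all_bytes)), all_bytes)
  # multi-byte streams, several radixes
  set.seed(7)
  for (radix in c(2L, 4L, 7L)) {
    x <- as.raw(sample.int(256L, 200, replace = TRUE) - 1L)
    expect_identical(digits_to_bytes(bytes_to_digits(x, radix), radix), x)
  }
  expect_error(digits_to_bytes(c(0L, 1L, 2L)), "divisible")
  expect_error(digits_to_bytes(c(0L, 1L, 2L, 4L)), "out of range")
})

test_that("transcoding round-trips and never repeats adjacent letters", {
  tab <- rotation_table()
  expect_identical(encode_digits(integer(0), tab), "")
  expect_identical(decode_letters("", tab), integer(0))
  # exhaustive single-byte round trip through the letter domain
  for (b in 0:255) {
    d <- bytes_to_digits(as.raw(b))
    seq <- encode_digits(d, tab)
    expect_identical(digits_to_bytes(decode_letters(seq, tab)), as.raw(b))
  }
  # long random stream: no two equal adjacent letters, first letter != A
  set.seed(1)
  stream <- bytes_to_digits(as.raw(sample.int(256L, 25000, replace = TRUE) - 1L))
  s <- encode_digits(stream, tab)
  cc <- strsplit(s, "")[[1]]
  expect_gte(length(cc), 1e5)
  expect_false(any(cc[-1] == cc[-length(cc)]))
  expect_false(cc[1] == "A")
})

test_that("decoding flags corrupt transitions and foreign symbols", {
  tab <- rotation_table()
  err <- tryCatch(decode_letters("AACG", tab), condition = identity)
  expect_s3_class(err, "methylstore_invalid_transition")
  expect_identical(err$position, 1L)
  err2 <- tryCatch(decode_letters("GAAC", tab), condition = identity)
  expect_identical(err2$position, 3L)
  expect_error(decode_letters("GAXA", tab), "not in alphabet")
  expect_error(encode_digits(4L, tab), "out of range")
})

test_that("information-density limit is log2 of the alphabet size", {
  expect_equal(density_limit(4), 2.0)
  expect_equal(round(density_limit(5), 2), 2.32)
  expect_equal(density_limit(8), 3.0)
  # radix N = 3..7 against the published table, to 2 decimal places
  expect_equal(round(density_limit(4:8), 2), c(2.0, 2.32, 2.58, 2.81, 3.0))
  expect_error(density_limit(1), ">= 2")
})

test_that("non-quinary alphabets encode and decode with adjusted digit width", {
  ab <- expanded_alphabet(c("A", "C", "G", "T", "M", "W", "X", "Y"))  # N = 7
  tab <- rotation_table(ab)
  set.seed(3)
  x <- as.raw(sample.int(256L, 100, replace = TRUE) - 1L)
  d <- bytes_to_digits(x, ab$radix)
  expect_length(d, 300)  # 3 digits per byte at N = 7
  s <- encode_digits(d, tab)
  expect_identical(digits_to_bytes(decode_letters(s, tab), ab$radix), x)
})
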