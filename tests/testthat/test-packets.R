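test_that("segmentation pads the tail and counts by the ceiling rule", {
  expect_identical(nrow(segment_file(as.raw(1:44))), 2L)
  s3 <- segment_file(as.raw(1:45))
  expect_identical(nrow(s3), 3L)
  expect_identical(s3$payload[[3]], c(as.raw(45), raw(21)))
  expect_identical(s3$address, 0:2)
  expect_identical(nrow(segment_file(fixture_bytes(5929, 1))), 270L)
  expect_identical(nrow(segment_file(raw(0))), 0L)
})

test_that("XOR algebra recovers any member of a triple", {
  set.seed(9)
  for (i in 1:100) {
    x <- random_payload()
    y <- random_payload()
    z <- xor_segment(x, y)
    expect_identical(as.integer(xor_segment(xor_segment(x, y), z)), rep(0L, 22))
    expect_identical(recover_segment(y, z), x)
    expect_identical(recover_segment(x, z), y)
    expect_identical(recover_segment(x, y), z)
  }
  expect_identical(xor_segment(as.raw(1:4), as.raw(1:4)), raw(4))
  expect_error(xor_segment(raw(3), raw(4)), "lengths differ")
})

test_that("redundancy adds one XOR segment per pair, phantom-padding odd counts", {
  counts <- c(`2` = 3L, `5` = 8L, `270` = 405L)
  for (n in as.integer(names(counts))) {
    segs <- segment_file(as.raw(seq_len(n * 22) %% 256))
    out <- add_redundancy(segs)
    expect_identical(nrow(out), counts[[as.character(n)]])
    expect_identical(sum(out$role == "xor"), as.integer(ceiling(n / 2)))
    expect_identical(out$address, seq_len(nrow(out)) - 1L)
  }
  # odd count: final xor pairs the last data segment with an all-zero phantom
  segs <- segment_file(as.raw(rep(7, 5 * 22)))
  out <- add_redundancy(segs)
  expect_identical(out$payload[[8]], segs$payload[[5]])
})

test_that("oligos are 100 letters and round-trip their segment", {
  cfg <- store_config()
  o <- build_oligo(raw(22), 0L, cfg)
  expect_identical(nchar(o), 100L)
  # all-zero digits walk the alphabet cyclically: T C G M A repeated
  expect_identical(o, strrep("TCGMA", 20))
  set.seed(5)
  segs <- tibble::tibble(
    address = 0:199, role = "data",
    payload = replicate(200, random_payload(), simplify = FALSE)
  )
  oligos <- build_oligos(segs, cfg)
  expect_true(all(nchar(oligos$sequence) == 100))
  for (i in seq_len(200)) {
    dec <- decode_oligo(oligos$sequence[i], cfg)
    expect_true(dec$valid)
    expect_identical(dec$address, segs$address[i])
    expect_identical(dec$payload, segs$payload[[i]])
  }
  expect_error(build_oligo(raw(22), 2^24, cfg), "capacity")
})

test_that("corrupt oligos are flagged for erasure, not decoded", {
  cfg <- store_config()
  o <- build_oligo(random_payload(), 3L, cfg)
  expect_identical(decode_oligo(substr(o, 1, 99), cfg)$reason, "length")
  # force an adjacent repeat: copy letter i-1 onto letter i
  oo <- o
  substr(oo, 10, 10) <- substr(oo, 9, 9)
  expect_identical(decode_oligo(oo, cfg)$reason, "transition")
  expect_identical(decode_oligo(gsub("A", "X", o), cfg)$reason, "symbol")
  big <- build_oligo(random_payload(), 500L, cfg)
  expect_identical(decode_oligo(big, cfg, n_expected = 10L)$reason, "address")
})

test_that("a store reassembles exactly and survives one erasure per triple", {
  data <- fixture_bytes(220, 2)  # 10 data + 5 xor segments
  store <- encode_store(data)
  rec <- reassemble_file(store$oligos, store$manifest, original = data)
  expect_identical(rec$bytes, data)
  expect_identical(rec$recovery_rate, 1)
  expect_true(all(rec$report$status == "ok"))
  # drop each member of each triple in turn: always fully recoverable
  n_data <- store$manifest$n_data
  for (k in 0:(store$manifest$n_xor - 1)) {
    for (member in c(2 * k, 2 * k + 1, n_data + k)) {
      if (member == 2 * k + 1 && member >= n_data) next
      rec1 <- reassemble_file(
        store$oligos$sequence[-(member + 1)], store$manifest, original = data
      )
      expect_identical(rec1$bytes, data)
      expect_identical(rec1$report$status[member + 1], "recovered")
    }
  }
})

test_that("losing a whole pair zero-fills exactly those bytes", {
  data <- fixture_bytes(220, 3)
  store <- encode_store(data)
  # drop data segments 2 and 3 (one full XOR pair): 44 bytes unrecoverable
  rec <- reassemble_file(store$oligos$sequence[-c(3, 4)], store$manifest,
    original = data
  )
  expected <- data
  expected[45:88] <- as.raw(0)
  expect_identical(rec$bytes, expected)
  wrong_bits <- sum(vapply(as.integer(data[45:88]), function(b) {
    sum(bitwAnd(bitwShiftR(b, 0:7), 1L))
  }, integer(1)))
  expect_equal(rec$recovery_rate, 1 - wrong_bits / (8 * length(data)))
  expect_identical(sum(rec$report$status == "lost"), 2L)
})

test_that("oligo counts follow the counting law across file sizes", {
  for (n in c(0L, 1L, 21L, 22L, 23L, 100L, 1000L)) {
    data <- fixture_bytes(n, n + 1)
    store <- encode_store(data)
    n_data <- ceiling(n / 22)
    expect_identical(nrow(store$oligos), as.integer(n_data + ceiling(n_data / 2)))
    if (n_data > 0 && n_data %% 2 == 0) {
      expect_equal(nrow(store$oligos) / n_data, 1.5)
    }
    rec <- reassemble_file(store$oligos, store$manifest, original = data)
    expect_identical(rec$bytes, data)
  }
})
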