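test_that("GC content counts M as a cytosine", {
  expect_equal(gc_content("GACA"), 0.5)
  expect_equal(gc_content("MMMM"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("MMMM", count_m = FALSE), 0)
  expect_error(gc_content(""), "empty")
})

test_that("homopolymer length honours the M == C chemistry", {
  expect_identical(max_homopolymer("CMCM"), 4L)
  expect_identical(max_homopolymer("CMCM", collapse_m_to_c = FALSE), 1L)
  expect_identical(max_homopolymer("AATTTA"), 3L)
  expect_error(max_homopolymer(""), "empty")
  # collapsing can only lengthen the maximum run
  set.seed(6)
  for (i in 1:50) {
    s <- paste(sample(c("A", "T", "C", "G", "M"), 60, replace = TRUE),
      collapse = ""
    )
    expect_gte(max_homopolymer(s), max_homopolymer(s, collapse_m_to_c = FALSE))
  }
})

test_that("raw rotational output never repeats a letter but collapses to runs", {
  store <- encode_store(fixture_bytes(2200, 12))
  raw_runs <- vapply(store$oligos$sequence, max_homopolymer,
    integer(1), collapse_m_to_c = FALSE, USE.NAMES = FALSE
  )
  expect_true(all(raw_runs == 1L))
  collapsed <- vapply(store$oligos$sequence, max_homopolymer, integer(1),
    USE.NAMES = FALSE
  )
  expect_true(any(collapsed > 1L))
})

test_that("encoded random bytes sit near uniform letter usage and 60% GC", {
  data <- fixture_bytes(30000, 13)  # > 1e5 letters
  prof <- profile_encoding(data)
  g <- glance(prof)
  expect_gte(g$gc_mean, 0.5)
  expect_lte(g$gc_mean, 0.7)
  # per-oligo letters (address prefix included) stay close to uniform
  letters_all <- strsplit(paste(
    build_oligos(segment_file(data[1:22000]), store_config())$sequence,
    collapse = ""
  ), "")[[1]]
  freq <- table(factor(letters_all, c("A", "T", "C", "G", "M"))) / length(letters_all)
  expect_true(all(abs(freq - 0.2) < 0.01))
  # the stationary distribution of the rotational chain on uniform digits
  # is exactly uniform: chi-square sanity check on a 1.2e5-letter stream
  stream <- encode_digits(bytes_to_digits(data), rotation_table())
  tab <- table(factor(strsplit(stream, "")[[1]], c("A", "T", "C", "G", "M")))
  chi <- stats::chisq.test(tab)
  expect_gt(chi$p.value, 1e-6)
})

test_that("per-oligo profile of the all-zero segment is the hand-traced cycle", {
  prof <- profile_encoding(raw(22))
  per <- tidy(prof)
  # 1 data segment + 1 phantom-paired XOR segment; the data oligo is the
  # pure TCGMA cycle, the XOR oligo's address digit 1 shifts the phase at
  # one position (59 of 100 letters in {C, G, M})
  expect_identical(nrow(per), 2L)
  expect_identical(
    build_oligos(segment_file(raw(22)), store_config())$sequence,
    strrep("TCGMA", 20)
  )
  expect_equal(per$gc, c(0.6, 0.59))
  expect_identical(per$max_homopolymer, c(1L, 1L))
  expect_identical(glance(prof)$oligo_length, 100L)
})

test_that("GC spread and homopolymer maxima grow with file size", {
  small <- glance(profile_encoding(fixture_bytes(5000, 14)))
  large <- glance(profile_encoding(fixture_bytes(200000, 14)))
  expect_gte(large$gc_range, small$gc_range)
  expect_gte(large$hp_max, small$hp_max)
  expect_s3_class(autoplot(profile_encoding(fixture_bytes(2000, 15))), "ggplot")
})
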