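test_that("candidate enumeration is complete and lexicographic", {
  expect_identical(enumerate_candidates(1), c("A", "C", "G", "T"))
  two <- enumerate_candidates(2)
  expect_length(two, 16L)
  expect_identical(two[1], "AA")
  expect_identical(two[16], "TT")
  expect_identical(two, sort(two))
  expect_length(enumerate_candidates(8), 65536L)
})

test_that("the composition filter keeps exactly the 40-60% GC, run<=2 8-mers", {
  expect_identical(composition_filter("ACGTACGT"), "ACGTACGT")
  expect_identical(composition_filter("AAAAAAAA"), character(0))
  expect_identical(composition_filter("GGGGAAAA"), character(0))  # run 4
  surv <- composition_filter(enumerate_candidates(8))
  # pinned against an independent exhaustive enumeration
  expect_identical(length(surv), 14696L)
  gc_counts <- vapply(surv, function(s) {
    sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, integer(1), USE.NAMES = FALSE)
  expect_true(all(gc_counts == 4L))  # only 4/8 lies inside [0.4, 0.6]
  runs <- vapply(surv, max_homopolymer, integer(1),
    collapse_m_to_c = FALSE, USE.NAMES = FALSE
  )
  expect_true(all(runs <= 2L))
})

test_that("hamming distance is a symmetric positional mismatch count", {
  expect_identical(hamming("AAAAAAAA", "AAAAAAAA"), 0L)
  expect_identical(hamming("AAAAAAAA", "TTTTTTTT"), 8L)
  set.seed(8)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    expect_identical(hamming(a, b), hamming(b, a))
  }
  expect_error(hamming("AA", "AAA"), "length")
})

test_that("greedy selection yields the pinned maximal distance-5 code", {
  surv <- composition_filter(enumerate_candidates(8))
  greedy <- select_adaptors(surv, 5, "greedy")
  expect_identical(nrow(greedy), 48L)
  expect_identical(greedy$adaptor[1], "AACAACCG")
  # all pairwise distances >= 5, exhaustively
  n <- nrow(greedy)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      expect_gte(hamming(greedy$adaptor[i], greedy$adaptor[j]), 5L)
    }
  }
  # maximality: every excluded survivor clashes with some kept adaptor
  kept_m <- seq_matrix(greedy$adaptor)
  excluded <- setdiff(surv, greedy$adaptor)
  set.seed(10)
  for (s in sample(excluded, 300)) {
    d <- rowSums(kept_m != matrix(strsplit(s, "")[[1]], nrow(kept_m), 8,
      byrow = TRUE
    ))
    expect_lt(min(d), 5L)
  }
})

test_that("the literal all-pairs filter annihilates the full survivor set", {
  surv <- composition_filter(enumerate_candidates(8))
  lit <- select_adaptors(surv, 5, "literal")
  expect_identical(nrow(lit), 0L)
  # and agrees with a brute-force double loop on a subsample
  set.seed(3)
  small <- sample(surv, 60)
  brute <- small[vapply(seq_along(small), function(i) {
    all(vapply(small[-i], hamming, integer(1), a = small[i]) >= 5)
  }, logical(1))]
  expect_setequal(select_adaptors(small, 5, "literal")$adaptor, brute)
  # duplicates collapse to one in greedy mode
  expect_identical(nrow(select_adaptors(rep("AACCGGTT", 2), 5, "greedy")), 1L)
})

test_that("reverse-complement screening drops clashing adaptors", {
  set.seed(2)
  with_rc <- design_adaptors(check_revcomp = TRUE)
  rc <- vapply(with_rc$adaptor, function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_false(any(rc %in% with_rc$adaptor & rc != with_rc$adaptor))
})
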