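test_that("alignment identity matches the direct mismatch count", {
  expect_equal(alignment_identity("GACAT", "GACAT"), 1)
  expect_equal(alignment_identity("AAAA", "TTTT", type = "global"), 0)
  set.seed(21)
  ref <- paste(sample(c("A", "T", "C", "G", "M"), 100, replace = TRUE),
    collapse = ""
  )
  read <- ref
  # one internal substitution -> identity 99/100
  cc <- strsplit(read, "")[[1]]
  cc[50] <- setdiff(c("A", "T", "C", "G", "M"), cc[50])[1]
  read <- paste(cc, collapse = "")
  expect_equal(alignment_identity(read, ref, type = "global"), 0.99)
})

test_that("methylation calling applies the inclusive 128 threshold", {
  expect_identical(call_methylation("ACGC", c(NA, 255L, NA, 0L)), "AMGC")
  expect_identical(call_methylation("ACGC", c(NA, 128L, NA, 127L)), "AMGC")
  expect_identical(call_methylation("ACGC", c(NA, 10L, NA, 10L)), "ACGC")
  # raising the threshold can only reduce the number of M calls
  set.seed(30)
  bases <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
    collapse = ""
  )
  meth <- ifelse(strsplit(bases, "")[[1]] == "C",
    sample(0:255, 200, replace = TRUE), NA_integer_
  )
  m_counts <- vapply(c(0L, 64L, 128L, 192L, 256L), function(thr) {
    sum(strsplit(call_methylation(bases, meth, thr), "")[[1]] == "M")
  }, integer(1))
  expect_identical(m_counts, sort(m_counts, decreasing = TRUE))
})

test_that("read screening keeps the 0.85 identity boundary inclusive", {
  set.seed(22)
  ref <- paste(sample(c("A", "T", "C", "G", "M"), 100, replace = TRUE),
    collapse = ""
  )
  # 15 internal substitutions -> identity exactly 0.85
  cc <- strsplit(ref, "")[[1]]
  at <- seq(5, 95, length.out = 15)
  for (i in at) cc[i] <- setdiff(c("A", "T", "C", "G", "M"), cc[i])[1]
  borderline <- paste(cc, collapse = "")
  expect_equal(alignment_identity(borderline, ref, type = "global"), 0.85)
  random <- paste(sample(c("A", "T", "C", "G"), 100, replace = TRUE),
    collapse = ""
  )
  kept <- filter_reads(c(ref, borderline, random), ref)
  expect_true(ref %in% kept)
  expect_true(borderline %in% kept)
  expect_false(random %in% kept)
})

test_that("simulated reads carry the requested depth and honest methylation", {
  set.seed(31)
  fragment <- strrep("GACMT", 30)
  cfg <- noise_free_config(depth = 10)
  reads <- simulate_reads(fragment, cfg)
  expect_identical(nrow(reads), 10L)
  for (i in 1:10) {
    called <- call_methylation(reads$bases[i], reads$meth[[i]])
    core <- substr(called, nchar(cfg$barcode_5p) + 1,
      nchar(called) - nchar(cfg$barcode_3p)
    )
    expect_identical(core, fragment)
  }
  # meth probabilities exist exactly at basecalled C positions
  cc <- strsplit(reads$bases[1], "")[[1]]
  expect_identical(which(!is.na(reads$meth[[1]])), which(cc == "C"))
})

test_that("methylation confusion produces predominantly C<->M substitutions", {
  set.seed(32)
  fragment <- paste(sample(c("A", "T", "C", "G", "M"), 200, replace = TRUE,
    prob = c(1, 1, 1, 1, 2)
  ), collapse = "")
  cfg <- read_sim_config(
    depth = 30, sub_rate = 1e-4, ins_rate = 1e-4, del_rate = 1e-4,
    m_miscall = 0.1, c_miscall = 0.1, barcode_5p = "", barcode_3p = ""
  )
  reads <- simulate_reads(fragment, cfg)
  pooled <- dplyr::bind_rows(lapply(seq_len(nrow(reads)), function(i) {
    called <- call_methylation(reads$bases[i], reads$meth[[i]])
    glance(error_statistics(called, fragment))
  }))
  n_sub <- sum(pooled$n_substitution)
  cm <- sum(pooled$cm_fraction * pooled$n_substitution)
  expect_gt(n_sub, 0)
  expect_gt(cm / n_sub, 0.5)  # confusion dominates when base errors are rare
})

test_that("trimming splits clean and corrupted units at the right places", {
  ad <- test_adaptors$adaptor[1:3]
  oligo1 <- strrep("GACAT", 20)
  oligo2 <- strrep("TMCGA", 20)
  read <- paste0(
    default_barcodes[1], oligo1, ad[1], oligo2, ad[2], default_barcodes[2]
  )
  pieces <- trim_and_size_filter(read, default_barcodes, ad)
  expect_identical(pieces, c(oligo1, oligo2))
  # a 70-nt remnant is dropped; 80 and 120-nt pieces are kept inclusively
  p70 <- strrep("GACAT", 14)
  p80 <- strrep("GACAT", 16)
  p120 <- strrep("GACAT", 24)
  read2 <- paste0(p70, ad[1], p80, ad[2], p120)
  expect_identical(
    trim_and_size_filter(read2, character(0), ad),
    c(p80, p120)
  )
  # one corrupted adaptor still splits via the in-piece fallback
  ad_bad <- ad[1]
  substr(ad_bad, 4, 4) <- if (substr(ad_bad, 4, 4) == "A") "C" else "A"
  read3 <- paste0(oligo1, ad_bad, oligo2)
  expect_identical(
    trim_and_size_filter(read3, character(0), ad),
    c(oligo1, oligo2)
  )
})

test_that("star-MSA consensus takes per-column majorities deterministically", {
  piece <- strrep("GACMT", 20)
  expect_identical(msa_consensus(rep(piece, 10)), piece)
  expect_identical(msa_consensus(piece), piece)
  # 9 correct + 1 substituted
  bad <- piece
  substr(bad, 30, 30) <- "A"
  expect_identical(msa_consensus(c(rep(piece, 9), bad)), piece)
  # an indel-bearing minority read does not shift the consensus
  del <- paste0(substr(piece, 1, 40), substr(piece, 42, 100))
  ins <- paste0(substr(piece, 1, 60), "T", substr(piece, 61, 100))
  expect_identical(msa_consensus(c(rep(piece, 8), del, ins)), piece)
  expect_error(msa_consensus(character(0)), "no pieces")
})

test_that("depth-10 consensus corrects 1% iid errors nearly always", {
  set.seed(33)
  alphabet <- expanded_alphabet()
  profile <- error_profile(0.01)
  wrong <- 0
  trials <- 60
  for (t in seq_len(trials)) {
    truth <- encode_digits(
      bytes_to_digits(random_payload(25)), rotation_table()
    )
    reads <- vapply(1:10, function(i) {
      inject_errors(truth, profile, alphabet)
    }, character(1))
    if (!identical(msa_consensus(reads), truth)) wrong <- wrong + 1
  }
  # majority vote at depth 10 leaves well under 1 failure per 100 fragments;
  # allow a generous margin for alignment-boundary effects
  expect_lte(wrong / trials, 0.05)
})

test_that("error classification separates the three types and C/M swaps", {
  clean <- glance(error_statistics("GACAT", "GACAT"))
  expect_identical(clean$n_errors, 0L)
  one <- error_statistics("ACGC", "ACGM")
  expect_identical(glance(one)$n_substitution, 1L)
  expect_equal(glance(one)$cm_fraction, 1)
  expect_identical(tidy(one)$position, 4L)
  del <- glance(error_statistics("GAAT", "GACAT"))
  expect_identical(del$n_deletion, 1L)
  ins <- glance(error_statistics("GACCAT", "GACAT"))
  expect_identical(ins$n_insertion, 1L)
})
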