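# Shared fixtures, built once per test run.

# the default greedy adaptor set (48 eight-mers, pairwise Hamming >= 5)
test_adaptors <- design_adaptors()

default_barcodes <- c(
  read_sim_config()$barcode_5p,
  read_sim_config()$barcode_3p
)

# A small but complete synthetic sequencing scenario: 220 bytes ->
# 15 oligos -> 3 assembly groups of 5 -> 6 fragments -> depth x 6 reads.
small_scenario <- function(seed = 4, cfg = read_sim_config(depth = 5)) {
  fixture_read_set(
    data = fixture_bytes(220, seed = seed), cfg = cfg, seed = seed,
    adaptors = test_adaptors$adaptor
  )
}

noise_free_config <- function(depth = 3) {
  read_sim_config(
    depth = depth, sub_rate = 0, ins_rate = 0, del_rate = 0,
    m_miscall = 0, c_miscall = 0
  )
}

scenario_reference <- function(fx) {
  list(fragments = fx$fragments$fragment, oligos = fx$store$oligos)
}

random_payload <- function(n = 22) as.raw(sample.int(256L, n, replace = TRUE) - 1L)
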