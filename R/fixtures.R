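#' Reproducible synthetic input fixtures
#'
#' `fixture_bytes()` draws a uniformly random byte stream of an exact
#' size -- the stand-in for arbitrary digital files in simulations and
#' benchmarks (the reference experiment stored a 5,929-byte text file).
#' `fixture_read_set()` builds a complete synthetic sequencing scenario:
#' it encodes a byte stream, lays the oligos out into adaptor-tagged
#' assembly groups, concatenates each group's subfragments, and
#' simulates methylation-aware reads of every fragment.
#'
#' @param n_bytes Exact byte count.
#' @param seed Integer seed (applied with `set.seed()`).
#' @return `fixture_bytes()`: a raw vector of length `n_bytes`.
#' @examples
#' length(fixture_bytes(5929, seed = 1))
#' @export
fixture_bytes <- function(n_bytes, seed = 1L) {
  set.seed(seed)
  as.raw(sample.int(256L, n_bytes, replace = TRUE) - 1L)
}

#' @rdname fixture_bytes
#' @param data Raw vector to store (default: a fresh [fixture_bytes()]).
#' @param cfg A [read_sim_config()].
#' @param config A [store_config()].
#' @param adaptors Adaptor sequences for the layout (default: greedy
#'   [design_adaptors()] set).
#' @param group_size Oligos per assembly group; the store is padded with
#'   zero-payload filler oligos when the count does not divide evenly.
#' @return `fixture_read_set()`: a list with `store` (the `dna_store`),
#'   `plan`, `fragments` (tibble), `reads` (tibble), `adaptors` and
#'   `data`.
#' @export
fixture_read_set <- function(data = fixture_bytes(220, seed = seed),
                             cfg = read_sim_config(), seed = 1L,
                             config = store_config(), adaptors = NULL,
                             group_size = 5L) {
  set.seed(seed)
  if (is.null(adaptors)) adaptors <- design_adaptors()
  if (is.data.frame(adaptors)) adaptors <- adaptors$adaptor
  store <- encode_store(data, config)
  oligos <- store$oligos
  pad <- (group_size - nrow(oligos) %% group_size) %% group_size
  if (pad > 0) {
    filler <- build_oligos(
      tibble::tibble(
        address = max(oligos$address) + seq_len(pad),
        role = "filler",
        payload = replicate(pad, raw(config$segment_length), simplify = FALSE)
      ),
      config
    )
    oligos <- dplyr::bind_rows(oligos, filler)
  }
  plan <- plan_groups(oligos, adaptors, group_size = group_size,
    subfragment_split = max(1L, min(group_size, ceiling(group_size / 2)))
  )
  fragments <- fragment_sequences(plan)
  frag_seqs <- fragments$fragment
  names(frag_seqs) <- paste0(fragments$group, ".", fragments$subfragment)
  reads <- simulate_read_set(frag_seqs, cfg)
  list(
    store = store, plan = plan, fragments = fragments, reads = reads,
    adaptors = adaptors, data = data
  )
}
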