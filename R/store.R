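#' Encode a byte stream into an oligo store
#'
#' Runs the full write path: split the bytes into 22-byte addressed
#' segments, append one XOR redundancy segment per pair of data segments,
#' and transcode every segment into a 100-letter oligo over the quinary
#' alphabet. The returned store couples the oligo table with a manifest
#' (file length, segment geometry, alphabet order, checksum) that the
#' decoder needs to size and verify its output.
#'
#' @param data Raw vector, or a file path read with [read_file_bytes()].
#' @param config A [store_config()].
#' @param redundancy Add XOR segments (default TRUE).
#' @return An object of class `dna_store`: list with `oligos` (tibble of
#'   `address`, `role`, `sequence`) and `manifest`.
#' @examples
#' store <- encode_store(as.raw(sample(0:255, 100, replace = TRUE)))
#' store$manifest$n_data
#' @export
encode_store <- function(data, config = store_config(), redundancy = TRUE) {
  stopifnot(is.raw(data))
  segments <- segment_file(data, config$segment_length)
  n_data <- nrow(segments)
  if (redundancy) segments <- add_redundancy(segments)
  oligos <- build_oligos(segments, config)
  manifest <- store_manifest(
    file_length = length(data),
    segment_length = config$segment_length,
    n_data = n_data,
    n_xor = nrow(segments) - n_data,
    address_length = config$address_length,
    alphabet = config$alphabet$letters,
    checksum = bytes_checksum(data)
  )
  structure(list(oligos = oligos, manifest = manifest), class = "dna_store")
}

#' @export
print.dna_store <- function(x, ...) {
  m <- x$manifest
  cat(
    "<dna_store> ", m$file_length, " bytes -> ", nrow(x$oligos), " oligos (",
    m$n_data, " data + ", m$n_xor, " xor), ",
    nchar(x$oligos$sequence[1]), " nt each\n",
    sep = ""
  )
  invisible(x)
}

#' Store manifest
#'
#' Decode-time metadata: without it the decoder cannot size the output or
#' know how many XOR triples to attempt. Kept outside the oligos
#' themselves (a JSON sidecar on disk) so the oligo count stays exactly
#' data + redundancy.
#'
#' @param file_length Original file length in bytes.
#' @param segment_length Bytes per segment.
#' @param n_data,n_xor Segment counts by role.
#' @param address_length Letters in the address field.
#' @param alphabet Letter order of the encoding alphabet.
#' @param checksum MD5 of the original bytes (hex string), or NA.
#' @return A list of class `store_manifest`.
#' @export
store_manifest <- function(file_length, segment_length, n_data, n_xor,
                           address_length = 12L,
                           alphabet = c("A", "T", "C", "G", "M"),
                           checksum = NA_character_) {
  stopifnot(n_data == ceiling(file_length / segment_length))
  structure(
    list(
      file_length = as.integer(file_length),
      segment_length = as.integer(segment_length),
      n_data = as.integer(n_data),
      n_xor = as.integer(n_xor),
      address_length = as.integer(address_length),
      alphabet = as.character(alphabet),
      checksum = checksum
    ),
    class = "store_manifest"
  )
}

config_from_manifest <- function(manifest) {
  store_config(
    segment_length = manifest$segment_length,
    address_length = manifest$address_length,
    alphabet = expanded_alphabet(manifest$alphabet)
  )
}

# MD5 of a raw vector (via a temp file; R ships no in-memory digest)
bytes_checksum <- function(data) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(data, tf)
  unname(tools::md5sum(tf))
}

#' Reassemble a file from (possibly damaged) oligos
#'
#' Decodes every oligo, flags corrupt ones (wrong length, impossible
#' letter transition, foreign symbol, out-of-range address) as erasures,
#' and then walks the XOR triples: whenever exactly one member of a
#' triple (data 2k, data 2k+1, xor k) is missing it is recovered from the
#' other two. Data segments that remain unrecoverable are filled with
#' zero bytes, so the output always has the manifest's file length and
#' the bit-recovery denominator is the whole file. When several decoded
#' oligos claim the same address the first is kept.
#'
#' @param oligos Character vector of oligo sequences, or a `dna_store`
#'   oligo tibble.
#' @param manifest A [store_manifest()].
#' @param original Optional raw vector of the true file; when supplied
#'   the report carries the bit-level recovery rate against it.
#' @return A list of class `store_recovery`: `bytes` (raw), `report`
#'   (tibble of per-segment `address`, `role`, `status` in
#'   ok/recovered/lost), and `recovery_rate` (fraction of correct bits,
#'   or NA without `original`).
#' @export
reassemble_file <- function(oligos, manifest, original = NULL) {
  if (is.data.frame(oligos)) oligos <- oligos$sequence
  config <- config_from_manifest(manifest)
  n_data <- manifest$n_data
  n_xor <- manifest$n_xor
  n_total <- n_data + n_xor
  seg_len <- manifest$segment_length

  decoded <- decode_oligos(oligos, config, n_expected = n_total)
  slots <- vector("list", n_total)
  ok <- decoded$valid & !duplicated(decoded$address)
  for (i in which(ok)) slots[[decoded$address[i] + 1L]] <- decoded$payload[[i]]

  status <- ifelse(
    vapply(slots, is.null, logical(1)), "lost", "ok"
  )
  # XOR triples: data 2k, 2k+1 (0-based), parity at n_data + k
  for (k in seq_len(n_xor) - 1L) {
    i1 <- 2L * k + 1L
    i2 <- 2L * k + 2L
    iz <- n_data + k + 1L
    phantom <- i2 > n_data  # odd data count: second member is all-zero
    have1 <- !is.null(slots[[i1]])
    have2 <- phantom || !is.null(slots[[i2]])
    havez <- !is.null(slots[[iz]])
    missing_n <- (!have1) + (!have2) + (!havez)
    if (missing_n != 1L) next
    p2 <- if (phantom) raw(seg_len) else slots[[i2]]
    if (!have1) {
      slots[[i1]] <- recover_segment(p2, slots[[iz]])
      status[i1] <- "recovered"
    } else if (!have2) {
      slots[[i2]] <- recover_segment(slots[[i1]], slots[[iz]])
      status[i2] <- "recovered"
    } else {
      slots[[iz]] <- recover_segment(slots[[i1]], p2)
      status[iz] <- "recovered"
    }
  }
  for (i in seq_len(n_data)) {
    if (is.null(slots[[i]])) slots[[i]] <- raw(seg_len)
  }
  bytes <- unlist(slots[seq_len(n_data)], use.names = FALSE)
  if (is.null(bytes)) bytes <- raw(0)
  bytes <- bytes[seq_len(manifest$file_length)]

  rate <- if (!is.null(original)) recovery_rate(original, bytes) else NA_real_
  structure(
    list(
      bytes = bytes,
      report = tibble::tibble(
        address = seq_len(n_total) - 1L,
        role = rep(c("data", "xor"), c(n_data, n_xor)),
        status = status
      ),
      recovery_rate = rate
    ),
    class = "store_recovery"
  )
}

#' @export
print.store_recovery <- function(x, ...) {
  tab <- table(factor(x$report$status, c("ok", "recovered", "lost")))
  cat(
    "<store_recovery> ", length(x$bytes), " bytes; segments ok ", tab[["ok"]],
    ", recovered ", tab[["recovered"]], ", lost ", tab[["lost"]],
    if (!is.na(x$recovery_rate)) {
      sprintf("; bit recovery %.4f", x$recovery_rate)
    } else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a file as raw bytes
#'
#' @param path File path.
#' @return Raw vector of the file contents.
#' @export
read_file_bytes <- function(path) {
  readBin(path, "raw", n = file.size(path))
}
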