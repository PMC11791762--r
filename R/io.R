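#' Read and write oligo stores as extended FASTA plus a JSON manifest
#'
#' Oligos are serialized as FASTA records (one per oligo, record id =
#' decimal address, description = role) over the extended alphabet --
#' note the deliberately non-IUPAC use of `M` for 5-methylcytosine,
#' declared in the record descriptions. The manifest travels as a JSON
#' sidecar so the decoder can size and verify its output; round-tripping
#' through `read_store_fasta()` is lossless, including the M letters.
#'
#' @param store A `dna_store` from [encode_store()].
#' @param fasta_path,manifest_path Output paths (manifest defaults to
#'   `<fasta_path>.manifest.json`).
#' @return `write_store_fasta()`: the FASTA path, invisibly.
#' @export
write_store_fasta <- function(store, fasta_path,
                              manifest_path = paste0(fasta_path, ".manifest.json")) {
  ids <- sprintf("%d %s alphabet=%s;M=5mC",
    store$oligos$address, store$oligos$role,
    paste(store$manifest$alphabet, collapse = "")
  )
  seqs <- Biostrings::BStringSet(store$oligos$sequence)
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_manifest(store$manifest, manifest_path)
  invisible(fasta_path)
}

#' @rdname write_store_fasta
#' @return `read_store_fasta()`: a `dna_store`.
#' @export
read_store_fasta <- function(fasta_path,
                             manifest_path = paste0(fasta_path, ".manifest.json")) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  fields <- strsplit(names(seqs), " ", fixed = TRUE)
  manifest <- read_manifest(manifest_path)
  structure(
    list(
      oligos = tibble::tibble(
        address = as.integer(vapply(fields, `[`, character(1), 1)),
        role = vapply(fields, function(f) {
          if (length(f) >= 2) f[2] else NA_character_
        }, character(1)),
        sequence = unname(as.character(seqs))
      ),
      manifest = manifest
    ),
    class = "dna_store"
  )
}

#' @rdname write_store_fasta
#' @param manifest A [store_manifest()].
#' @param path Manifest path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_store_fasta
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  store_manifest(
    file_length = m$file_length, segment_length = m$segment_length,
    n_data = m$n_data, n_xor = m$n_xor, address_length = m$address_length,
    alphabet = m$alphabet, checksum = m$checksum
  )
}

#' Strict-IUPAC export: plain FASTA plus a methylation BED sidecar
#'
#' For interoperability with tools that reject the extended alphabet,
#' oligos can be written with `C` at methylated positions and a BED file
#' (0-based, half-open intervals, one line per methylated cytosine)
#' recording where the M letters were.
#'
#' @param store A `dna_store`.
#' @param fasta_path,bed_path Output paths.
#' @return The FASTA path, invisibly.
#' @export
write_store_iupac <- function(store, fasta_path,
                              bed_path = paste0(fasta_path, ".5mc.bed")) {
  plain <- gsub("M", "C", store$oligos$sequence, fixed = TRUE)
  seqs <- Biostrings::BStringSet(plain)
  names(seqs) <- as.character(store$oligos$address)
  Biostrings::writeXStringSet(seqs, fasta_path)
  bed <- dplyr::bind_rows(lapply(seq_len(nrow(store$oligos)), function(i) {
    pos <- which(chars(store$oligos$sequence[i]) == "M")
    if (length(pos) == 0) return(NULL)
    tibble::tibble(
      chrom = as.character(store$oligos$address[i]),
      start = pos - 1L, end = pos, name = "5mC"
    )
  }))
  if (is.null(bed) || nrow(bed) == 0) {
    bed <- tibble::tibble(
      chrom = character(0), start = integer(0), end = integer(0),
      name = character(0)
    )
  }
  utils::write.table(bed, bed_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(fasta_path)
}

#' Write and read simulated read sets
#'
#' Reads travel as a FASTQ-like FASTA of base sequences plus a TSV
#' sidecar with one row per basecalled C carrying its 0-255 methylation
#' probability, mirroring how methylation tags ride along with real
#' basecalls.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param fasta_path Output FASTA path.
#' @param meth_path Sidecar path (default `<fasta_path>.meth.tsv`).
#' @return The FASTA path, invisibly.
#' @export
write_reads <- function(reads, fasta_path,
                        meth_path = paste0(fasta_path, ".meth.tsv")) {
  ids <- sprintf("read%d source=%s", seq_len(nrow(reads)), reads$source)
  seqs <- Biostrings::BStringSet(reads$bases)
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, fasta_path)
  tab <- dplyr::bind_rows(lapply(seq_len(nrow(reads)), function(i) {
    m <- reads$meth[[i]]
    pos <- which(!is.na(m))
    if (length(pos) == 0) return(NULL)
    tibble::tibble(read = i, position = pos, meth_prob = m[pos])
  }))
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- tibble::tibble(
      read = integer(0), position = integer(0), meth_prob = integer(0)
    )
  }
  utils::write.table(tab, meth_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(fasta_path)
}

#' @rdname write_reads
#' @return `read_reads()`: a read tibble (`read`, `source`, `bases`,
#'   `meth`).
#' @export
read_reads <- function(fasta_path, meth_path = paste0(fasta_path, ".meth.tsv")) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  tab <- utils::read.table(meth_path, header = TRUE, sep = "\t")
  bases <- as.character(seqs)
  source <- sub("^.* source=", "", names(seqs))
  meth <- lapply(seq_along(bases), function(i) {
    m <- rep(NA_integer_, nchar(bases[i]))
    rows <- tab[tab$read == i, , drop = FALSE]
    m[rows$position] <- as.integer(rows$meth_prob)
    m
  })
  tibble::tibble(
    read = seq_along(bases), source = source, bases = unname(bases),
    meth = meth
  )
}
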