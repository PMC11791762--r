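#' Attach or strip a ligation adaptor
#'
#' Each 100-nt oligo receives an 8-nt single-stranded adaptor appended at
#' its 3' end to direct ordered ligation, giving the 108-nt unit that is
#' phosphorylated and annealed in the wet protocol.
#'
#' @param oligo Oligo letter string (default design length 100).
#' @param adaptor Adaptor string over {A, C, G, T} (default length 8).
#' @param oligo_length,adaptor_length Expected lengths, checked.
#' @return `attach_adaptor()`: the concatenated unit string.
#' @examples
#' nchar(attach_adaptor(strrep("AT", 50), "ACGTACGT"))  # 108
#' @export
attach_adaptor <- function(oligo, adaptor, oligo_length = 100L,
                           adaptor_length = 8L) {
  if (nchar(adaptor) == 0) stop("empty adaptor", call. = FALSE)
  if (nchar(oligo) != oligo_length) {
    stop("oligo must have ", oligo_length, " letters", call. = FALSE)
  }
  if (nchar(adaptor) != adaptor_length) {
    stop("adaptor must have ", adaptor_length, " letters", call. = FALSE)
  }
  paste0(oligo, adaptor)
}

#' @rdname attach_adaptor
#' @param unit A unit string produced by `attach_adaptor()`.
#' @return `strip_adaptor()`: the oligo without its adaptor.
#' @export
strip_adaptor <- function(unit, adaptor_length = 8L) {
  substr(unit, 1L, nchar(unit) - adaptor_length)
}

#' Plan the staged-ligation assembly of an oligo store
#'
#' Oligos are grouped by consecutive address into groups of 27, labelled
#' A, B, C, ... in order. Within a group the first 15 units form
#' subfragment 1 (ligated five at a time, then the three 540-bp products
#' joined) and the remaining 12 units form subfragment 2 (ligated four at
#' a time, then joined). Every unit is a 108-nt oligo + adaptor
#' concatenation; adaptors are assigned round-robin from the supplied
#' set, so within a group all 27 adaptors are distinct.
#'
#' @param oligos A `dna_store`, its oligo tibble, or a character vector
#'   of oligo sequences.
#' @param adaptors Character vector of adaptor sequences (an
#'   [adaptor_set()][select_adaptors] tibble works); at least
#'   `group_size` are needed.
#' @param group_size Oligos per assembly group (default 27).
#' @param subfragment_split Units in the first subfragment (default 15;
#'   the rest form the second).
#' @return An object of class `assembly_plan`: tibble with `group`
#'   (label), `subfragment` (1 or 2), `position` (1-based within group),
#'   `address`, `adaptor`, `unit` (108-nt sequence).
#' @export
plan_groups <- function(oligos, adaptors, group_size = 27L,
                        subfragment_split = 15L) {
  if (inherits(oligos, "dna_store")) oligos <- oligos$oligos
  if (is.data.frame(oligos)) {
    addresses <- oligos$address
    sequences <- oligos$sequence
  } else {
    sequences <- oligos
    addresses <- seq_along(oligos) - 1L
  }
  if (is.data.frame(adaptors)) adaptors <- adaptors$adaptor
  n <- length(sequences)
  if (n %% group_size != 0) {
    stop(
      "oligo count ", n, " is not divisible by group size ", group_size,
      "; pad the store with ", group_size - n %% group_size,
      " filler oligos or change group_size",
      call. = FALSE
    )
  }
  if (length(adaptors) < group_size) {
    stop("need at least ", group_size, " adaptors, got ", length(adaptors),
      call. = FALSE
    )
  }
  if (anyDuplicated(adaptors[seq_len(group_size)])) {
    stop("adaptors must be distinct within a group", call. = FALSE)
  }
  n_groups <- n %/% group_size
  group_labels <- make_group_labels(n_groups)
  position <- rep(seq_len(group_size), n_groups)
  adaptor <- adaptors[position]
  plan <- tibble::tibble(
    group = rep(group_labels, each = group_size),
    subfragment = ifelse(position <= subfragment_split, 1L, 2L),
    position = position,
    address = addresses,
    adaptor = adaptor,
    unit = vapply(seq_len(n), function(i) {
      attach_adaptor(sequences[i], adaptor[i],
        oligo_length = nchar(sequences[i]),
        adaptor_length = nchar(adaptor[i])
      )
    }, character(1))
  )
  structure(
    plan,
    group_size = group_size, subfragment_split = subfragment_split,
    class = c("assembly_plan", class(tibble::tibble()))
  )
}

make_group_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  # beyond Z: AA, AB, ... (spreadsheet style)
  vapply(seq_len(n), function(i) {
    s <- ""
    while (i > 0) {
      r <- (i - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      i <- (i - 1) %/% 26
    }
    s
  }, character(1))
}

#' Expected assembled fragment lengths per group
#'
#' With 108-nt units, subfragment 1 (15 units) assembles to
#' 15 x 108 = 1620 bp. For subfragment 2 (12 units) the final unit's
#' trailing adaptor is not part of the assembled product, giving
#' 12 x 108 - 8 = 1288 bp; set `omit_terminal_adaptor = FALSE` to count
#' the full 1296 bp instead.
#'
#' @param plan An [plan_groups()] result.
#' @param omit_terminal_adaptor Omit the terminal adaptor of the last
#'   subfragment (default TRUE, matching the assembled product).
#' @param adaptor_length Adaptor length in nt.
#' @return Tibble with `group`, `subfragment`, `n_units`,
#'   `expected_length`.
#' @export
expected_fragment_lengths <- function(plan, omit_terminal_adaptor = TRUE,
                                      adaptor_length = 8L) {
  lens <- plan |>
    dplyr::group_by(group, subfragment) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      expected_length = sum(nchar(unit)),
      .groups = "drop"
    )
  if (omit_terminal_adaptor) {
    last_sub <- max(lens$subfragment)
    lens$expected_length <- lens$expected_length -
      ifelse(lens$subfragment == last_sub, adaptor_length, 0L)
  }
  lens
}

#' Assembled fragment sequences per group and subfragment
#'
#' Concatenates the units of each subfragment in position order; under
#' the terminal-adaptor convention the trailing adaptor of the last
#' subfragment is dropped, matching [expected_fragment_lengths()].
#'
#' @inheritParams expected_fragment_lengths
#' @return Tibble with `group`, `subfragment`, `fragment` (sequence) and
#'   `addresses` (list of member addresses in order).
#' @export
fragment_sequences <- function(plan, omit_terminal_adaptor = TRUE,
                               adaptor_length = 8L) {
  frags <- plan |>
    dplyr::arrange(group, subfragment, position) |>
    dplyr::group_by(group, subfragment) |>
    dplyr::summarise(
      fragment = paste(unit, collapse = ""),
      addresses = list(address),
      .groups = "drop"
    )
  if (omit_terminal_adaptor) {
    last_sub <- max(frags$subfragment)
    sel <- frags$subfragment == last_sub
    frags$fragment[sel] <- substr(
      frags$fragment[sel], 1L,
      nchar(frags$fragment[sel]) - adaptor_length
    )
  }
  frags
}
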