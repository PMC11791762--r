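#' Classify errors between a consensus and its reference
#'
#' Globally aligns the consensus to the reference and classifies every
#' difference as a substitution, insertion (letter present in the
#' consensus but not the reference) or deletion. Substitutions between C
#' and M -- the two chemical cytosines the methylation caller can
#' confuse -- are tracked separately, since they dominate the error
#' spectrum of methylation-aware reading.
#'
#' @param consensus,reference Non-empty letter strings.
#' @return An object of class `error_stats`: `events` (tibble with
#'   `position` in reference coordinates, `type`, `ref`, `alt`) and
#'   `summary` (one row: counts, per-type proportions, `cm_fraction` of
#'   substitutions that are C/M swaps). `tidy()` returns the events,
#'   `glance()` the summary.
#' @examples
#' glance(error_statistics("ACGC", "ACGM"))  # one C<->M substitution
#' @export
error_statistics <- function(consensus, reference) {
  if (nchar(consensus) == 0 || nchar(reference) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  aln <- align_pair(consensus, reference, type = "global")
  s <- aligned_strings(aln)
  ca <- chars(s$pattern)
  ra <- chars(s$subject)
  pos <- cumsum(ra != "-")  # reference coordinate of each column
  type <- dplyr::case_when(
    ra == "-" ~ "insertion",
    ca == "-" ~ "deletion",
    ca != ra ~ "substitution",
    TRUE ~ NA_character_
  )
  sel <- !is.na(type)
  events <- tibble::tibble(
    position = pmax(pos[sel], 1L),
    type = type[sel],
    ref = ifelse(ra[sel] == "-", NA_character_, ra[sel]),
    alt = ifelse(ca[sel] == "-", NA_character_, ca[sel])
  )
  new_error_stats(events, reference_length = nchar(reference))
}

new_error_stats <- function(events, reference_length) {
  n_sub <- sum(events$type == "substitution")
  n_ins <- sum(events$type == "insertion")
  n_del <- sum(events$type == "deletion")
  n_all <- nrow(events)
  cm <- sum(
    events$type == "substitution" &
      ((events$ref == "C" & events$alt == "M") |
        (events$ref == "M" & events$alt == "C"))
  )
  summary <- tibble::tibble(
    n_errors = n_all,
    n_substitution = n_sub, n_insertion = n_ins, n_deletion = n_del,
    prop_substitution = if (n_all) n_sub / n_all else 0,
    prop_insertion = if (n_all) n_ins / n_all else 0,
    prop_deletion = if (n_all) n_del / n_all else 0,
    cm_fraction = if (n_sub) cm / n_sub else 0,
    reference_length = reference_length
  )
  structure(
    list(events = events, summary = summary),
    class = "error_stats"
  )
}

#' @export
print.error_stats <- function(x, ...) {
  cat("<error_stats> ", x$summary$n_errors, " errors (",
    x$summary$n_substitution, " sub, ", x$summary$n_insertion, " ins, ",
    x$summary$n_deletion, " del); C/M fraction of subs ",
    round(x$summary$cm_fraction, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname error_statistics
#' @param x An `error_stats`.
#' @param ... Unused.
#' @method tidy error_stats
#' @export
tidy.error_stats <- function(x, ...) x$events

#' @rdname error_statistics
#' @method glance error_stats
#' @export
glance.error_stats <- function(x, ...) x$summary

# pool several error_stats objects (one per oligo) into one report
combine_error_stats <- function(stats_list, oligo_ids = NULL) {
  if (is.null(oligo_ids)) oligo_ids <- seq_along(stats_list)
  events <- dplyr::bind_rows(
    lapply(seq_along(stats_list), function(i) {
      ev <- stats_list[[i]]$events
      if (nrow(ev)) ev$oligo <- oligo_ids[i]
      ev
    })
  )
  ref_len <- sum(vapply(stats_list, function(s) s$summary$reference_length,
    numeric(1)
  ))
  if (nrow(events) == 0) {
    events <- tibble::tibble(
      position = integer(0), type = character(0),
      ref = character(0), alt = character(0), oligo = integer(0)
    )
  }
  out <- new_error_stats(events, reference_length = ref_len)
  out$per_position <- events |>
    dplyr::count(position, type, name = "errors") |>
    dplyr::mutate(rate = errors / length(stats_list))
  out
}

#' Per-position error profile across oligos
#'
#' Pools [error_statistics()] over a table of consensus sequences and
#' their references, reporting the error proportions by type, the C/M
#' substitution fraction, and the per-position error rate along the
#' oligo (the fraction of oligos with an error at each position).
#'
#' @param consensus Tibble with `address` and `consensus` columns, as
#'   produced by [decode_read_store()].
#' @param reference_oligos Tibble with `address` and `sequence` of the
#'   true oligos (e.g. `encode_store(...)$oligos`).
#' @return A pooled `error_stats` with an extra `per_position` tibble.
#' @export
consensus_error_report <- function(consensus, reference_oligos) {
  merged <- dplyr::inner_join(
    consensus, reference_oligos,
    by = "address"
  )
  stats_list <- lapply(seq_len(nrow(merged)), function(i) {
    error_statistics(merged$consensus[i], merged$sequence[i])
  })
  combine_error_stats(stats_list, merged$address)
}
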