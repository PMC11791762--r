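#' Error-channel profile
#'
#' Describes the per-letter mutation channel applied to stored oligos:
#' each position is independently hit with probability `total_rate`, and
#' a hit is a substitution (uniformly chosen different letter), an
#' insertion (uniform letter inserted after the position) or a deletion,
#' drawn from `mix`. The paper-style sweep uses rates from 0.01% to 1%
#' with the three mutation classes equally likely.
#'
#' @param total_rate Per-position error probability in [0, 1].
#' @param mix Numeric length-3 weights (substitution, insertion,
#'   deletion); normalised to sum to 1.
#' @return A list of class `error_profile`.
#' @export
error_profile <- function(total_rate, mix = c(1, 1, 1) / 3) {
  stopifnot(total_rate >= 0, total_rate <= 1, length(mix) == 3, all(mix >= 0),
            sum(mix) > 0)
  structure(
    list(total_rate = total_rate, mix = mix / sum(mix)),
    class = "error_profile"
  )
}

#' Inject random substitutions, insertions and deletions
#'
#' Mutates a letter sequence under an [error_profile()] using R's global
#' RNG, so results are reproducible under `set.seed()`.
#'
#' @param seq A letter string.
#' @param profile An [error_profile()].
#' @param alphabet The [expanded_alphabet()] the sequence is drawn from.
#' @return The mutated letter string (length may differ from the input
#'   when insertions or deletions occur).
#' @examples
#' set.seed(1)
#' inject_errors("GACA", error_profile(0.5))
#' @export
inject_errors <- function(seq, profile, alphabet = expanded_alphabet()) {
  cc <- chars(seq)
  n <- length(cc)
  if (n == 0 || profile$total_rate == 0) return(seq)
  hit <- which(stats::runif(n) < profile$total_rate)
  if (length(hit) == 0) return(seq)
  type <- sample.int(3L, length(hit), replace = TRUE, prob = profile$mix)
  out <- as.list(cc)
  k <- alphabet$size
  for (j in seq_along(hit)) {
    i <- hit[j]
    if (type[j] == 1L) {            # substitution: any different letter
      cur <- match(cc[i], alphabet$letters)
      pick <- sample.int(k - 1L, 1L)
      if (!is.na(cur) && pick >= cur) pick <- pick + 1L
      out[[i]] <- alphabet$letters[pick]
    } else if (type[j] == 2L) {     # insertion after the position
      out[[i]] <- c(cc[i], alphabet$letters[sample.int(k, 1L)])
    } else {                        # deletion
      out[[i]] <- character(0)
    }
  }
  paste(unlist(out, use.names = FALSE), collapse = "")
}

bit_counts <- local({
  counts <- vapply(0:255, function(x) {
    sum(bitwAnd(bitwShiftR(x, 0:7), 1L))
  }, integer(1))
  function(x) counts[x + 1L]
})

#' Bit-level data recovery rate
#'
#' The fraction of accurately decoded bits relative to the total bits of
#' the original byte stream; the decoded stream is zero-padded or
#' truncated to the original length before comparison.
#'
#' @param original,decoded Raw vectors.
#' @return Fraction in [0, 1] (1 for an empty original).
#' @examples
#' recovery_rate(as.raw(c(255, 0)), as.raw(c(255, 1)))  # 15/16
#' @export
recovery_rate <- function(original, decoded) {
  n <- length(original)
  if (n == 0) return(1)
  length(decoded) <- n                       # raw vectors pad with 0x00
  wrong <- sum(bit_counts(bitwXor(as.integer(original), as.integer(decoded))))
  1 - wrong / (8 * n)
}

derive_seed <- function(seed, rate_i, rep_j) {
  as.integer((as.numeric(seed) + 1000003 * rate_i + 7919 * rep_j) %% 2147483647)
}

#' Replicated recovery-rate simulation across error rates
#'
#' Encodes a byte stream once (with XOR redundancy unless disabled),
#' then, for every error rate and replicate, corrupts each oligo
#' independently under the channel, decodes with erasure recovery and
#' measures the bit recovery rate against the original. Per rate it
#' reports the replicate mean (Avg) and coefficient of variation
#' (Cov = sd/mean), the two summary statistics used to characterise
#' recovery under an error sweep.
#'
#' @param data Raw vector to store.
#' @param rates Numeric vector of per-position error probabilities.
#' @param reps Replicates per rate (default 10).
#' @param mix Substitution/insertion/deletion weights, see
#'   [error_profile()].
#' @param seed Integer seed; each (rate, replicate) cell derives its own
#'   sub-seed so the experiment is reproducible yet cells are
#'   independent.
#' @param config A [store_config()].
#' @param redundancy Encode with XOR segments (default TRUE).
#' @return An object of class `recovery_sim` with `replicates` (tibble:
#'   rate, replicate, recovery), `summary` (tibble: rate, n, avg, cov)
#'   and the call parameters. `tidy()` returns the per-rate summary,
#'   `glance()` a one-row overview, `autoplot()` the mean-recovery curve.
#' @examples
#' sim <- run_recovery_experiment(as.raw(0:255), rates = c(0, 0.001),
#'                                reps = 3, seed = 1)
#' tidy(sim)
#' @export
run_recovery_experiment <- function(data, rates, reps = 10L,
                                    mix = c(1, 1, 1) / 3, seed = 1L,
                                    config = store_config(),
                                    redundancy = TRUE) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  stopifnot(all(rates >= 0), all(rates <= 1))
  store <- encode_store(data, config, redundancy = redundancy)
  grid <- tidyr::expand_grid(rate_i = seq_along(rates), replicate = seq_len(reps))
  recov <- purrr::pmap_dbl(grid, function(rate_i, replicate) {
    profile <- error_profile(rates[rate_i], mix)
    set.seed(derive_seed(seed, rate_i, replicate))
    corrupted <- vapply(
      store$oligos$sequence, inject_errors, character(1),
      profile = profile, alphabet = config$alphabet,
      USE.NAMES = FALSE
    )
    reassemble_file(corrupted, store$manifest, original = data)$recovery_rate
  })
  replicates <- tibble::tibble(
    rate = rates[grid$rate_i], replicate = grid$replicate, recovery = recov
  )
  summary <- replicates |>
    dplyr::group_by(rate) |>
    dplyr::summarise(
      n = dplyr::n(),
      avg = mean(recovery),
      cov = ifelse(mean(recovery) > 0, stats::sd(recovery) / mean(recovery), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(cov = ifelse(is.na(cov), 0, cov))
  structure(
    list(
      replicates = replicates, summary = summary,
      params = list(
        n_bytes = length(data), rates = rates, reps = reps, mix = mix,
        seed = seed, redundancy = redundancy
      )
    ),
    class = "recovery_sim"
  )
}

#' @export
print.recovery_sim <- function(x, ...) {
  cat(
    "<recovery_sim> ", x$params$n_bytes, " bytes, ", x$params$reps,
    " replicates per rate", if (!x$params$redundancy) ", XOR disabled", "\n",
    sep = ""
  )
  print(x$summary)
  invisible(x)
}

#' @rdname run_recovery_experiment
#' @param x A `recovery_sim`.
#' @param ... Unused.
#' @method tidy recovery_sim
#' @export
tidy.recovery_sim <- function(x, ...) x$summary

#' @rdname run_recovery_experiment
#' @method glance recovery_sim
#' @export
glance.recovery_sim <- function(x, ...) {
  tibble::tibble(
    n_rates = length(x$params$rates),
    reps = x$params$reps,
    min_avg = min(x$summary$avg),
    max_avg = max(x$summary$avg),
    max_cov = max(x$summary$cov)
  )
}

#' @rdname run_recovery_experiment
#' @param object A `recovery_sim`.
#' @method autoplot recovery_sim
#' @export
autoplot.recovery_sim <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = rate, y = avg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = avg - avg * cov, ymax = pmin(1, avg + avg * cov)),
      width = 0.05
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "per-position error rate", y = "mean bit recovery rate",
      title = "Data recovery under the substitution/indel channel"
    )
}
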