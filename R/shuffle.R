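#' Shuffle (permutation) validation of DMR calls
#'
#' Estimates how many DMRs arise by chance in one father-sorted comparison.
#' The null is a site-wise group-label permutation: at every common CpG the
#' (methylated, unmethylated) count pairs of the two groups are swapped
#' independently with probability 0.5, the DMR caller is re-run, and the
#' resulting DMR count recorded — repeated `n_shuffles` times (default 100).
#'
#' Because the two-sided Fisher p-value, the BH q-value and the absolute
#' ratio difference at a site are invariant under swapping that site's two
#' groups, the per-site statistics are computed once and each shuffle only
#' flips the sign of the ratio difference at swapped sites before re-running
#' the region merging; this is exactly equivalent to re-calling DMRs on the
#' swapped tables.
#'
#' @param control,treated Methylome tables (as for [call_dmrs()]).
#' @param params A [dmr_params()] object.
#' @param n_shuffles Number of shuffles; default 100.
#' @param seed Integer seed making the shuffle sequence reproducible.
#' @param father_id Optional father label.
#' @return An object of class `shuffle_result`: a list with `father_id`,
#'   `n_shuffles`, `null_counts` (per-shuffle DMR counts), `mean_null`,
#'   `max_null` and `observed` (the unshuffled DMR count).
#' @export
shuffle_test <- function(control, treated, params = dmr_params(),
                         n_shuffles = 100, seed = 1,
                         father_id = NA_character_) {
  if (!is_count(n_shuffles, min = 1)) {
    stop("n_shuffles must be a positive integer", call. = FALSE)
  }
  stats <- site_stats(control, treated, params)
  observed <- nrow(segment_dmrs(stats, params, father_id))
  counts <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      swap <- runif(nrow(stats)) < 0.5
      nrow(shuffle_once(stats, params, swap))
    }, integer(1))
  })
  structure(
    list(
      father_id = father_id,
      n_shuffles = as.integer(n_shuffles),
      null_counts = counts,
      mean_null = mean(counts),
      max_null = max(counts),
      observed = observed
    ),
    class = "shuffle_result"
  )
}

# One shuffle: flip the difference sign at swapped sites, re-segment.
shuffle_once <- function(stats, params, swap) {
  stopifnot(length(swap) == nrow(stats))
  flipped <- stats
  flipped$diff <- ifelse(swap, -stats$diff, stats$diff)
  segment_dmrs(flipped, params)
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(
    "Shuffle validation", if (!is.na(x$father_id)) paste0("(father ", x$father_id, ")"),
    "\n  shuffles:  ", x$n_shuffles,
    "\n  observed:  ", x$observed, " DMRs",
    "\n  null mean: ", format(x$mean_null, digits = 4),
    " (max ", x$max_null, ") DMRs per calculation\n",
    sep = ""
  )
  invisible(x)
}
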