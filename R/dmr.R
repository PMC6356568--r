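#' Parameters for DMR calling
#'
#' Bundles the thresholds of the region caller. Per-CpG 2x2 Fisher exact
#' p-values are corrected by Benjamini-Hochberg across all sites of one
#' comparison; sites with `q <= q_max`, `|ratio difference| >= min_diff` and
#' a common sign are merged into a region when consecutive significant sites
#' lie at most `max_gap` bp apart, and regions with at least `min_cpgs`
#' sites are reported.
#'
#' @param min_coverage Minimum reads per CpG in each group (after pooling)
#'   for the site to be tested. Default 5.
#' @param q_max Per-site BH q-value threshold. Default 0.05.
#' @param min_diff Minimum absolute methylation-ratio difference
#'   (treated - control). Default 0.10.
#' @param min_cpgs Minimum number of significant CpGs per region. Default 3.
#' @param max_gap Maximum distance in bp between consecutive significant
#'   CpGs merged into one region. Default 100.
#' @return An object of class `dmr_params`.
#' @export
dmr_params <- function(min_coverage = 5, q_max = 0.05, min_diff = 0.10,
                       min_cpgs = 3, max_gap = 100) {
  stopifnot(
    is_count(min_coverage, min = 1), is_prob(q_max),
    is.numeric(min_diff), min_diff >= 0, min_diff <= 1,
    is_count(min_cpgs, min = 1), is_count(max_gap, min = 0)
  )
  structure(
    list(
      min_coverage = as.integer(min_coverage), q_max = q_max,
      min_diff = min_diff, min_cpgs = as.integer(min_cpgs),
      max_gap = as.integer(max_gap)
    ),
    class = "dmr_params"
  )
}

#' Pool methylation counts across samples
#'
#' Sums per-CpG methylated and unmethylated counts across the given samples,
#' emulating pooling of DNA from several offspring of one sire. The union of
#' sites is kept: a site missing from a sample contributes 0/0 there.
#'
#' @param methylomes Named list of methylome tables (see [read_coverage()]).
#' @param group Character vector of sample ids to pool; default all.
#' @param sample_id Identifier for the pooled table.
#' @return A methylome table of summed counts.
#' @export
pool_counts <- function(methylomes, group = names(methylomes), sample_id = "pool") {
  if (length(group) == 0) stop("empty group", call. = FALSE)
  missing <- setdiff(group, names(methylomes))
  if (length(missing) > 0) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  stacked <- dplyr::bind_rows(methylomes[group])
  pooled <- dplyr::summarise(
    dplyr::group_by(stacked, .data$chrom, .data$pos),
    count_meth = sum(.data$count_meth),
    count_unmeth = sum(.data$count_unmeth),
    .groups = "drop"
  )
  methylome_table(pooled, sample_id)
}

#' Two-sided Fisher exact test for a 2x2 methylation table
#'
#' Exact two-sided p-value for the table
#' `[[count_meth_c, count_unmeth_c], [count_meth_t, count_unmeth_t]]`,
#' computed by hypergeometric enumeration (summing all tables with
#' point probability at most that of the observed table). Vectorised over
#' sites.
#'
#' @param count_meth_c,count_unmeth_c Methylated/unmethylated read counts in
#'   the control group.
#' @param count_meth_t,count_unmeth_t Counts in the treated group.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
site_test <- function(count_meth_c, count_unmeth_c, count_meth_t, count_unmeth_t) {
  n <- length(count_meth_c)
  stopifnot(
    length(count_unmeth_c) == n, length(count_meth_t) == n,
    length(count_unmeth_t) == n
  )
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- count_meth_c[i] + count_meth_t[i]
    u <- count_unmeth_c[i] + count_unmeth_t[i]
    k <- count_meth_c[i] + count_unmeth_c[i]
    lo <- max(0L, k - u)
    hi <- min(k, m)
    d <- dhyper(lo:hi, m, u, k)
    # relative tolerance guards against ties lost to floating point,
    # matching the convention of exact-test implementations
    p[i] <- sum(d[d <= d[count_meth_c[i] - lo + 1L] * (1 + 1e-7)])
  }
  pmin(p, 1)
}

# Align two methylome tables on their common CpG grid, apply the coverage
# floor per group, and compute per-site statistics: ratio difference
# (treated - control), Fisher p and BH q. The q correction spans all tested
# sites of the comparison.
site_stats <- function(control, treated, params) {
  joined <- dplyr::inner_join(
    control, treated,
    by = c("chrom", "pos"), suffix = c("_c", "_t")
  )
  if (nrow(joined) == 0) stop("zero overlapping CpG sites", call. = FALSE)
  cov_c <- joined$count_meth_c + joined$count_unmeth_c
  cov_t <- joined$count_meth_t + joined$count_unmeth_t
  keep <- cov_c >= params$min_coverage & cov_t >= params$min_coverage
  joined <- joined[keep, , drop = FALSE]
  if (nrow(joined) == 0) stop("no CpG sites pass the coverage floor", call. = FALSE)
  ratio_c <- joined$count_meth_c / (joined$count_meth_c + joined$count_unmeth_c)
  ratio_t <- joined$count_meth_t / (joined$count_meth_t + joined$count_unmeth_t)
  p <- site_test(
    joined$count_meth_c, joined$count_unmeth_c,
    joined$count_meth_t, joined$count_unmeth_t
  )
  tibble::tibble(
    chrom = joined$chrom,
    pos = joined$pos,
    diff = ratio_t - ratio_c,
    p_value = p,
    q_value = p.adjust(p, method = "BH")
  )
}

# Merge significant sites into regions. `diff` supplies both the magnitude
# filter and the sign used for same-direction merging; shuffle_test calls
# this with sign-flipped diffs.
segment_dmrs <- function(stats, params, father_id = NA_character_) {
  sig <- stats$q_value <= params$q_max & abs(stats$diff) >= params$min_diff
  s <- stats[sig, , drop = FALSE]
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), mean_diff = numeric(),
    direction = character(), p_value = numeric(), q_value = numeric(),
    father_id = character()
  )
  if (nrow(s) == 0) return(empty)
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  sgn <- sign(s$diff)
  new_run <- c(
    TRUE,
    s$chrom[-1] != s$chrom[-nrow(s)] |
      sgn[-1] != sgn[-nrow(s)] |
      (s$pos[-1] - s$pos[-nrow(s)]) > params$max_gap
  )
  run <- cumsum(new_run)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(s, run = run), .data$run),
    chrom = .data$chrom[1],
    start = min(.data$pos),
    end = max(.data$pos) + 1L,
    n_cpgs = dplyr::n(),
    mean_diff = mean(.data$diff),
    p_value = min(.data$p_value),
    q_value = min(.data$q_value),
    .groups = "drop"
  )
  out <- out[out$n_cpgs >= params$min_cpgs, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  tibble::tibble(
    chrom = out$chrom,
    start = as.integer(out$start),
    end = as.integer(out$end),
    n_cpgs = as.integer(out$n_cpgs),
    mean_diff = out$mean_diff,
    direction = ifelse(out$mean_diff > 0, "hyper", "hypo"),
    p_value = out$p_value,
    q_value = out$q_value,
    father_id = father_id
  )
}

#' Call differentially methylated regions between two groups
#'
#' Compares a control and a treated methylome (typically pooled counts of
#' one sire's offspring on each side) on their common CpG grid: per-site
#' two-sided Fisher exact tests, BH correction across all tested sites,
#' then merging of significant same-direction sites within `max_gap` bp
#' into regions of at least `min_cpgs` CpGs. Region `mean_diff` is the
#' unweighted mean of site ratio differences; region p and q are the minima
#' over member sites.
#'
#' @param control,treated Methylome tables.
#' @param params A [dmr_params()] object.
#' @param father_id Optional father label stamped on the result.
#' @return A tibble with one row per DMR: `chrom`, `start`, `end` (0-based
#'   half-open), `n_cpgs`, `mean_diff` (treated - control), `direction`
#'   (`hyper`/`hypo`), `p_value`, `q_value`, `father_id`.
#' @export
call_dmrs <- function(control, treated, params = dmr_params(),
                      father_id = NA_character_) {
  segment_dmrs(site_stats(control, treated, params), params, father_id)
}
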