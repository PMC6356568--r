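# Fixture builders and independent brute-force oracles shared across tests.
# Oracles deliberately use naive enumeration (or a different library routine)
# than the shipped implementation.

make_methylome <- function(pos, meth, unmeth, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    count_meth = as.integer(meth), count_unmeth = as.integer(unmeth)
  )
}

# random 2x2 count tables for Fisher-test comparisons
random_tables <- function(n, max_count = 40) {
  tibble::tibble(
    mc = sample(0:max_count, n, replace = TRUE),
    uc = sample(0:max_count, n, replace = TRUE),
    mt = sample(0:max_count, n, replace = TRUE),
    ut = sample(0:max_count, n, replace = TRUE)
  ) |>
    dplyr::filter(mc + uc > 0, mt + ut > 0)
}

# oracle: per-table stats::fisher.test
fisher_oracle <- function(tab) {
  vapply(seq_len(nrow(tab)), function(i) {
    stats::fisher.test(matrix(
      c(tab$mc[i], tab$uc[i], tab$mt[i], tab$ut[i]),
      nrow = 2, byrow = TRUE
    ))$p.value
  }, numeric(1))
}

# oracle: explicit enumeration of maximal significant same-sign runs
brute_segment_oracle <- function(stats, params) {
  sig <- stats$q_value <= params$q_max & abs(stats$diff) >= params$min_diff
  s <- stats[sig, , drop = FALSE]
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  regions <- list()
  run <- integer(0)
  flush <- function(run) {
    if (length(run) >= params$min_cpgs) {
      r <- s[run, , drop = FALSE]
      regions[[length(regions) + 1L]] <<- tibble::tibble(
        chrom = r$chrom[1],
        start = as.integer(min(r$pos)),
        end = as.integer(max(r$pos) + 1L),
        n_cpgs = nrow(r),
        mean_diff = mean(r$diff),
        direction = if (mean(r$diff) > 0) "hyper" else "hypo",
        p_value = min(r$p_value),
        q_value = min(r$q_value)
      )
    }
  }
  for (i in seq_len(nrow(s))) {
    if (length(run) == 0) {
      run <- i
    } else {
      prev <- run[length(run)]
      broken <- s$chrom[i] != s$chrom[prev] ||
        sign(s$diff[i]) != sign(s$diff[prev]) ||
        (s$pos[i] - s$pos[prev]) > params$max_gap
      if (broken) {
        flush(run)
        run <- i
      } else {
        run <- c(run, i)
      }
    }
  }
  flush(run)
  if (length(regions) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      n_cpgs = integer(), mean_diff = numeric(), direction = character(),
      p_value = numeric(), q_value = numeric()
    ))
  }
  dplyr::bind_rows(regions)
}

# random site-statistics table on an irregular grid
random_stats <- function(n_sites, seed) {
  sireDMR:::with_seed(seed, {
    pos <- cumsum(sample(c(10L, 40L, 90L, 150L), n_sites, replace = TRUE))
    p <- runif(n_sites)^3
    tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n_sites, replace = TRUE),
      pos = pos,
      diff = runif(n_sites, -0.6, 0.6),
      p_value = p,
      q_value = stats::p.adjust(p, "BH")
    )
  })
}

# oracle: O(n * m) interval overlap scan (0-based half-open)
brute_overlap_oracle <- function(dmrs, features) {
  hits <- list()
  for (i in seq_len(nrow(dmrs))) {
    for (j in seq_len(nrow(features))) {
      if (dmrs$chrom[i] == features$chrom[j] &&
          max(dmrs$start[i], features$start[j]) <
            min(dmrs$end[i], features$end[j])) {
        hits[[length(hits) + 1L]] <- c(i = i, j = j)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(i = integer(), j = integer()))
  }
  as.data.frame(do.call(rbind, hits))
}

# oracle: count within-set edges by explicit row filtering
brute_edge_oracle <- function(genes, interactions, threshold) {
  n <- 0L
  for (i in seq_len(nrow(interactions))) {
    if (interactions$combined_score[i] >= threshold &&
        interactions$gene_a[i] %in% genes &&
        interactions$gene_b[i] %in% genes) {
      n <- n + 1L
    }
  }
  n
}

# small annotation + simulated experiment used by several tests
small_simulation <- function(seed, planted_genes = NULL, pooled = TRUE,
                             replication_pattern = NULL, planted_effect = -0.4,
                             n_genes = 10, chrom_length = 1.5e5, ...) {
  feat <- simulate_annotation(n_genes, chrom_length, seed = seed)
  n_planted <- if (is.null(planted_genes)) 0 else length(planted_genes)
  design <- sim_design(
    planted_genes = planted_genes,
    n_planted_genes = n_planted,
    replication_pattern = replication_pattern,
    planted_effect = if (n_planted == 0) 0 else planted_effect,
    pooled = pooled,
    seed = seed,
    ...
  )
  sim <- simulate_methylomes(design, feat)
  sim$features <- feat
  sim
}
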