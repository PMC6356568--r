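#' Count interactions within a gene set
#'
#' Number of edges of the interaction table whose two endpoints both lie in
#' the gene set and whose combined score is at least `threshold`. This is
#' the observed statistic of the enrichment test; raising the stringency
#' threshold can only reduce it.
#'
#' @param genes Character vector of gene ids.
#' @param interactions An interaction tibble (see [read_interactions()]).
#' @param threshold Combined-score stringency in \[0, 1\]; default 0.5.
#' @return Integer edge count.
#' @export
edge_count <- function(genes, interactions, threshold = 0.5) {
  stopifnot(is_prob(threshold))
  sum(
    interactions$combined_score >= threshold &
      interactions$gene_a %in% genes &
      interactions$gene_b %in% genes
  )
}

#' Permutation test of interaction enrichment in a gene set
#'
#' Compares the observed within-set edge count against the counts of
#' uniformly sampled gene sets of the same size drawn from the table's gene
#' universe (all genes appearing in any edge). The empirical p-value uses
#' add-one smoothing, `p = (1 + #[null >= observed]) / (n_perm + 1)`, so it
#' is never zero. Genes absent from the universe are dropped with a
#' warning. The null ignores node degree: it asks whether this many
#' interactions would be seen in a random gene set of similar size.
#'
#' @param genes Character vector of gene ids.
#' @param interactions An interaction tibble.
#' @param threshold Combined-score stringency; default 0.5.
#' @param n_perm Number of random gene sets; default 999.
#' @param seed Integer seed.
#' @return An object of class `enrichment_result`: list with `n_obs`,
#'   `n_exp` (null mean), `p_value`, `n_perm`, `n_genes`, `threshold`,
#'   `seed` and the vector `null_counts`.
#' @export
enrichment_test <- function(genes, interactions, threshold = 0.5,
                            n_perm = 999, seed = 1) {
  stopifnot(is_count(n_perm, min = 1))
  universe <- unique(c(interactions$gene_a, interactions$gene_b))
  genes <- unique(genes)
  unknown <- setdiff(genes, universe)
  if (length(unknown) > 0) {
    warning(
      length(unknown), " gene(s) absent from the interaction universe dropped",
      call. = FALSE
    )
    genes <- intersect(genes, universe)
  }
  if (length(genes) == 0) stop("no genes left in the interaction universe", call. = FALSE)
  n_obs <- edge_count(genes, interactions, threshold)
  m <- length(genes)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      edge_count(sample(universe, m), interactions, threshold)
    }, integer(1))
  })
  structure(
    list(
      n_obs = n_obs,
      n_exp = mean(null_counts),
      p_value = (1 + sum(null_counts >= n_obs)) / (n_perm + 1),
      n_perm = as.integer(n_perm),
      n_genes = m,
      threshold = threshold,
      seed = seed,
      null_counts = null_counts
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(
    "Interaction enrichment (", x$n_genes, " genes, score >= ", x$threshold, ")\n",
    "  n_obs = ", x$n_obs, ", n_exp = ", format(x$n_exp, digits = 4),
    ", p = ", format(x$p_value, digits = 4),
    " (", x$n_perm, " permutations)\n",
    sep = ""
  )
  invisible(x)
}

#' Export a gene list as plain text
#'
#' One gene symbol per line, suitable for pasting into interaction-database
#' web services.
#'
#' @param genes Character vector of gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sort(unique(genes)), path)
  invisible(path)
}
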