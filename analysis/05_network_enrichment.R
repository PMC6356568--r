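#!/usr/bin/env Rscript
# Step 5 -- interaction-network enrichment of the shared gene set, offline.
# A synthetic interaction table stands in for a protein-interaction
# database: 400 background genes plus the workflow's shared genes as a
# partially connected module. The statistic is the within-set edge count at
# stringency 0.5 versus random same-size gene sets drawn from the table's
# universe (999 permutations, add-one-smoothed empirical p).

suppressMessages(library(sireDMR))

seed <- 2024
shared <- readLines("results/genes_shared.txt")

universe_extra <- sprintf("g%04d", 1:400)
background <- simulate_interaction_table(400, 800, seed = seed)
# connect the shared genes among themselves at high confidence
pairs <- utils::combn(sort(shared), 2)
module_edges <- tibble::tibble(
  gene_a = pairs[1, ], gene_b = pairs[2, ], combined_score = 0.9
)
keep <- sireDMR:::with_seed(seed, runif(nrow(module_edges)) < 0.6)
interactions <- dplyr::bind_rows(background, module_edges[keep, ])
# anchor shared genes in the universe with low-confidence background edges
anchor <- tibble::tibble(
  gene_a = pmin(shared, universe_extra[seq_along(shared)]),
  gene_b = pmax(shared, universe_extra[seq_along(shared)]),
  combined_score = 0.2
)
interactions <- sireDMR:::interaction_table(dplyr::bind_rows(interactions, anchor))
write_interactions(interactions, "scratch/analysis_data/interactions.tsv")

res <- enrichment_test(shared, interactions, threshold = 0.5,
                       n_perm = 999, seed = seed)
print(res)

readr::write_tsv(
  tibble::tibble(
    n_genes = res$n_genes, threshold = res$threshold,
    n_obs = res$n_obs, n_exp = res$n_exp,
    p_value = res$p_value, n_perm = res$n_perm
  ),
  "results/network_enrichment.tsv"
)
write_gene_list(shared, "results/string_export_shared.txt")
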