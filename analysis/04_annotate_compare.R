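#!/usr/bin/env Rscript
# Step 4 -- annotation, replication filtering and the cross-factor
# comparison. DMRs are overlapped with promoters/CDS/CpG islands; genes hit
# in all 5 father groups (experiment D, the conservative rule for pooled
# data) or in at least 4 of 5 (experiment H, individually sequenced) are
# kept; the two gene lists are intersected and shared genes classified by
# regulatory region (promoter takes precedence over CDS). The same
# bookkeeping is applied to the packaged 21-gene shared table as a
# reference calculation.

suppressMessages(library(sireDMR))

data_dir <- "scratch/analysis_data"
features <- read_features("results/annotation.bed", "bed")
params <- dmr_params()

hit_matrices <- list()
for (label in c("D", "H")) {
  design <- read_design_table(file.path(data_dir, paste0("design_", label, ".tsv")))
  methylomes <- lapply(design$sample_id, function(sid) {
    read_coverage(file.path(data_dir, paste0(sid, ".cov")), sample_id = sid)
  })
  names(methylomes) <- design$sample_id
  dmrs <- run_father_comparisons(methylomes, design, params)
  hit_matrices[[label]] <- experiment_gene_hits(dmrs, features)
}

genes_d <- replication_filter(hit_matrices$D, k = 5)
genes_h <- replication_filter(hit_matrices$H, k = 4)
venn <- cross_factor_venn(genes_d, genes_h, hit_matrices$D, hit_matrices$H,
                          labels = c("D", "H"))
print(venn)
tally <- classify_shared(venn)
cat("shared-gene classes:", paste(names(tally), tally, collapse = ", "), "\n")

planted_shared <- readLines("results/planted_shared_genes.txt")
cat(sprintf(
  "planted shared genes recovered: %d of %d\n",
  sum(planted_shared %in% venn$shared), length(planted_shared)
))

write_gene_list(genes_d, "results/genes_D_5of5.txt")
write_gene_list(genes_h, "results/genes_H_4of5.txt")
write_gene_list(venn$shared, "results/genes_shared.txt")
readr::write_tsv(
  tibble::tibble(
    set = c("D_only", "H_only", "shared", "shared_promoter", "shared_CDS"),
    n = c(length(venn$a_only), length(venn$b_only), tally["shared"],
          tally["promoter"], tally["CDS"])
  ),
  "results/venn_summary.tsv"
)

# reference bookkeeping on the packaged shared-gene table
tab <- shared_gene_table()
ref <- classify_shared(venn_result(
  character(0), character(0), tab$gene_id,
  shared_classes = tibble::tibble(gene_id = tab$gene_id, class = tab$region)
))
cat(sprintf(
  "packaged shared-gene table: %d shared (%d CDS, %d promoter), %d with known function\n",
  ref["shared"], ref["CDS"], ref["promoter"], sum(tab$function_known == "yes")
))
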