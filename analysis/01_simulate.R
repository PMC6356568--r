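#!/usr/bin/env Rscript
# Step 1 -- generate the two synthetic experiments the rest of the workflow
# analyses, mirroring the study design: five sires per experiment, offspring
# sired before (control) and after (treated) the father's exposure.
#
#   experiment D ("diet"):  offspring DNA pooled by father and condition,
#                           planted shifts carried by all 5 sires
#   experiment H ("heat"):  offspring sequenced individually,
#                           planted shifts carried by 4 of 5 sires
#
# Six genes are planted in both experiments (the "general response" genes
# this workflow should recover as shared), plus four factor-specific genes
# per experiment. Everything is written as plain text: Bismark-style
# coverage files and design tables under scratch/ (bulky intermediates),
# annotation and ground truth under results/.

suppressMessages(library(sireDMR))

data_dir <- "scratch/analysis_data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

seed <- 2024
features <- simulate_annotation(n_genes = 40, chrom_length = 4e5, seed = seed)
write_features(features, file.path("results", "annotation.bed"))

genes <- sort(features$gene_id[features$class == "gene"])
shared_genes <- genes[1:6]
d_only <- genes[7:10]
h_only <- genes[11:14]

pat_all <- function(n) matrix(TRUE, n, 5)
pat_4of5 <- function(n) {
  m <- matrix(TRUE, n, 5)
  for (i in seq_len(n)) m[i, ((i - 1) %% 5) + 1] <- FALSE
  m
}

design_d <- sim_design(
  pooled = TRUE,
  planted_genes = c(shared_genes, d_only),
  replication_pattern = pat_all(10),
  experiment = "D", father_ids = LETTERS[1:5], seed = seed + 1
)
design_h <- sim_design(
  pooled = FALSE,
  planted_genes = c(shared_genes, h_only),
  replication_pattern = rbind(pat_4of5(6), pat_all(4)),
  experiment = "H", father_ids = LETTERS[6:10], seed = seed + 2
)

for (label in c("D", "H")) {
  design <- if (label == "D") design_d else design_h
  sim <- simulate_methylomes(design, features)
  for (sid in names(sim$methylomes)) {
    write_coverage(sim$methylomes[[sid]], file.path(data_dir, paste0(sid, ".cov")))
  }
  write_design_table(sim$design_table, file.path(data_dir, paste0("design_", label, ".tsv")))
  write_truth(sim$truth, file.path("results", paste0("truth_", label, ".bed")))
  cat(sprintf(
    "experiment %s: %d samples, %d CpG sites, %d planted regions\n",
    label, length(sim$methylomes), nrow(sim$methylomes[[1]]), nrow(sim$truth)
  ))
}

writeLines(shared_genes, file.path("results", "planted_shared_genes.txt"))
cat("planted shared genes:", paste(shared_genes, collapse = ", "), "\n")
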