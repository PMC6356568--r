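#!/usr/bin/env Rscript
# Step 2 -- father-sorted DMR calling. For each experiment, each father's
# control samples are pooled and compared against his treated samples:
# per-CpG Fisher exact tests, BH correction per comparison, merging of
# significant same-direction sites (gap <= 100 bp, >= 3 CpGs,
# |ratio difference| >= 0.10, q <= 0.05). Writes one BED6+ DMR table per
# experiment under results/.

suppressMessages(library(sireDMR))

data_dir <- "scratch/analysis_data"
params <- dmr_params()

for (label in c("D", "H")) {
  design <- read_design_table(file.path(data_dir, paste0("design_", label, ".tsv")))
  methylomes <- lapply(design$sample_id, function(sid) {
    read_coverage(file.path(data_dir, paste0(sid, ".cov")), sample_id = sid)
  })
  names(methylomes) <- design$sample_id
  dmrs <- run_father_comparisons(methylomes, design, params)
  all_dmrs <- dplyr::bind_rows(dmrs)
  write_dmrs(all_dmrs, file.path("results", paste0("dmrs_", label, ".bed")))
  cat(sprintf(
    "experiment %s: %s DMRs per father (total %d, %d hyper / %d hypo)\n",
    label,
    paste(vapply(dmrs, nrow, integer(1)), collapse = "/"),
    nrow(all_dmrs),
    sum(all_dmrs$direction == "hyper"),
    sum(all_dmrs$direction == "hypo")
  ))
}
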