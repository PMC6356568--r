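#' Run father-sorted DMR comparisons for one experiment
#'
#' For each father in the design table, pools the control and the treated
#' samples separately (an identity when the data are already one pool per
#' side) and calls DMRs between the two pooled methylomes.
#'
#' @param methylomes Named list of methylome tables.
#' @param design_table Design tibble (see [read_design_table()]).
#' @param params A [dmr_params()] object.
#' @return Named list (father id -> DMR tibble).
#' @export
run_father_comparisons <- function(methylomes, design_table, params = dmr_params()) {
  design_table <- validate_design(design_table)
  fathers <- unique(design_table$father_id)
  out <- lapply(fathers, function(f) {
    rows <- design_table[design_table$father_id == f, , drop = FALSE]
    ctrl <- pool_counts(
      methylomes, rows$sample_id[rows$condition == "control"],
      sample_id = paste0(f, "_control")
    )
    trt <- pool_counts(
      methylomes, rows$sample_id[rows$condition == "treated"],
      sample_id = paste0(f, "_treated")
    )
    call_dmrs(ctrl, trt, params, father_id = f)
  })
  names(out) <- fathers
  out
}

#' Annotate per-father DMRs and build the gene hit matrix
#'
#' @param dmrs_by_father Named list from [run_father_comparisons()].
#' @param features A feature-set tibble with promoter/CDS (and optionally
#'   CGI) rows.
#' @return A [gene_hit_matrix()].
#' @export
experiment_gene_hits <- function(dmrs_by_father, features) {
  gene_hit_matrix(lapply(dmrs_by_father, annotate_dmrs, features = features))
}

#' Shuffle validation for every father of an experiment
#'
#' Runs [shuffle_test()] per father and returns the per-father results plus
#' the grand mean of the per-calculation null DMR counts — the quantity
#' benchmarked against the expectation that random shuffling yields fewer
#' than 2 DMRs per calculation.
#'
#' @inheritParams run_father_comparisons
#' @param n_shuffles Shuffles per father; default 100.
#' @param seed Integer seed; each father uses `seed + father index`.
#' @return List with `per_father` (list of `shuffle_result`) and
#'   `mean_null` (mean over fathers of each father's mean null count).
#' @export
run_shuffle_validation <- function(methylomes, design_table,
                                   params = dmr_params(),
                                   n_shuffles = 100, seed = 1) {
  design_table <- validate_design(design_table)
  fathers <- unique(design_table$father_id)
  res <- lapply(seq_along(fathers), function(i) {
    f <- fathers[i]
    rows <- design_table[design_table$father_id == f, , drop = FALSE]
    ctrl <- pool_counts(
      methylomes, rows$sample_id[rows$condition == "control"],
      sample_id = paste0(f, "_control")
    )
    trt <- pool_counts(
      methylomes, rows$sample_id[rows$condition == "treated"],
      sample_id = paste0(f, "_treated")
    )
    shuffle_test(ctrl, trt, params,
      n_shuffles = n_shuffles, seed = seed + i, father_id = f
    )
  })
  names(res) <- fathers
  list(
    per_father = res,
    mean_null = mean(vapply(res, function(r) r$mean_null, numeric(1)))
  )
}
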