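#' Replication filter: genes hit in at least k father groups
#'
#' Implements the k-of-n replicate-consistency rule: a gene passes when it
#' carries a DMR (in a promoter or CDS) in at least `k` of the father-sorted
#' comparisons. `k = n` is the most conservative choice (used for pooled
#' designs where individual-level DMRs are unavailable); `k = n - 1` relaxes
#' it slightly for individually sequenced designs.
#'
#' @param matrix A [gene_hit_matrix()].
#' @param k Minimum number of father groups; must lie in 1..n_fathers.
#' @return Sorted character vector of gene ids.
#' @export
replication_filter <- function(matrix, k) {
  stopifnot(inherits(matrix, "gene_hit_matrix"))
  n <- length(matrix$fathers)
  if (!is_count(k, min = 1) || k > n) {
    stop("k must be an integer in 1..", n, call. = FALSE)
  }
  per_gene <- table(unique(matrix$hits[, c("gene_id", "father_id")])$gene_id)
  sort(names(per_gene)[per_gene >= k])
}

# gene -> single region label under precedence promoter > CDS
gene_classes <- function(matrix, genes) {
  h <- matrix$hits[matrix$hits$gene_id %in% genes, , drop = FALSE]
  vapply(genes, function(g) {
    cl <- h$class[h$gene_id == g]
    if ("promoter" %in% cl) "promoter" else if ("CDS" %in% cl) "CDS" else NA_character_
  }, character(1))
}

#' Construct a Venn result object
#'
#' @param a_only,b_only,shared Disjoint character vectors of gene ids.
#' @param shared_classes Optional tibble (`gene_id`, `class`) giving the
#'   region class of each shared gene.
#' @param labels Length-2 character vector naming the two experiments.
#' @return An object of class `venn_result`.
#' @export
venn_result <- function(a_only, b_only, shared, shared_classes = NULL,
                        labels = c("A", "B")) {
  if (length(intersect(a_only, b_only)) > 0 ||
      length(intersect(a_only, shared)) > 0 ||
      length(intersect(b_only, shared)) > 0) {
    stop("venn sets must be disjoint", call. = FALSE)
  }
  structure(
    list(
      labels = labels,
      a_only = sort(unique(a_only)),
      b_only = sort(unique(b_only)),
      shared = sort(unique(shared)),
      shared_classes = shared_classes
    ),
    class = "venn_result"
  )
}

#' Cross-factor comparison of affected gene sets
#'
#' Splits the gene sets of two environmental-factor experiments into
#' factor-specific and shared genes (the gene-level Venn of the two
#' replication-filtered lists). Region classes for shared genes, when hit
#' matrices are supplied, are assigned under the precedence
#' promoter > CDS over the union of both experiments' hits.
#'
#' @param genes_a,genes_b Character vectors of gene ids (e.g. from
#'   [replication_filter()]).
#' @param matrix_a,matrix_b Optional [gene_hit_matrix()] objects used to
#'   attach region classes to shared genes.
#' @param labels Experiment labels.
#' @return A [venn_result()].
#' @export
cross_factor_venn <- function(genes_a, genes_b, matrix_a = NULL, matrix_b = NULL,
                              labels = c("A", "B")) {
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  shared <- sort(intersect(genes_a, genes_b))
  shared_classes <- NULL
  if (!is.null(matrix_a) && !is.null(matrix_b) && length(shared) > 0) {
    cls_a <- gene_classes(matrix_a, shared)
    cls_b <- gene_classes(matrix_b, shared)
    cls <- ifelse(
      cls_a == "promoter" | cls_b == "promoter", "promoter",
      ifelse(!is.na(cls_a), cls_a, cls_b)
    )
    shared_classes <- tibble::tibble(gene_id = shared, class = unname(cls))
  }
  venn_result(
    a_only = setdiff(genes_a, genes_b),
    b_only = setdiff(genes_b, genes_a),
    shared = shared,
    shared_classes = shared_classes,
    labels = labels
  )
}

#' Tally shared genes by regulatory region class
#'
#' Counts the shared genes of a Venn result by region class under the
#' precedence promoter > CDS; genes without a class are counted as
#' `unknown` with a warning.
#'
#' @param venn A [venn_result()] whose shared genes carry region classes.
#' @return Named integer vector with elements `shared`, `promoter`, `CDS`
#'   and `unknown`.
#' @export
classify_shared <- function(venn) {
  stopifnot(inherits(venn, "venn_result"))
  n_shared <- length(venn$shared)
  if (n_shared == 0) {
    return(c(shared = 0L, promoter = 0L, CDS = 0L, unknown = 0L))
  }
  sc <- venn$shared_classes
  cls <- rep(NA_character_, n_shared)
  if (!is.null(sc)) {
    cls <- tolower(sc$class[match(venn$shared, sc$gene_id)])
  }
  unknown <- sum(is.na(cls) | !(cls %in% c("promoter", "cds")))
  if (unknown > 0) {
    warning(unknown, " shared gene(s) without region class counted as unknown",
      call. = FALSE
    )
  }
  c(
    shared = n_shared,
    promoter = sum(cls == "promoter", na.rm = TRUE),
    CDS = sum(cls == "cds", na.rm = TRUE),
    unknown = as.integer(unknown)
  )
}

#' @export
print.venn_result <- function(x, ...) {
  cat(
    "Cross-factor gene sets (", x$labels[1], " vs ", x$labels[2], ")\n",
    "  ", x$labels[1], " only: ", length(x$a_only), " genes\n",
    "  ", x$labels[2], " only: ", length(x$b_only), " genes\n",
    "  shared:  ", length(x$shared), " genes\n",
    sep = ""
  )
  invisible(x)
}
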