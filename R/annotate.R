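#' Derive promoter intervals from gene features
#'
#' The promoter of a gene is a fixed window around its transcription start
#' site: `[TSS - upstream, TSS + downstream)` for a gene on the + strand,
#' mirrored for the - strand (the TSS is then the gene's end coordinate).
#' Windows are clipped at position 0 and, when the feature set carries a
#' `chrom_length` attribute, at the chromosome end.
#'
#' @param features A feature-set tibble containing `gene` rows with strand.
#' @param upstream,downstream Window extent in bp. Defaults 2000 and 500.
#' @return A feature-set tibble of promoter intervals (class `"promoter"`),
#'   one per gene.
#' @export
define_promoters <- function(features, upstream = 2000, downstream = 500) {
  genes <- features[features$class == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("genes must carry strand (+/-)", call. = FALSE)
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start - upstream, genes$end - downstream)
  end <- ifelse(plus, genes$start + downstream, genes$end + upstream)
  start <- pmax(start, 0)
  chrom_length <- attr(features, "chrom_length")
  if (!is.null(chrom_length)) end <- pmin(end, chrom_length)
  out <- tibble::tibble(
    chrom = genes$chrom,
    start = as.integer(start),
    end = as.integer(end),
    strand = genes$strand,
    gene_id = genes$gene_id,
    class = "promoter"
  )
  attr(out, "chrom_length") <- chrom_length
  out
}

#' Annotate DMRs with overlapping genomic features
#'
#' A DMR hits a feature when their intervals share at least 1 bp under
#' 0-based half-open semantics. All promoter, CDS and CpG-island hits are
#' reported; for single-label summaries the precedence is
#' promoter > CDS > CGI. A DMR overlapping features of two genes is
#' attributed to both.
#'
#' @param dmrs A DMR tibble from [call_dmrs()].
#' @param features A feature-set tibble; only rows of class `promoter`,
#'   `CDS` or `CGI` take part in annotation.
#' @return The DMR tibble with three added columns: `annotated` (any hit),
#'   `top_class` (highest-precedence class hit, `NA` if none) and `hits`
#'   (list column of tibbles with `gene_id` and `class` per hit).
#' @export
annotate_dmrs <- function(dmrs, features) {
  ann <- features[features$class %in% c("promoter", "CDS", "CGI"), , drop = FALSE]
  hits_per_dmr <- rep(list(tibble::tibble(
    gene_id = character(), class = character()
  )), nrow(dmrs))
  if (nrow(dmrs) > 0 && nrow(ann) > 0) {
    gr_d <- GenomicRanges::GRanges(
      dmrs$chrom, IRanges::IRanges(start = dmrs$start + 1L, end = dmrs$end)
    )
    gr_f <- GenomicRanges::GRanges(
      ann$chrom, IRanges::IRanges(start = ann$start + 1L, end = ann$end)
    )
    ov <- GenomicRanges::findOverlaps(gr_d, gr_f)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (i in unique(qh)) {
      f <- ann[sh[qh == i], , drop = FALSE]
      hits_per_dmr[[i]] <- dplyr::distinct(
        tibble::tibble(gene_id = f$gene_id, class = f$class)
      )
    }
  }
  top <- vapply(hits_per_dmr, function(h) {
    if (nrow(h) == 0) return(NA_character_)
    for (cl in c("promoter", "CDS", "CGI")) {
      if (cl %in% h$class) return(cl)
    }
    NA_character_
  }, character(1))
  out <- tibble::as_tibble(dmrs)
  out$annotated <- vapply(hits_per_dmr, nrow, integer(1)) > 0
  out$top_class <- top
  out$hits <- hits_per_dmr
  out
}

#' Gene-level hits per father comparison
#'
#' Flattens annotated DMRs of several father-sorted comparisons into the
#' gene-by-father hit structure used by the replication filter: one row per
#' (gene, father, region class). Only promoter and CDS hits attribute a DMR
#' to a gene (CpG islands carry no gene), and hypo-/hypermethylated DMRs are
#' pooled, since downstream gene sets ignore direction.
#'
#' @param annotated_by_father Named list (father id -> annotated DMR tibble
#'   from [annotate_dmrs()]).
#' @return An object of class `gene_hit_matrix`: list with `hits` (tibble
#'   `gene_id`, `father_id`, `class`) and `fathers` (character vector).
#' @export
gene_hit_matrix <- function(annotated_by_father) {
  stopifnot(is.list(annotated_by_father), !is.null(names(annotated_by_father)))
  rows <- lapply(names(annotated_by_father), function(f) {
    a <- annotated_by_father[[f]]
    if (nrow(a) == 0) {
      return(tibble::tibble(
        gene_id = character(), father_id = character(), class = character()
      ))
    }
    h <- dplyr::bind_rows(a$hits)
    h <- h[!is.na(h$gene_id) & h$class %in% c("promoter", "CDS"), , drop = FALSE]
    if (nrow(h) == 0) {
      return(tibble::tibble(
        gene_id = character(), father_id = character(), class = character()
      ))
    }
    tibble::tibble(gene_id = h$gene_id, father_id = f, class = h$class)
  })
  structure(
    list(
      hits = dplyr::distinct(dplyr::bind_rows(rows)),
      fathers = names(annotated_by_father)
    ),
    class = "gene_hit_matrix"
  )
}
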