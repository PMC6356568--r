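#' Read a bisulfite coverage file into a methylome table
#'
#' Parses the Bismark-coverage text dialect: six tab-separated columns
#' (chromosome, start, end, methylation percentage, methylated count,
#' unmethylated count) with 1-based inclusive coordinates on disk. Internally
#' all positions are 0-based, so a site at disk coordinate 101 becomes
#' `pos = 100`. Counts are authoritative: the percentage column is recomputed
#' from the counts and, when it disagrees by more than 0.5, a warning is
#' emitted and the counts win. Sites with zero total coverage are dropped
#' with a warning.
#'
#' @param path Path to a coverage file.
#' @param sample_id Sample identifier attached to the table; defaults to the
#'   file name without extension.
#' @return A methylome table: a tibble with columns `chrom`, `pos` (0-based),
#'   `count_meth`, `count_unmeth`, sorted by (chrom, pos), carrying a
#'   `sample_id` attribute.
#' @seealso [write_coverage()]
#' @export
read_coverage <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("coverage file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "pct", "count_meth", "count_unmeth"),
    col_types = "ciidii",
    progress = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop(
      "malformed coverage line ", probs$row[1], " in ", path, ": ",
      probs$expected[1], " vs ", probs$actual[1],
      call. = FALSE
    )
  }
  bad <- which(is.na(raw$start) | is.na(raw$count_meth) | is.na(raw$count_unmeth))
  if (length(bad) > 0) {
    stop("malformed coverage line ", bad[1], " in ", path, call. = FALSE)
  }
  cov <- raw$count_meth + raw$count_unmeth
  zero <- cov == 0
  if (any(zero)) {
    warning(sum(zero), " zero-coverage site(s) dropped", call. = FALSE)
  }
  recomputed <- ifelse(cov > 0, 100 * raw$count_meth / cov, NA_real_)
  mismatch <- !zero & abs(recomputed - raw$pct) > 0.5
  if (any(mismatch)) {
    warning(
      sum(mismatch), " site(s) with percentage/count mismatch > 0.5; counts win",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    chrom = raw$chrom[!zero],
    pos = raw$start[!zero] - 1L,
    count_meth = raw$count_meth[!zero],
    count_unmeth = raw$count_unmeth[!zero]
  )
  methylome_table(out, sample_id)
}

#' Write a methylome table as a bisulfite coverage file
#'
#' Inverse of [read_coverage()]: internal 0-based positions are written as
#' 1-based inclusive start/end, and the percentage column is derived from the
#' counts.
#'
#' @param methylome A methylome table (see [read_coverage()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(methylome, path) {
  stopifnot(is.data.frame(methylome))
  cov <- methylome$count_meth + methylome$count_unmeth
  out <- data.frame(
    chrom = methylome$chrom,
    start = methylome$pos + 1L,
    end = methylome$pos + 1L,
    pct = formatC(100 * methylome$count_meth / cov, format = "f", digits = 6),
    count_meth = methylome$count_meth,
    count_unmeth = methylome$count_unmeth
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# canonicalise + validate a methylome table
methylome_table <- function(df, sample_id = NULL) {
  stopifnot(all(c("chrom", "pos", "count_meth", "count_unmeth") %in% names(df)))
  if (any(df$pos < 0)) stop("negative position in methylome table", call. = FALSE)
  if (any(df$count_meth < 0 | df$count_unmeth < 0)) {
    stop("negative count in methylome table", call. = FALSE)
  }
  df <- dplyr::arrange(tibble::as_tibble(df), .data$chrom, .data$pos)
  if (anyDuplicated(df[, c("chrom", "pos")]) > 0) {
    stop("duplicate positions in methylome table", call. = FALSE)
  }
  if (!is.null(sample_id)) attr(df, "sample_id") <- sample_id
  df
}

#' Read genomic features (genes, CDS, promoters, CpG islands)
#'
#' Reads a BED6 or GFF3 file into a feature set: a tibble of strand-aware,
#' 0-based half-open intervals with columns `chrom`, `start`, `end`,
#' `strand`, `gene_id`, `class`. In BED input the name field carries
#' `gene_id|class` (as written by [write_features()]); a bare name is taken
#' as a gene identifier with class `"gene"`. In GFF3 input, `gene` rows map
#' to class `"gene"` (identifier from the `ID` attribute) and `CDS` rows to
#' class `"CDS"` (identifier from `Parent`); rows of any other type are
#' skipped with a warning. CpG islands carry `NA` as gene identifier.
#'
#' @param path Path to the annotation file.
#' @param kind `"bed"` or `"gff"`.
#' @return A feature-set tibble.
#' @export
read_features <- function(path, kind = c("bed", "gff")) {
  kind <- match.arg(tolower(kind), c("bed", "gff"))
  if (kind == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
    has_class <- grepl("|", nm, fixed = TRUE)
    gene_id <- ifelse(has_class, sub("\\|.*$", "", nm), nm)
    class <- ifelse(has_class, sub("^.*\\|", "", nm), "gene")
    out <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      gene_id = ifelse(gene_id == "." | gene_id == "", NA_character_, gene_id),
      class = class
    )
  } else {
    g <- rtracklayer::readGFF(path)
    type <- as.character(g$type)
    keep <- type %in% c("gene", "CDS")
    if (any(!keep)) {
      warning(
        "skipping ", sum(!keep), " feature(s) of unknown class: ",
        paste(unique(type[!keep]), collapse = ", "),
        call. = FALSE
      )
    }
    g <- g[keep, , drop = FALSE]
    type <- type[keep]
    parent <- vapply(
      g$Parent,
      function(p) if (length(p) > 0) as.character(p[[1]]) else NA_character_,
      character(1)
    )
    gene_id <- ifelse(type == "gene", as.character(g$ID), parent)
    out <- tibble::tibble(
      chrom = as.character(g$seqid),
      start = as.integer(g$start) - 1L,
      end = as.integer(g$end),
      strand = as.character(g$strand),
      gene_id = gene_id,
      class = type
    )
  }
  validate_features(out)
}

#' Write a feature set as BED6
#'
#' The BED name field encodes `gene_id|class` so that [read_features()] can
#' round-trip class information; coordinates are written 0-based half-open
#' as BED requires.
#'
#' @param features A feature-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  features <- validate_features(features)
  name <- paste0(
    ifelse(is.na(features$gene_id), ".", features$gene_id),
    "|", features$class
  )
  out <- data.frame(
    chrom = features$chrom,
    start = features$start,
    end = features$end,
    name = name,
    score = 0L,
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, ".")
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

validate_features <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id", "class") %in% names(df)))
  if (any(df$end <= df$start)) stop("feature with end <= start", call. = FALSE)
  genes <- df$gene_id[df$class == "gene"]
  linked <- df$class %in% c("CDS", "promoter")
  if (any(linked) && length(genes) > 0 && !all(df$gene_id[linked] %in% genes)) {
    stop("CDS/promoter feature references a gene absent from the set", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read or write a sample design table
#'
#' The design table maps samples to the pedigree/treatment structure: one
#' row per sample with columns `sample_id`, `father_id`, `condition`
#' (`control` or `treated`) and `experiment`. Every father must have at
#' least one control and one treated sample.
#'
#' @param path Path to a tab-separated design table with a header line.
#' @return A tibble with the four design columns.
#' @export
read_design_table <- function(path) {
  d <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  validate_design(d)
}

#' @rdname read_design_table
#' @param design A design tibble.
#' @export
write_design_table <- function(design, path) {
  validate_design(design)
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

validate_design <- function(d) {
  stopifnot(all(c("sample_id", "father_id", "condition", "experiment") %in% names(d)))
  if (!all(d$condition %in% c("control", "treated"))) {
    stop("condition must be 'control' or 'treated'", call. = FALSE)
  }
  both <- tapply(d$condition, d$father_id, function(x) {
    all(c("control", "treated") %in% x)
  })
  if (!all(both)) {
    stop(
      "father(s) without both control and treated samples: ",
      paste(names(both)[!both], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(d)
}

#' Write called DMRs as BED6+ text
#'
#' Columns: chrom, start, end, name (`father:index`), score
#' (`round(1000 * |mean_diff|)`), strand (`.`), then `n_cpgs`, `mean_diff`,
#' `p_value`, `q_value`, `direction`.
#'
#' @param dmrs A DMR tibble from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  father <- if ("father_id" %in% names(dmrs)) dmrs$father_id else "NA"
  out <- data.frame(
    chrom = dmrs$chrom,
    start = dmrs$start,
    end = dmrs$end,
    name = paste0(father, ":", seq_len(nrow(dmrs))),
    score = round(1000 * abs(dmrs$mean_diff)),
    strand = ".",
    n_cpgs = dmrs$n_cpgs,
    mean_diff = dmrs$mean_diff,
    p_value = dmrs$p_value,
    q_value = dmrs$q_value,
    direction = dmrs$direction
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read or write a protein interaction table
#'
#' Three tab-separated columns without header: `gene_a`, `gene_b`,
#' `combined_score` in \[0, 1\]. Edges are undirected: pairs are stored once
#' under canonical (alphabetical) ordering, duplicates are collapsed keeping
#' the maximum score, and self-edges are dropped with a warning.
#'
#' @param path Path to the interaction file.
#' @return A tibble with columns `gene_a`, `gene_b`, `combined_score`.
#' @export
read_interactions <- function(path) {
  d <- readr::read_tsv(
    path,
    col_names = c("gene_a", "gene_b", "combined_score"),
    col_types = "ccd",
    progress = FALSE
  )
  interaction_table(d)
}

#' @rdname read_interactions
#' @param interactions An interaction tibble.
#' @export
write_interactions <- function(interactions, path) {
  readr::write_tsv(interactions, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# canonicalise an interaction table: undirected, deduplicated, no self-edges
interaction_table <- function(d) {
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(d)))
  if (any(d$combined_score < 0 | d$combined_score > 1)) {
    stop("combined_score outside [0, 1]", call. = FALSE)
  }
  self <- d$gene_a == d$gene_b
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped", call. = FALSE)
    d <- d[!self, , drop = FALSE]
  }
  a <- pmin(d$gene_a, d$gene_b)
  b <- pmax(d$gene_a, d$gene_b)
  out <- tibble::tibble(gene_a = a, gene_b = b, combined_score = d$combined_score)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$gene_a, .data$gene_b),
    combined_score = max(.data$combined_score),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

#' Packaged table of shared diet/heat differentially methylated genes
#'
#' Loads the packaged 21-gene table of genes whose methylation responded in
#' all father-sorted comparisons of both environmental-factor experiments
#' (low-protein diet and temperature increase), with the regulatory region
#' (CDS or promoter) each shared region fell in and whether the gene's
#' function is known.
#'
#' @return A tibble with columns `gene_id`, `ensembl_id`, `region`
#'   (`CDS`/`Promoter`) and `function_known` (`yes`/`no`).
#' @export
shared_gene_table <- function() {
  path <- system.file("extdata", "shared_genes.tsv", package = "sireDMR", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cccc", progress = FALSE)
}
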