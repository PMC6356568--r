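#' Simulation design for synthetic RRBS data
#'
#' Describes the pedigree/treatment structure emulated by
#' [simulate_methylomes()]: several sires, each with control offspring
#' (sired before the father's environmental exposure) and treated offspring
#' (sired after), either pooled by father and condition or kept as
#' individual samples. Regional methylation shifts of size `planted_effect`
#' are planted in promoters or CDS of `n_planted_genes` genes for treated
#' samples of carrier fathers.
#'
#' Defaults reflect the emulated study design: 5 fathers, 3 offspring per
#' side per father, mean coverage 30 reads per CpG, baseline methylation
#' 0.7, and a planted shift of magnitude 0.4 (negative, i.e.
#' hypomethylation, so that the shifted probability stays inside \[0, 1\]
#' at the default baseline; the pipeline pools hypo- and hypermethylated
#' regions, so the sign does not matter downstream).
#'
#' @param n_fathers Number of sires. Default 5.
#' @param n_offspring_control,n_offspring_treated Offspring per father per
#'   side. Default 3 each.
#' @param pooled Pool offspring counts by father and condition (one table
#'   per father x condition), as when DNA is pooled before sequencing;
#'   otherwise one table per individual offspring. Default `TRUE`.
#' @param mean_coverage Mean reads per CpG (Poisson, truncated at >= 1).
#'   Must be > 0. Default 30.
#' @param baseline_meth Background methylation probability. Default 0.7.
#' @param planted_effect Methylation-probability shift in planted regions
#'   of treated samples of carrier fathers; `baseline_meth + planted_effect`
#'   must lie in \[0, 1\]. Default -0.4.
#' @param n_planted_genes Number of genes carrying a planted region.
#'   Default 10. Ignored when `planted_genes` is given.
#' @param planted_genes Optional explicit gene ids to plant in (lets two
#'   simulated experiments share planted genes).
#' @param replication_pattern Logical matrix (planted genes x fathers):
#'   which fathers transmit each planted effect. Default: all fathers.
#' @param experiment Label written into the design table. Default "sim".
#' @param father_ids Father labels; default `LETTERS[1:n_fathers]`.
#' @param seed Integer seed; the generator is deterministic given the
#'   design.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_fathers = 5,
                       n_offspring_control = 3,
                       n_offspring_treated = 3,
                       pooled = TRUE,
                       mean_coverage = 30,
                       baseline_meth = 0.7,
                       planted_effect = -0.4,
                       n_planted_genes = 10,
                       planted_genes = NULL,
                       replication_pattern = NULL,
                       experiment = "sim",
                       father_ids = NULL,
                       seed = 1) {
  stopifnot(
    is_count(n_fathers, min = 1),
    is_count(n_offspring_control, min = 1),
    is_count(n_offspring_treated, min = 1),
    is.logical(pooled), length(pooled) == 1L,
    is.numeric(mean_coverage), length(mean_coverage) == 1L,
    is_prob(baseline_meth),
    is.numeric(planted_effect), length(planted_effect) == 1L,
    planted_effect >= -1, planted_effect <= 1,
    is_count(n_planted_genes, min = 0)
  )
  if (mean_coverage <= 0) {
    stop("mean_coverage must be > 0", call. = FALSE)
  }
  shifted <- baseline_meth + planted_effect
  if (shifted < 0 || shifted > 1) {
    stop("baseline_meth + planted_effect must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(father_ids)) father_ids <- LETTERS[seq_len(n_fathers)]
  stopifnot(length(father_ids) == n_fathers)
  if (!is.null(planted_genes)) n_planted_genes <- length(planted_genes)
  if (is.null(replication_pattern)) {
    replication_pattern <- matrix(
      TRUE, nrow = n_planted_genes, ncol = n_fathers
    )
  }
  if (n_planted_genes > 0) {
    stopifnot(
      is.logical(replication_pattern),
      nrow(replication_pattern) == n_planted_genes,
      ncol(replication_pattern) == n_fathers
    )
  }
  structure(
    list(
      n_fathers = as.integer(n_fathers),
      n_offspring_control = as.integer(n_offspring_control),
      n_offspring_treated = as.integer(n_offspring_treated),
      pooled = pooled,
      mean_coverage = mean_coverage,
      baseline_meth = baseline_meth,
      planted_effect = planted_effect,
      n_planted_genes = as.integer(n_planted_genes),
      planted_genes = planted_genes,
      replication_pattern = replication_pattern,
      experiment = experiment,
      father_ids = father_ids,
      seed = as.integer(seed)
    ),
    class = "sim_design"
  )
}

#' Simulate a gene annotation on one synthetic chromosome
#'
#' Places `n_genes` non-overlapping, strand-assigned genes on a chromosome
#' of length `chrom_length`, each with one or two CDS exons inside the gene
#' body, a promoter window derived by [define_promoters()], and (for ~70%
#' of genes) a CpG island around the transcription start site. Deterministic
#' for a fixed seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param chrom_length Chromosome length in bp.
#' @param seed Integer seed.
#' @param chrom Chromosome name. Default "chr1".
#' @param gene_length Length-2 range genes are drawn from. Default
#'   1500-4000 bp.
#' @param min_gap Minimum gap between consecutive genes. Default 2600 bp
#'   (room for a full upstream promoter window).
#' @param cgi_prob Probability a gene gets a CpG island. Default 0.7.
#' @return A feature-set tibble (classes `gene`, `CDS`, `promoter`, `CGI`)
#'   with a `chrom_length` attribute.
#' @export
simulate_annotation <- function(n_genes, chrom_length, seed = 1,
                                chrom = "chr1",
                                gene_length = c(1500, 4000),
                                min_gap = 2600, cgi_prob = 0.7) {
  if (!is_count(n_genes, min = 1)) stop("n_genes must be >= 1", call. = FALSE)
  stopifnot(is_count(chrom_length, min = 1))
  with_seed(seed, {
    len <- sample(seq(gene_length[1], gene_length[2]), n_genes, replace = TRUE)
    need <- sum(len) + (n_genes + 1L) * min_gap
    if (need > chrom_length) {
      stop(
        "cannot place ", n_genes, " non-overlapping genes in ",
        chrom_length, " bp (need >= ", need, ")",
        call. = FALSE
      )
    }
    # distribute the slack over the n_genes + 1 gaps
    slack <- chrom_length - need
    w <- runif(n_genes + 1L)
    extra <- floor(slack * w / sum(w))
    gaps <- min_gap + extra
    starts <- cumsum(gaps[seq_len(n_genes)]) + cumsum(c(0L, head(len, -1L)))
    ends <- starts + len
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_id <- sprintf("gene%03d", seq_len(n_genes))
    genes <- tibble::tibble(
      chrom = chrom, start = as.integer(starts), end = as.integer(ends),
      strand = strand, gene_id = gene_id, class = "gene"
    )
    cds <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      # CDS occupies the gene body downstream of the promoter window's
      # 500 bp overhang, as one or two exons
      body_start <- starts[i] + max(600L, round(0.15 * len[i]))
      body_end <- ends[i] - round(0.1 * len[i])
      if (sample(1:2, 1) == 1L) {
        es <- body_start
        ee <- body_end
      } else {
        mid <- floor((body_start + body_end) / 2)
        es <- c(body_start, mid + 100L)
        ee <- c(mid - 100L, body_end)
      }
      data.frame(
        chrom = chrom, start = as.integer(es), end = as.integer(ee),
        strand = strand[i], gene_id = gene_id[i], class = "CDS"
      )
    }))
    cds <- cds[cds$end > cds$start, , drop = FALSE]
    tss <- ifelse(strand == "+", starts, ends)
    has_cgi <- runif(n_genes) < cgi_prob
    cgi <- tibble::tibble(
      chrom = chrom,
      start = as.integer(pmax(tss[has_cgi] - 300L, 0L)),
      end = as.integer(pmin(tss[has_cgi] + 300L, chrom_length)),
      strand = "*", gene_id = NA_character_, class = "CGI"
    )
    features <- dplyr::bind_rows(genes, tibble::as_tibble(cds), cgi)
    attr(features, "chrom_length") <- as.integer(chrom_length)
    promoters <- define_promoters(features)
    out <- dplyr::bind_rows(features, promoters)
    attr(out, "chrom_length") <- as.integer(chrom_length)
    validate_features(out)
  })
}

# CpG coordinate grid: dense fixed-step sites inside promoters and CDS
# (mimicking RRBS enrichment of CpG-rich regions) plus a sparse background
# grid across the chromosome.
cpg_grid <- function(features, dense_step = 25L, background_step = 500L) {
  chrom <- features$chrom[1]
  chrom_length <- attr(features, "chrom_length")
  if (is.null(chrom_length)) chrom_length <- max(features$end)
  dense <- features[features$class %in% c("promoter", "CDS"), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(dense)), function(i) {
    seq(dense$start[i], dense$end[i] - 1L, by = dense_step)
  }))
  pos <- c(pos, seq(0L, chrom_length - 1L, by = background_step))
  sort(unique(as.integer(pos[pos >= 0 & pos < chrom_length])))
}

#' Simulate RRBS methylomes with planted regional shifts
#'
#' Generates per-sample CpG count tables on a common coordinate grid
#' (dense inside promoters/CDS, sparse background). At each CpG, each
#' offspring's coverage is Poisson(`mean_coverage`) truncated at >= 1 and
#' its methylated count Binomial(coverage, p), with p = `baseline_meth`
#' everywhere except inside planted regions for treated offspring of
#' carrier fathers, where p = `baseline_meth + planted_effect`. Planted
#' regions are whole promoter or CDS intervals of randomly chosen genes
#' (the unit of inference is the region). With `pooled = TRUE`, offspring
#' counts are summed per father and condition.
#'
#' @param design A [sim_design()].
#' @param features A feature set from [simulate_annotation()].
#' @param dense_step,background_step CpG grid spacing in bp inside
#'   promoters/CDS and elsewhere. Defaults 25 and 500.
#' @return A list with `methylomes` (named list of methylome tables),
#'   `design_table` (sample design tibble), and `truth` (tibble of planted
#'   regions: `gene_id`, `chrom`, `start`, `end`, `class`, `effect`, and a
#'   comma-separated `carriers` column).
#' @export
simulate_methylomes <- function(design, features,
                                dense_step = 25L, background_step = 500L) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    pos <- cpg_grid(features, dense_step, background_step)
    n_sites <- length(pos)
    chrom <- features$chrom[1]

    # planted regions: whole promoter or (first) CDS interval per gene
    genes_all <- features$gene_id[features$class == "gene"]
    if (!is.null(design$planted_genes)) {
      stopifnot(all(design$planted_genes %in% genes_all))
      planted_genes <- design$planted_genes
    } else {
      planted_genes <- sort(sample(genes_all, design$n_planted_genes))
    }
    truth <- NULL
    shift <- rep(FALSE, n_sites)
    carrier_shift <- vector("list", design$n_fathers)
    for (f in seq_len(design$n_fathers)) carrier_shift[[f]] <- rep(FALSE, n_sites)
    if (length(planted_genes) > 0) {
      rows <- lapply(seq_along(planted_genes), function(i) {
        g <- planted_genes[i]
        cls <- sample(c("promoter", "CDS"), 1)
        cand <- features[features$class == cls & !is.na(features$gene_id) &
          features$gene_id == g, , drop = FALSE]
        cand[1, c("chrom", "start", "end", "class", "gene_id")]
      })
      truth <- dplyr::bind_rows(rows)
      truth$effect <- design$planted_effect
      truth$carriers <- vapply(seq_len(nrow(truth)), function(i) {
        paste(design$father_ids[design$replication_pattern[i, ]], collapse = ",")
      }, character(1))
      truth <- tibble::as_tibble(
        truth[, c("gene_id", "chrom", "start", "end", "class", "effect", "carriers")]
      )
      for (i in seq_len(nrow(truth))) {
        in_region <- pos >= truth$start[i] & pos < truth$end[i]
        for (f in seq_len(design$n_fathers)) {
          if (design$replication_pattern[i, f]) {
            carrier_shift[[f]] <- carrier_shift[[f]] | in_region
          }
        }
      }
    } else {
      truth <- tibble::tibble(
        gene_id = character(), chrom = character(), start = integer(),
        end = integer(), class = character(), effect = numeric(),
        carriers = character()
      )
    }

    draw_sample <- function(p_site) {
      # Poisson truncated at >= 1, sampled exactly via the quantile method
      cov <- stats::qpois(
        runif(n_sites, stats::ppois(0, design$mean_coverage), 1),
        design$mean_coverage
      )
      meth <- rbinom(n_sites, cov, p_site)
      tibble::tibble(
        chrom = chrom, pos = pos,
        count_meth = as.integer(meth),
        count_unmeth = as.integer(cov - meth)
      )
    }

    methylomes <- list()
    design_rows <- list()
    for (f in seq_len(design$n_fathers)) {
      fid <- design$father_ids[f]
      p_control <- rep(design$baseline_meth, n_sites)
      p_treated <- ifelse(
        carrier_shift[[f]],
        design$baseline_meth + design$planted_effect,
        design$baseline_meth
      )
      for (cond in c("control", "treated")) {
        n_off <- if (cond == "control") design$n_offspring_control else design$n_offspring_treated
        p_site <- if (cond == "control") p_control else p_treated
        offspring <- lapply(seq_len(n_off), function(i) draw_sample(p_site))
        if (design$pooled) {
          sid <- sprintf("%s_%s_pool", fid, cond)
          pooled <- offspring[[1]]
          if (n_off > 1) {
            for (i in 2:n_off) {
              pooled$count_meth <- pooled$count_meth + offspring[[i]]$count_meth
              pooled$count_unmeth <- pooled$count_unmeth + offspring[[i]]$count_unmeth
            }
          }
          methylomes[[sid]] <- methylome_table(pooled, sid)
          design_rows[[length(design_rows) + 1L]] <- tibble::tibble(
            sample_id = sid, father_id = fid, condition = cond,
            experiment = design$experiment
          )
        } else {
          for (i in seq_len(n_off)) {
            sid <- sprintf("%s_%s_%d", fid, cond, i)
            methylomes[[sid]] <- methylome_table(offspring[[i]], sid)
            design_rows[[length(design_rows) + 1L]] <- tibble::tibble(
              sample_id = sid, father_id = fid, condition = cond,
              experiment = design$experiment
            )
          }
        }
      }
    }
    list(
      methylomes = methylomes,
      design_table = validate_design(dplyr::bind_rows(design_rows)),
      truth = truth
    )
  })
}

#' Write planted ground truth as BED
#'
#' Planted regions are written as BED6 with the effect sign in the score
#' column (+1/-1) and the carrier fathers appended to the name.
#'
#' @param truth The `truth` tibble from [simulate_methylomes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- data.frame(
    chrom = truth$chrom,
    start = truth$start,
    end = truth$end,
    name = paste0(truth$gene_id, ":", truth$class, ":", truth$carriers),
    score = sign(truth$effect),
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Simulate a protein interaction table
#'
#' Random undirected graph over `n_genes` gene symbols with `n_edges`
#' distinct edges and uniform combined scores, optionally with a fully
#' connected planted module at a fixed high score — the positive control
#' for [enrichment_test()].
#'
#' @param n_genes Universe size.
#' @param n_edges Number of random background edges.
#' @param seed Integer seed.
#' @param score_range Range background scores are drawn from. Default
#'   c(0.15, 0.95).
#' @param planted_genes Optional character vector forming a clique.
#' @param planted_score Score of clique edges. Default 0.9.
#' @return An interaction tibble (see [read_interactions()]).
#' @export
simulate_interaction_table <- function(n_genes, n_edges, seed = 1,
                                       score_range = c(0.15, 0.95),
                                       planted_genes = NULL,
                                       planted_score = 0.9) {
  stopifnot(is_count(n_genes, min = 2), is_count(n_edges, min = 0))
  with_seed(seed, {
    universe <- sprintf("g%04d", seq_len(n_genes))
    max_edges <- n_genes * (n_genes - 1) / 2
    stopifnot(n_edges <= max_edges)
    idx <- sample.int(max_edges, n_edges)
    # map linear index to (i, j), i < j
    i <- ceiling((sqrt(8 * idx + 1) - 1) / 2)
    j <- idx - i * (i - 1) / 2
    edges <- tibble::tibble(
      gene_a = universe[j],
      gene_b = universe[i + 1L],
      combined_score = runif(n_edges, score_range[1], score_range[2])
    )
    if (!is.null(planted_genes)) {
      stopifnot(all(planted_genes %in% universe))
      pairs <- utils::combn(sort(planted_genes), 2)
      clique <- tibble::tibble(
        gene_a = pairs[1, ], gene_b = pairs[2, ],
        combined_score = planted_score
      )
      edges <- dplyr::bind_rows(edges, clique)
    }
    interaction_table(edges)
  })
}
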