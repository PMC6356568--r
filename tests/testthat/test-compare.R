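# build a gene_hit_matrix directly from a logical gene x father matrix
matrix_from_bool <- function(m, fathers = LETTERS[seq_len(ncol(m))],
                             class = "CDS") {
  hits <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    f <- fathers[m[i, ]]
    if (length(f) == 0) return(NULL)
    data.frame(gene_id = rownames(m)[i], father_id = f, class = class)
  }))
  if (is.null(hits)) {
    hits <- data.frame(
      gene_id = character(), father_id = character(), class = character()
    )
  }
  structure(
    list(hits = tibble::as_tibble(hits), fathers = fathers),
    class = "gene_hit_matrix"
  )
}

test_that("the replication filter equals a brute-force row-sum filter", {
  set.seed(5)
  m <- matrix(runif(250) < 0.4, nrow = 50, ncol = 5,
              dimnames = list(sprintf("gene%02d", 1:50), NULL))
  ghm <- matrix_from_bool(m)
  for (k in 1:5) {
    want <- sort(rownames(m)[rowSums(m) >= k])
    expect_equal(replication_filter(ghm, k), want)
  }
  # degenerate thresholds: union and intersection
  expect_equal(replication_filter(ghm, 1), sort(rownames(m)[rowSums(m) >= 1]))
  expect_equal(replication_filter(ghm, 5), sort(rownames(m)[rowSums(m) == 5]))
  expect_error(replication_filter(ghm, 0), "k must be")
  expect_error(replication_filter(ghm, 6), "k must be")

  # antitone in k
  for (k in 1:4) {
    expect_true(all(replication_filter(ghm, k + 1) %in% replication_filter(ghm, k)))
  }
})

test_that("cross-factor Venn sets partition the union", {
  a <- paste0("g", 1:10)
  same <- cross_factor_venn(a, a)
  expect_equal(same$shared, sort(a))
  expect_equal(length(same$a_only), 0)
  expect_equal(length(same$b_only), 0)

  disj <- cross_factor_venn(paste0("g", 1:5), paste0("h", 1:5))
  expect_equal(length(disj$shared), 0)

  set.seed(9)
  for (i in 1:20) {
    ga <- sample(paste0("g", 1:40), sample(5:30, 1))
    gb <- sample(paste0("g", 1:40), sample(5:30, 1))
    v <- cross_factor_venn(ga, gb)
    parts <- c(v$a_only, v$b_only, v$shared)
    expect_equal(sort(parts), sort(union(ga, gb)))  # partition, no dupes
    expect_lte(length(v$shared), min(length(unique(ga)), length(unique(gb))))
  }
})

test_that("shared genes take their region class with promoter precedence", {
  m_a <- matrix(TRUE, 3, 2, dimnames = list(c("g1", "g2", "g3"), NULL))
  ghm_a <- matrix_from_bool(m_a, fathers = c("A", "B"), class = "CDS")
  ghm_b <- matrix_from_bool(m_a, fathers = c("F", "G"), class = "CDS")
  # give g2 a promoter hit on the B side: precedence must pick promoter
  ghm_b$hits$class[ghm_b$hits$gene_id == "g2"] <- "promoter"
  v <- cross_factor_venn(c("g1", "g2", "g3"), c("g1", "g2", "g3"),
                         matrix_a = ghm_a, matrix_b = ghm_b)
  tally <- classify_shared(v)
  expect_equal(unname(tally["shared"]), 3L)
  expect_equal(unname(tally["promoter"]), 1L)
  expect_equal(unname(tally["CDS"]), 2L)
  expect_equal(unname(tally["unknown"]), 0L)
  # conservation
  expect_equal(
    unname(tally["shared"]),
    unname(tally["promoter"] + tally["CDS"] + tally["unknown"])
  )
})

test_that("unclassified shared genes are tallied as unknown with a warning", {
  v <- venn_result(character(0), character(0), c("g1", "g2"),
                   shared_classes = tibble::tibble(gene_id = "g1", class = "CDS"))
  expect_warning(tally <- classify_shared(v), "unknown")
  expect_equal(unname(tally["unknown"]), 1L)
  empty <- venn_result(character(0), character(0), character(0))
  expect_equal(unname(classify_shared(empty)["shared"]), 0L)
})

test_that("the packaged shared-gene table reproduces its printed totals", {
  tab <- shared_gene_table()
  v <- venn_result(
    character(0), character(0), tab$gene_id,
    shared_classes = tibble::tibble(gene_id = tab$gene_id, class = tab$region)
  )
  tally <- classify_shared(v)
  expect_equal(unname(tally["shared"]), 21L)
  expect_equal(unname(tally["CDS"]), 18L)
  expect_equal(unname(tally["promoter"]), 3L)
  expect_equal(sum(tab$function_known == "yes"), 20L)
})
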