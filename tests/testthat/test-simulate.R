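test_that("simulated annotation places non-overlapping strand-assigned genes", {
  one <- simulate_annotation(1, 10000, seed = 7)
  expect_equal(sum(one$class == "gene"), 1)
  expect_equal(sum(one$class == "promoter"), 1)
  expect_gte(sum(one$class == "CDS"), 1)
  expect_true(all(one$strand[one$class == "gene"] %in% c("+", "-")))

  expect_error(simulate_annotation(0, 10000), "n_genes")
  expect_error(simulate_annotation(50, 10000, seed = 1), "cannot place")

  feat <- simulate_annotation(50, 1e6, seed = 1)
  genes <- feat[feat$class == "gene", ]
  expect_equal(nrow(genes), 50)
  # brute-force O(n^2) overlap scan
  for (i in seq_len(49)) {
    for (j in (i + 1):50) {
      expect_true(
        genes$end[i] <= genes$start[j] || genes$end[j] <= genes$start[i]
      )
    }
  }
  # deterministic for fixed seed
  expect_identical(feat, simulate_annotation(50, 1e6, seed = 1))
})

test_that("simulated counts respect bounds, share one grid, and are reproducible", {
  sim <- small_simulation(seed = 4, n_fathers = 2)
  grids <- lapply(sim$methylomes, function(m) paste(m$chrom, m$pos))
  for (g in grids[-1]) expect_identical(g, grids[[1]])
  for (m in sim$methylomes) {
    expect_true(all(m$count_meth >= 0))
    expect_true(all(m$count_unmeth >= 0))
    expect_true(all(m$count_meth + m$count_unmeth >= 1))
  }
  sim2 <- small_simulation(seed = 4, n_fathers = 2)
  expect_identical(sim$methylomes, sim2$methylomes)

  # same seed + design -> byte-identical files on disk
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_coverage(sim$methylomes[[1]], f1)
  write_coverage(sim2$methylomes[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate designs are rejected", {
  expect_error(sim_design(mean_coverage = 0), "mean_coverage")
  expect_error(
    sim_design(baseline_meth = 0.7, planted_effect = 0.4),
    "\\[0, 1\\]"
  )
})

test_that("with no planted effect, treated and control ratios are exchangeable", {
  # distributional null: KS on pooled ratios should rarely reject at alpha 0.01
  rejections <- 0L
  for (seed in 1:20) {
    sim <- small_simulation(seed = seed, n_fathers = 1, n_genes = 6,
                            chrom_length = 1e5)
    ctrl <- sim$methylomes[["A_control_pool"]]
    trt <- sim$methylomes[["A_treated_pool"]]
    r_c <- ctrl$count_meth / (ctrl$count_meth + ctrl$count_unmeth)
    r_t <- trt$count_meth / (trt$count_meth + trt$count_unmeth)
    p <- suppressWarnings(stats::ks.test(r_c, r_t)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("planted regional shifts have the designed magnitude", {
  # law of large numbers: 10 pooled offspring per side at 30x coverage
  feat <- simulate_annotation(10, 1.5e5, seed = 2)
  genes <- sort(feat$gene_id[feat$class == "gene"])[1:4]
  design <- sim_design(
    n_fathers = 1, n_offspring_control = 10, n_offspring_treated = 10,
    baseline_meth = 0.3, planted_effect = 0.4,
    planted_genes = genes,
    replication_pattern = matrix(TRUE, 4, 1),
    seed = 9
  )
  sim <- simulate_methylomes(design, feat)
  ctrl <- sim$methylomes[["A_control_pool"]]
  trt <- sim$methylomes[["A_treated_pool"]]
  for (i in seq_len(nrow(sim$truth))) {
    inside <- ctrl$pos >= sim$truth$start[i] & ctrl$pos < sim$truth$end[i]
    r_c <- sum(ctrl$count_meth[inside]) /
      sum(ctrl$count_meth[inside] + ctrl$count_unmeth[inside])
    r_t <- sum(trt$count_meth[inside]) /
      sum(trt$count_meth[inside] + trt$count_unmeth[inside])
    expect_lt(abs((r_t - r_c) - 0.4), 0.05)
  }
})

test_that("null simulations produce no DMRs at default thresholds", {
  zero_runs <- 0L
  for (seed in 21:40) {
    sim <- small_simulation(seed = seed, n_fathers = 1, n_genes = 8,
                            chrom_length = 1.2e5)
    dm <- call_dmrs(
      sim$methylomes[["A_control_pool"]],
      sim$methylomes[["A_treated_pool"]]
    )
    if (nrow(dm) == 0) zero_runs <- zero_runs + 1L
  }
  expect_gte(zero_runs, 19L)
})

test_that("planted truth maps onto exactly one annotated gene feature", {
  sim <- small_simulation(
    seed = 5, planted_genes = c("gene002", "gene005"),
    replication_pattern = matrix(TRUE, 2, 5)
  )
  expect_equal(nrow(sim$truth), 2)
  for (i in seq_len(nrow(sim$truth))) {
    f <- sim$features
    match_rows <- f$class == sim$truth$class[i] &
      !is.na(f$gene_id) & f$gene_id == sim$truth$gene_id[i] &
      f$start <= sim$truth$start[i] & f$end >= sim$truth$end[i]
    expect_equal(sum(match_rows), 1)
  }
})
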