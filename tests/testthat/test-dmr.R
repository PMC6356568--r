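test_that("pooling sums counts and equals the coverage-weighted mean ratio", {
  a <- make_methylome(c(100, 200), c(3, 5), c(1, 5))
  b <- make_methylome(c(100, 300), c(2, 1), c(2, 9))
  pooled <- pool_counts(list(s1 = a, s2 = b), c("s1", "s2"))
  expect_equal(pooled$count_meth[pooled$pos == 100], 5L)
  expect_equal(pooled$count_unmeth[pooled$pos == 100], 3L)
  # union of sites, missing sample contributes 0/0
  expect_equal(sort(pooled$pos), c(100L, 200L, 300L))

  expect_equal(
    as.data.frame(pool_counts(list(s1 = a), "s1")),
    as.data.frame(a),
    ignore_attr = TRUE
  )
  expect_error(pool_counts(list(s1 = a), character(0)), "empty")

  # algebraic oracle on 100 random sites: pooled ratio is the
  # coverage-weighted mean of per-sample ratios
  set.seed(42)
  pos <- seq_len(100) * 10
  x <- make_methylome(pos, rbinom(100, 20, 0.4), rbinom(100, 20, 0.6) + 1)
  y <- make_methylome(pos, rbinom(100, 30, 0.2), rbinom(100, 30, 0.8) + 1)
  p <- pool_counts(list(x = x, y = y))
  cov_x <- x$count_meth + x$count_unmeth
  cov_y <- y$count_meth + y$count_unmeth
  r_x <- x$count_meth / cov_x
  r_y <- y$count_meth / cov_y
  expect_equal(
    p$count_meth / (p$count_meth + p$count_unmeth),
    (cov_x * r_x + cov_y * r_y) / (cov_x + cov_y)
  )
})

test_that("the site test agrees exactly with Fisher's exact test", {
  # frozen closed form: complete separation at 10 vs 10 reads
  expect_equal(site_test(10, 0, 0, 10), 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(site_test(10, 0, 0, 10), 1.082e-5, tolerance = 1e-3)
  expect_equal(site_test(7, 3, 7, 3), 1)
  expect_equal(site_test(5, 5, 5, 5), 1)

  set.seed(7)
  tab <- random_tables(200)
  expect_gte(nrow(tab), 150)
  got <- site_test(tab$mc, tab$uc, tab$mt, tab$ut)
  expect_equal(got, fisher_oracle(tab), tolerance = 1e-10)
})

test_that("identical groups yield no DMRs and disjoint grids error", {
  m <- make_methylome(seq(0, 990, by = 10), rep(5, 100), rep(5, 100))
  expect_equal(nrow(call_dmrs(m, m)), 0)
  other <- make_methylome(seq(5, 995, by = 10), rep(5, 100), rep(5, 100))
  expect_error(call_dmrs(m, other), "zero overlapping")
})

test_that("a planted region is recovered with correct direction and bounds", {
  # 40 sites spaced 50 bp; sites 11-20 carry a +0.4 shift at deep coverage
  pos <- seq(0, 39) * 50
  ctrl <- make_methylome(pos, rep(30, 40), rep(70, 40))
  meth_t <- rep(30, 40)
  meth_t[11:20] <- 70
  trt <- make_methylome(pos, meth_t, 100 - meth_t)
  dm <- call_dmrs(ctrl, trt, dmr_params(), father_id = "A")
  expect_equal(nrow(dm), 1)
  expect_equal(dm$direction, "hyper")
  expect_equal(dm$n_cpgs, 10L)
  expect_equal(dm$father_id, "A")
  # boundaries within one site spacing of the truth
  expect_lte(abs(dm$start - pos[11]), 50)
  expect_lte(abs(dm$end - (pos[20] + 1)), 50)
  expect_equal(dm$mean_diff, 0.4, tolerance = 1e-12)
  # sign invariant: mean_diff sign matches direction
  expect_true(all(sign(dm$mean_diff) == ifelse(dm$direction == "hyper", 1, -1)))
})

test_that("region merging matches the brute-force run-enumeration oracle", {
  params <- dmr_params()
  for (seed in 1:100) {
    stats <- random_stats(60, seed)
    got <- sireDMR:::segment_dmrs(stats, params)
    want <- brute_segment_oracle(stats, params)
    expect_equal(
      as.data.frame(got[, names(want)]),
      as.data.frame(want)
    )
  }
})

test_that("gap splitting respects max_gap around intervening non-significant sites", {
  # two significant 3-site clusters separated by > max_gap with one
  # non-significant site between them -> two DMRs
  pos <- c(0, 30, 60, 200, 400, 430, 460)
  ctrl <- make_methylome(pos, rep(10, 7), rep(90, 7))
  meth_t <- c(60, 60, 60, 10, 60, 60, 60)
  trt <- make_methylome(pos, meth_t, 100 - meth_t)
  dm <- call_dmrs(ctrl, trt, dmr_params(max_gap = 100))
  expect_equal(nrow(dm), 2)
  expect_equal(dm$n_cpgs, c(3L, 3L))
  # same data but a merging-wide gap -> one DMR
  dm_wide <- call_dmrs(ctrl, trt, dmr_params(max_gap = 400))
  expect_equal(nrow(dm_wide), 1)
  expect_equal(dm_wide$n_cpgs, 6L)
})

test_that("called DMRs never overlap and are invariant to input row order", {
  sim <- small_simulation(
    seed = 13, planted_genes = c("gene001", "gene004", "gene007"),
    replication_pattern = matrix(TRUE, 3, 5)
  )
  ctrl <- sim$methylomes[["A_control_pool"]]
  trt <- sim$methylomes[["A_treated_pool"]]
  dm <- call_dmrs(ctrl, trt)
  expect_gte(nrow(dm), 1)
  if (nrow(dm) > 1) {
    o <- order(dm$chrom, dm$start)
    dm_o <- dm[o, ]
    same_chrom <- dm_o$chrom[-1] == dm_o$chrom[-nrow(dm_o)]
    expect_true(all(!same_chrom | dm_o$start[-1] >= dm_o$end[-nrow(dm_o)]))
  }
  set.seed(1)
  shuf <- function(m) m[sample(nrow(m)), ]
  expect_equal(as.data.frame(call_dmrs(shuf(ctrl), shuf(trt))), as.data.frame(dm))
})

test_that("stricter thresholds never yield more DMRs", {
  for (seed in c(3, 14)) {
    sim <- small_simulation(
      seed = seed, planted_genes = c("gene002", "gene006"),
      replication_pattern = matrix(TRUE, 2, 5), planted_effect = -0.25
    )
    ctrl <- sim$methylomes[["B_control_pool"]]
    trt <- sim$methylomes[["B_treated_pool"]]
    base <- nrow(call_dmrs(ctrl, trt, dmr_params()))
    expect_lte(nrow(call_dmrs(ctrl, trt, dmr_params(min_cpgs = 6))), base)
    expect_lte(nrow(call_dmrs(ctrl, trt, dmr_params(min_diff = 0.2))), base)
    expect_lte(nrow(call_dmrs(ctrl, trt, dmr_params(min_cpgs = 10, min_diff = 0.3))), base)
  }
})
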