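test_that("p-value filter is strict and order-preserving", {
  tab <- make_table(3, pval = c(1e-6, 1e-4, 1e-5))
  kept <- filter_by_pvalue(tab, 1e-5)
  expect_equal(kept$records$variant_id, "rs001")   # exactly 1e-5 is excluded
  expect_equal(n_variants(filter_by_pvalue(tab, 1.0)), 3)
})

test_that("f_statistic matches (beta/se)^2 and the literal variant", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.5), 0)
  expect_equal(f_statistic(-0.3, 0.1), 9)            # sign-invariant
  expect_equal(f_statistic(0.1, 0.02), f_statistic(-0.1, 0.02))
  expect_equal(f_statistic(0.1, 0.02, literal = TRUE), 0.1 / 0.02^2)
})

test_that("F filter keeps the boundary (exclusion is F < min_f)", {
  tab <- make_table(3, beta = c(0.1, 0.06, 0.02 * sqrt(10)), se = 0.02)
  # F = 25, 9, exactly 10
  kept <- filter_by_f(tab, 10)
  expect_setequal(kept$records$variant_id, c("rs001", "rs003"))
  expect_equal(n_variants(filter_by_f(tab, 0)), 3)
})

test_that("ld_r2 lookup is symmetric with identity and independence defaults", {
  ld <- ld_pair_table(data.frame(variant_a = "rs1", variant_b = "rs2", r2 = 0.4))
  expect_equal(ld_r2(ld, "rs1", "rs2"), 0.4)
  expect_equal(ld_r2(ld, "rs2", "rs1"), 0.4)
  expect_equal(ld_r2(ld, "rs1", "rs1"), 1)
  expect_equal(ld_r2(ld, "rs1", "rs9"), 0)
  expect_error(ld_pair_table(data.frame(variant_a = "a", variant_b = "b",
                                        r2 = 1.2)), "r2")
})

test_that("ld_clump follows the greedy definition", {
  # two SNPs 1 kb apart in LD: only the smaller p-value survives
  tab <- make_table(2, pos = c(1000, 2000), pval = c(1e-8, 1e-6))
  ld <- ld_pair_table(data.frame(variant_a = "rs001", variant_b = "rs002",
                                 r2 = 0.5))
  expect_equal(ld_clump(tab, ld, 0.001, 10000)$records$variant_id, "rs001")

  # different chromosomes: window never spans them
  tab2 <- make_table(2, chrom = c("1", "2"), pos = c(1000, 2000),
                     pval = c(1e-8, 1e-6))
  expect_equal(n_variants(ld_clump(tab2, ld, 0.001, 10000)), 2)

  # pairwise independent: identity
  tab3 <- make_table(3, pval = c(1e-8, 1e-7, 1e-6))
  expect_equal(n_variants(ld_clump(tab3, ld_pair_table(), 0.001, 10000)), 3)
})

test_that("clumping is invariant to input row order", {
  set.seed(11)
  for (rep in 1:10) {
    rec <- make_records(8, pos = sample(seq(1000, 8000, by = 1000)),
                        pval = runif(8, 1e-9, 1e-5))
    prs <- t(utils::combn(rec$variant_id, 2))
    ld <- ld_pair_table(data.frame(variant_a = prs[, 1], variant_b = prs[, 2],
                                   r2 = sample(c(0, 0.3), nrow(prs),
                                               replace = TRUE)))
    a <- ld_clump(sumstats_table(rec), ld, 0.1, 10000)
    b <- ld_clump(sumstats_table(rec[sample(nrow(rec)), ]), ld, 0.1, 10000)
    expect_setequal(a$records$variant_id, b$records$variant_id)
  }
})

test_that("greedy clumping returns a maximal conflict-free subset (oracle)", {
  set.seed(23)
  for (rep in 1:15) {
    n <- 6
    rec <- make_records(n, chrom = sample(c("1", "2"), n, replace = TRUE),
                        pos = sample(1:20, n) * 1e6,
                        pval = round(runif(n, 1e-8, 1e-5), 12))
    prs <- t(utils::combn(rec$variant_id, 2))
    ld <- ld_pair_table(data.frame(variant_a = prs[, 1], variant_b = prs[, 2],
                                   r2 = round(runif(nrow(prs)), 3)))
    got <- sort(ld_clump(sumstats_table(rec), ld, 0.5, 10000)$records$variant_id)
    maximal <- clump_oracle_maximal_subsets(rec, ld, 0.5, 10000)
    expect_true(any(vapply(maximal, identical, logical(1), y = got)),
                info = paste("rep", rep))
  }
})

test_that("select_instruments applies p, clump, F in order with a stage log", {
  rec <- make_records(5,
    variant_id = c("s1", "s2", "s3", "s4", "s5"),
    chrom = c("1", "1", "1", "2", "1"),
    pos = c(1000, 2000, 5e6, 1000, 8e6),
    beta = c(0.10, 0.09, 0.05, 0.08, 0.10),
    se = c(0.01, 0.02, 0.02, 0.02, 0.02),
    pval = c(1e-8, 1e-6, 1e-7, 1e-6, 1e-3))
  ld <- ld_pair_table(data.frame(variant_a = "s1", variant_b = "s2", r2 = 0.5))
  # hand enumeration: p-filter drops s5 (4 left); clumping removes s2 via s1
  # (3 left); F-filter drops s3 with F = 6.25 (2 left)
  sel <- select_instruments(sumstats_table(rec), ld, instrument_config())
  expect_setequal(sel$records$variant_id, c("s1", "s4"))
  expect_equal(attr(sel, "selection_log")$n_retained, c(5L, 4L, 3L, 2L))

  # pass-everything thresholds: identity
  loose <- instrument_config(pval_threshold = 1, clump_r2 = 0.999, min_f = 0)
  expect_equal(n_variants(select_instruments(sumstats_table(rec), ld, loose)), 5)

  # all p too large: typed error naming the first empty stage
  bad <- sumstats_table(make_records(3, pval = 0.5))
  err <- expect_error(select_instruments(bad, ld, instrument_config()),
                      class = "mrpath_no_instruments")
  expect_match(conditionMessage(err), "pvalue")
})
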