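test_that("Cochran's Q matches hand computation and the homogeneous null", {
  # identical ratios: zero heterogeneity
  h <- hset_from_ratios(c(0.3, 0.3, 0.3))
  q <- cochran_q(h, "ivw")
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
  expect_equal(q$df, 2L)

  # two SNPs, beta_exp = 1, beta_out {0.5, 1.0}, unit se: fit 0.75, Q = 0.125
  h2 <- harmonized_set(c(1, 1), c(0.01, 0.01), c(0.5, 1.0), c(1, 1))
  q2 <- cochran_q(h2, "ivw")
  expect_equal(q2$Q, 0.125)
  expect_equal(q2$df, 1L)

  expect_error(cochran_q(harmonized_set(1, 1, 1, 1), "ivw"),
               class = "mrpath_insufficient_instruments")
})

test_that("overdispersed sets are detected by Q in most replicates", {
  rejections <- sapply(1:40, function(s) {
    sim <- simulate_mediation_system(sim_config(
      seed = s, n_snps = 30, n_mediator_snps = 0, a = 0, b = 0, c = 0.3,
      pleiotropy = list(mode = "balanced", sd = 0.05, fraction = 1)))
    cochran_q(harmonize(sim$exposure, sim$outcome), "ivw")$pval < 0.05
  })
  expect_gt(mean(rejections), 0.5)
})

test_that("Egger intercept test: exact fits and the proportional null", {
  h <- harmonized_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                      0.6 * c(0.1, 0.2, 0.3), rep(0.05, 3))
  it <- egger_intercept_test(h)
  expect_equal(it$estimate, 0, tolerance = 1e-10)
  expect_equal(it$pval, 1, tolerance = 1e-6)

  h2 <- harmonized_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                       -0.05 + 1.0 * c(0.1, 0.2, 0.3), rep(0.05, 3))
  expect_equal(egger_intercept_test(h2)$estimate, -0.05, tolerance = 1e-10)
})

test_that("Egger intercept covers simulated directional pleiotropy", {
  # run on selected instruments, as the pipeline does: near-null SNPs would
  # be flipped by the positive-exposure orientation and dilute the intercept
  ints <- t(sapply(1:20, function(s) {
    sim <- simulate_mediation_system(sim_config(
      seed = 300 + s, n_snps = 40, n_mediator_snps = 0, a = 0, b = 0, c = 0.3,
      pleiotropy = list(mode = "directional", mean = 0.03, sd = 0.005,
                        fraction = 1)))
    sel <- select_instruments(sim$exposure, sim$ld)
    it <- egger_intercept_test(harmonize(sel, sim$outcome))
    c(it$estimate, it$se)
  }))
  covered <- abs(ints[, 1] - 0.03) <= 3 * ints[, 2]
  expect_gt(mean(covered), 0.9)
})

test_that("Egger weighted RSS never exceeds the through-origin RSS", {
  set.seed(31)
  for (i in 1:30) {
    h <- random_hset(sample(3:20, 1))
    rows <- mrpath:::orient_positive(h$rows)
    w <- 1 / rows$se_out^2
    b0 <- mr_ivw(h, model = "fixed")$b
    rss_origin <- sum(w * (rows$beta_out - b0 * rows$beta_exp)^2)
    eg <- mr_egger(h)
    rss_egger <- sum(w * (rows$beta_out - eg$intercept$estimate -
                            eg$slope$b * rows$beta_exp)^2)
    expect_lte(rss_egger, rss_origin + 1e-10)
  }
})

test_that("MR-PRESSO flags a constructed outlier and corrects toward truth", {
  sim <- simulate_mediation_system(sim_config(
    seed = 17, n_snps = 30, n_mediator_snps = 0, a = 0, b = 0, c = 0.3,
    n_outliers = 1, outlier_scale = 10))
  set <- harmonize(sim$exposure, sim$outcome)
  out_id <- sim$truth$snps$variant_id[sim$truth$snps$outlier]
  pr <- mr_presso(set, n_sim = 1000, seed = 5)
  expect_true(out_id %in% pr$outlier_ids)
  expect_lt(pr$global_p, 0.05)
  expect_false(is.null(pr$distortion_p))
  err_full <- abs(mr_ivw(set, model = "fixed")$b - 0.3)
  err_corr <- abs(pr$corrected_estimate$b - 0.3)
  expect_lt(err_corr, err_full)
})

test_that("MR-PRESSO null behavior and contracts", {
  sim <- simulate_mediation_system(sim_config(
    seed = 23, n_snps = 20, n_mediator_snps = 0, a = 0, b = 0, c = 0.3))
  set <- harmonize(sim$exposure, sim$outcome)
  pr <- mr_presso(set, n_sim = 1000, seed = 9)
  # clean data: no outliers => distortion test and correction absent by contract
  expect_equal(length(pr$outlier_ids), 0)
  expect_null(pr$distortion_p)
  expect_null(pr$corrected_estimate)
  expect_gt(pr$global_p, 0.05)

  expect_error(mr_presso(harmonized_set(1:3, rep(1, 3), 1:3, rep(1, 3)),
                         n_sim = 1000, seed = 1),
               class = "mrpath_insufficient_instruments")
})

test_that("MR-PRESSO global p is stable across seeds within Monte-Carlo error", {
  # a strongly heterogeneous set gives a small, stable p
  sim <- simulate_mediation_system(sim_config(
    seed = 41, n_snps = 25, n_mediator_snps = 0, a = 0, b = 0, c = 0.3,
    pleiotropy = list(mode = "balanced", sd = 0.08, fraction = 1)))
  set <- harmonize(sim$exposure, sim$outcome)
  p1 <- mr_presso(set, n_sim = 2000, seed = 1)$global_p
  p2 <- mr_presso(set, n_sim = 2000, seed = 2)$global_p
  expect_lte(abs(p1 - p2),
             3 * sqrt(max(p1, 1 / 2001) * (1 - min(p1, 0.999)) / 2000) + 1e-9)
})

test_that("leave-one-out equals per-SNP refits and spots a gross outlier", {
  set.seed(53)
  h <- random_hset(8)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 8)
  for (j in 1:8) {
    sub <- h
    sub$rows <- h$rows[-j, ]
    ref <- mr_ivw(sub)
    expect_equal(loo$beta_without[j], ref$b)
    expect_equal(loo$se_without[j], ref$se)
  }

  # homogeneous ratios: every leave-one-out estimate equals the full one
  hom <- hset_from_ratios(rep(0.25, 5))
  loo2 <- leave_one_out(hom)
  expect_true(all(abs(loo2$beta_without - 0.25) < 1e-12))

  # one gross outlier: its removal moves the estimate the most
  out <- hset_from_ratios(c(rep(0.2, 6), 5))
  loo3 <- leave_one_out(out)
  full <- mr_ivw(out)$b
  expect_equal(which.max(abs(loo3$beta_without - full)), 7L)

  expect_error(leave_one_out(harmonized_set(1, 1, 1, 1)),
               class = "mrpath_insufficient_instruments")
})

test_that("sensitivity_report bundles components and records skips", {
  set.seed(67)
  h <- random_hset(10)
  rep10 <- sensitivity_report(h, n_sim = 1000, seed = 3)
  expect_s3_class(rep10, "sensitivity_report")
  expect_equal(rep10$q_ivw$df, 9L)
  expect_equal(rep10$q_egger$df, 8L)
  expect_equal(nrow(rep10$loo), 10)
  expect_length(rep10$skipped, 0)

  h2 <- random_hset(2)
  rep2 <- sensitivity_report(h2, n_sim = 1000, seed = 3)
  expect_false(is.null(rep2$q_ivw))
  expect_null(rep2$presso)
  expect_null(rep2$loo)
  expect_gte(length(rep2$skipped), 3)
})
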