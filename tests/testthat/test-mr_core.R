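test_that("Wald ratio arithmetic and guards", {
  est <- mr_wald_ratio(0.2, 0.01, 0.1, 0.05)
  expect_equal(est$b, 0.5)
  expect_equal(est$se, 0.25)
  expect_equal(est$or, exp(0.5))
  expect_equal(mr_wald_ratio(0.2, 0.01, 0, 0.05)$b, 0)
  expect_equal(mr_wald_ratio(-0.2, 0.01, 0.1, 0.05)$b, -0.5)
  expect_error(mr_wald_ratio(0, 0.01, 0.1, 0.05), "undefined")
})

test_that("IVW reduces to the Wald ratio in degenerate cases", {
  one <- harmonized_set(0.2, 0.01, 0.1, 0.05)
  expect_error(mr_ivw(one), class = "mrpath_insufficient_instruments")
  expect_match(tryCatch(mr_ivw(one), error = conditionMessage), "wald_ratio")

  dup <- harmonized_set(c(0.2, 0.2), c(0.01, 0.01), c(0.1, 0.1), c(0.05, 0.05))
  expect_equal(mr_ivw(dup, model = "fixed")$b, 0.5)

  two <- harmonized_set(c(1, 1), c(0.01, 0.01), c(0.5, 0.7), c(0.05, 0.05))
  expect_equal(mr_ivw(two, model = "fixed")$b, 0.6)
})

test_that("fixed-effect IVW equals a WLS-through-origin oracle (100 instances)", {
  set.seed(101)
  for (i in 1:100) {
    h <- random_hset(sample(3:30, 1))
    est <- mr_ivw(h, model = "fixed")
    fit <- lm(beta_out ~ 0 + beta_exp, data = h$rows,
              weights = 1 / h$rows$se_out^2)
    expect_equal(est$b, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("multiplicative random effects never shrinks the fixed-effect se", {
  set.seed(7)
  for (i in 1:25) {
    h <- random_hset(sample(3:20, 1))
    expect_gte(mr_ivw(h)$se, mr_ivw(h, model = "fixed")$se - 1e-12)
  }
})

test_that("MR-Egger recovers an exact line and a proportional null", {
  h <- harmonized_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                      c(0.05, 0.15, 0.25), rep(0.05, 3))
  eg <- mr_egger(h)
  expect_equal(eg$slope$b, 1.0, tolerance = 1e-10)
  expect_equal(eg$intercept$estimate, -0.05, tolerance = 1e-10)

  h2 <- harmonized_set(c(0.1, 0.25, 0.4), rep(0.01, 3),
                       2.5 * c(0.1, 0.25, 0.4), rep(0.05, 3))
  eg2 <- mr_egger(h2)
  expect_equal(eg2$slope$b, 2.5, tolerance = 1e-10)
  expect_equal(eg2$intercept$estimate, 0, tolerance = 1e-10)

  expect_error(mr_egger(harmonized_set(c(1, 1), c(1, 1), c(1, 1), c(1, 1))),
               class = "mrpath_insufficient_instruments")
})

test_that("weighted median matches definition, dominance and a hand oracle", {
  # equal weights, odd n: exactly the sample median
  expect_equal(mrpath:::weighted_median_value(c(0.1, 0.3, 0.2), rep(1, 3)), 0.2)
  # via the estimator, ratio variances are only near-equal
  h <- hset_from_ratios(c(0.1, 0.2, 0.3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$b, 0.2,
               tolerance = 1e-3)

  # one ratio holding > 50% of the weight wins
  expect_equal(mrpath:::weighted_median_value(c(0.1, 0.2, 0.3),
                                              c(0.1, 0.8, 0.1)), 0.2)

  # hand-computed interpolation: cum weights (0.05, 0.2, 0.45, 0.8), the 0.5
  # crossing sits between 0.3 and 0.4 at 0.3 + 0.1 * (0.05 / 0.35)
  expect_equal(mrpath:::weighted_median_value(c(0.1, 0.2, 0.3, 0.4),
                                              c(0.1, 0.2, 0.3, 0.4)),
               0.3 + 0.1 * (0.05 / 0.35))
})

test_that("mode estimators find the dominant cluster", {
  ratios <- c(0.08, 0.09, 0.1, 0.1, 0.11, 0.12, 0.88, 0.9, 0.92)
  h <- hset_from_ratios(ratios)
  sm <- mr_mode(h, weighted = FALSE, n_boot = 50, seed = 1)
  expect_lt(abs(sm$b - 0.1), 0.05)

  # dense-grid KDE argmax oracle, computed independently
  wr <- mrpath:::wald_ratios(h$rows)
  hbw <- stats::mad(wr$ratio, constant = 1.4826)
  grid <- seq(min(wr$ratio) - 3 * hbw, max(wr$ratio) + 3 * hbw,
              length.out = 10000)
  dens <- sapply(grid, function(x) mean(stats::dnorm((x - wr$ratio) / hbw)))
  expect_equal(sm$b, grid[which.max(dens)])

  # weighted mode: put nearly all inverse-variance weight on the 0.9 cluster
  h2 <- harmonized_set(beta_exp = rep(1, 9), se_exp = rep(0.001, 9),
                       beta_out = ratios,
                       se_out = c(rep(0.5, 6), rep(0.01, 3)))
  wm <- mr_mode(h2, weighted = TRUE, n_boot = 50, seed = 1)
  expect_lt(abs(wm$b - 0.9), 0.05)

  # zero spread: the common ratio is returned
  h3 <- hset_from_ratios(rep(0.4, 5))
  expect_equal(mr_mode(h3, n_boot = 50, seed = 1)$b, 0.4)
})

test_that("estimators are sign-equivariant", {
  set.seed(5)
  for (i in 1:10) {
    h <- random_hset(8)
    flip_joint <- h
    flip_joint$rows$beta_exp <- -h$rows$beta_exp
    flip_joint$rows$beta_out <- -h$rows$beta_out
    flip_out <- h
    flip_out$rows$beta_out <- -h$rows$beta_out
    for (f in list(function(x) mr_ivw(x)$b,
                   function(x) mr_egger(x)$slope$b,
                   function(x) mr_weighted_median(x, n_boot = 10, seed = 1)$b)) {
      expect_equal(f(flip_joint), f(h), tolerance = 1e-10)
      expect_equal(f(flip_out), -f(h), tolerance = 1e-10)
    }
  }
})

test_that("mr_run_all dispatches by instrument count with logged skips", {
  one <- harmonized_set(0.2, 0.01, 0.1, 0.05)
  r1 <- mr_run_all(one)
  expect_equal(r1$method, "wald_ratio")
  expect_equal(nrow(attr(r1, "skipped")), 5)

  two <- harmonized_set(c(1, 1), c(0.01, 0.01), c(0.5, 0.7), c(0.05, 0.05))
  r2 <- mr_run_all(two, seed = 1)
  expect_equal(r2$method, "ivw_mre")
  expect_setequal(attr(r2, "skipped")$method,
                  c("egger", "weighted_median", "simple_mode", "weighted_mode"))

  set.seed(2)
  many <- random_hset(20)
  r3 <- mr_run_all(many, n_boot = 25, seed = 3)
  expect_setequal(r3$method, c("ivw_mre", "egger", "weighted_median",
                               "simple_mode", "weighted_mode"))
  expect_equal(attr(r3, "primary"), "ivw_mre")
  expect_true(all(r3$or == exp(r3$b)))
  expect_true(all(r3$ci_low <= r3$b & r3$b <= r3$ci_high))
})
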