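test_that("estimate_proportion: closed forms and edge cases", {
  est <- estimate_proportion(63, 100)
  expect_equal(est$point, 0.63)
  expect_true(est$lower < 0.63 && est$upper > 0.63)
  full <- estimate_proportion(10, 10)
  expect_equal(full$point, 1)
  expect_equal(full$upper, 1)
  # zero-count Clopper-Pearson bound: 1 - (alpha/2)^(1/n)
  cp <- estimate_proportion(0, 100, method = "clopper_pearson")
  expect_equal(cp$lower, 0)
  expect_equal(cp$upper, 1 - 0.025^(1 / 100), tolerance = 1e-10)
  expect_error(estimate_proportion(1, 0))
  expect_error(estimate_proportion(5, 3))
  # Clopper-Pearson agrees with binom.test (independent route)
  bt <- binom.test(17, 60)$conf.int
  cp2 <- estimate_proportion(17, 60, method = "clopper_pearson")
  expect_equal(c(cp2$lower, cp2$upper), as.numeric(bt), tolerance = 1e-9)
})

test_that("Wilson interval coverage is near nominal (property)", {
  set.seed(2024)
  p_true <- 0.3; n <- 200
  covered <- vapply(1:500, function(i) {
    k <- rbinom(1, n, p_true)
    est <- estimate_proportion(k, n)
    est$lower <= p_true && p_true <= est$upper
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("germination_success and delayed_fraction arithmetic", {
  expect_equal(germination_success(288, 288), 1)
  expect_equal(germination_success(288, 0), 0)
  expect_equal(germination_success(288, 18), 0.0625)
  expect_error(germination_success(0, 0))
  expect_equal(as.numeric(delayed_fraction(50, 50)), 0)
  expect_equal(as.numeric(delayed_fraction(40, 50)), 0.2)
  und <- delayed_fraction(0, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_error(delayed_fraction(5, 3))
})

test_that("fitness_table composes proportion and fitness index row-wise", {
  m <- rbind(
    make_measurement(facs_analyzed = 100000, facs_positive = 10,
                     wells_sorted_pos = 288, germinated_day1_pos = 15,
                     germinated_day2_pos = 18),
    make_measurement(line_id = "L2", facs_positive = 0,
                     germinated_day1_pos = 0, germinated_day2_pos = 0))
  ft <- fitness_table(m)
  expect_equal(ft$positive_fraction[1], 1e-4)
  expect_equal(ft$germination_pos[1], 0.0625)
  expect_equal(ft$fitness_index[1], 6.25e-6)
  # composition identity: no hidden recomputation
  expect_equal(ft$fitness_index[1],
               fitness_index(estimate_proportion(10, 100000)$point,
                             estimate_proportion(18, 288)$point))
  expect_equal(ft$fitness_index[2], 0)
  # the printed-style worked example: 0.01% x 6.3% -> 0.0006% at 1 s.f.
  m3 <- make_measurement(facs_analyzed = 1e6, facs_positive = 100,
                         wells_sorted_pos = 1000, germinated_day1_pos = 50,
                         germinated_day2_pos = 63)
  ft3 <- fitness_table(m3)
  expect_equal(signif(ft3$fitness_index * 100, 1), 6e-4)
  # missing arm flagged
  m4 <- make_measurement(wells_sorted_pos = 0, germinated_day1_pos = 0,
                         germinated_day2_pos = 0)
  expect_true(fitness_table(m4)$incomplete)
})

test_that("estimate_transmission_params recovers and falls back", {
  row <- make_measurement(facs_analyzed = 1e6, facs_positive = 290000,
                          wells_sorted_pos = 1000, germinated_day2_pos = 880,
                          germinated_day1_pos = 700,
                          wells_sorted_neg = 1000, germinated_day2_neg = 690,
                          germinated_day1_neg = 600)
  est <- estimate_transmission_params(row)
  expect_equal(est$g, 0.88)
  expect_equal(est$e, 0.69)
  expect_equal(est$p0, 0.29)
  expect_false(attr(est, "e_fallback"))
  expect_named(attr(est, "intervals"), c("g", "e", "p0"))
  # negative arm absent -> fallback e flagged
  row2 <- make_measurement(wells_sorted_neg = 0, germinated_day1_neg = 0,
                           germinated_day2_neg = 0)
  est2 <- estimate_transmission_params(row2)
  expect_equal(est2$e, 0.69)
  expect_true(attr(est2, "e_fallback"))
  # positive arm absent -> error
  row3 <- make_measurement(wells_sorted_pos = 0, germinated_day1_pos = 0,
                           germinated_day2_pos = 0)
  expect_error(estimate_transmission_params(row3), "positive")
})

test_that("parameter recovery bias shrinks with arm size", {
  truth <- transmission_params(g = 0.6, e = 0.69, p0 = 0.15)
  bias <- vapply(c(100, 1000, 10000), function(n) {
    est <- vapply(1:40, function(i) {
      m <- generate_round0_measurement(truth, n_analyzed = 1e5,
                                       wells_pos = n, wells_neg = n,
                                       seed = 7000 + n + i)
      p <- estimate_transmission_params(m)
      c(p$g, p$e, p$p0)
    }, numeric(3))
    mean(abs(rowMeans(est) - c(0.6, 0.69, 0.15)))
  }, numeric(1))
  expect_lt(bias[3], 0.01)
  expect_lt(bias[3], bias[1] + 0.01)
})

test_that("model_fit_error is a log10 RMSE with censoring", {
  obs <- data.frame(round = 1:3, p = c(1e-2, 1e-3, 1e-4))
  expect_equal(model_fit_error(obs, obs), 0)
  expect_equal(model_fit_error(data.frame(round = 1, p = 1e-3),
                               data.frame(round = 1, p = 1e-4)), 1)
  # censored rounds excluded
  obs2 <- data.frame(round = 1:2, p = c(1e-3, 0),
                     below_det = c(FALSE, TRUE))
  pred <- data.frame(round = 1:2, p = c(1e-4, 1e-5))
  expect_equal(model_fit_error(obs2, pred), 1)
  expect_error(model_fit_error(data.frame(round = 5, p = 0.1),
                               data.frame(round = 1, p = 0.1)), "missing")
  expect_error(model_fit_error(obs2[2, ], pred), "censored")
})

test_that("filter_sweeping_mutations applies the inclusive >= 50% rule", {
  tab <- data.frame(
    mutation_id = rep(c("a", "b", "c", "anc"), each = 3),
    round = rep(1:3, 4),
    frequency = c(0.1, 0.3, 0.50,   # a peaks exactly at 0.50 -> kept
                  0.1, 0.2, 0.49,   # b stays below -> dropped
                  0.2, 0.6, 0.9,    # c sweeps -> kept
                  0.9, 0.9, 0.9),   # ancestral -> dropped
    present_in_ancestor = rep(c(FALSE, FALSE, FALSE, TRUE), each = 3))
  expect_equal(filter_sweeping_mutations(tab), c("a", "c"))
  empty <- tab[0, ]
  expect_equal(filter_sweeping_mutations(empty), character(0))
  # constructed fixture: 9 above vs 3 below
  set.seed(10)
  big <- do.call(rbind, lapply(1:12, function(i) {
    peak <- if (i <= 9) runif(1, 0.5, 1) else runif(1, 0, 0.49)
    data.frame(mutation_id = sprintf("m%02d", i), round = 1:4,
               frequency = seq(0, peak, length.out = 4),
               present_in_ancestor = FALSE)
  }))
  expect_equal(sort(filter_sweeping_mutations(big)), sprintf("m%02d", 1:9))
})

test_that("sweep_fitness_correlation is Spearman rho", {
  expect_equal(as.numeric(sweep_fitness_correlation(1:5, 2^(1:5))), 1)
  expect_equal(as.numeric(sweep_fitness_correlation(1:5, 5:1)), -1)
  # 5-point case vs independent rank computation
  set.seed(8)
  x <- runif(5); y <- runif(5)
  expect_equal(as.numeric(sweep_fitness_correlation(x, y)),
               cor(x, y, method = "spearman"))
  const <- sweep_fitness_correlation(rep(0.5, 4), 1:4)
  expect_true(is.na(const) && attr(const, "undefined"))
  expect_error(sweep_fitness_correlation(1:2, 1:2), "3 rounds")
})

test_that("welch_t_test reproduces the hand-computed example and t.test", {
  res <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224744871, tolerance = 1e-8)
  expect_equal(res$df, 4.0)
  # identical samples: t = 0, p = 1
  same <- welch_t_test(c(1, 2, 5), c(1, 2, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # antisymmetry
  set.seed(31)
  x <- rnorm(8); y <- rnorm(6, 1)
  a <- welch_t_test(x, y); b <- welch_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # independent oracle: stats::t.test across random cases
  for (i in 1:25) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    mine <- welch_t_test(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  zero <- welch_t_test(c(1, 1), c(1, 1))
  expect_true(zero$undefined)
  expect_error(welch_t_test(1, c(1, 2)))
})

test_that("wilcoxon_signed_rank: exact p matches full enumeration", {
  res <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(res$W, 6)
  expect_equal(res$p, 0.25)
  expect_true(res$exact)
  # antisymmetric under negating all differences
  set.seed(17)
  d <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_signed_rank(-d)$p)
  # all-zero differences: undefined flag
  und <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(und$undefined)
  # exact p equals literal 2^n enumeration, incl. ties, n <= 10
  for (i in 1:60) {
    n <- sample(3:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # integer ties likely
    expect_equal(wilcoxon_signed_rank(d)$p, oracle_signed_rank_p(d),
                 tolerance = 1e-12, info = paste(d, collapse = ","))
  }
  # tie-free exact p also matches stats::wilcox.test
  for (i in 1:20) {
    d <- rnorm(sample(4:12, 1))
    expect_equal(wilcoxon_signed_rank(d)$p,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large-n approximate path returns a sane p
  big <- wilcoxon_signed_rank(rnorm(40, 0.3))
  expect_false(big$exact)
  expect_true(big$p > 0 && big$p <= 1)
})

test_that("test p-values are order-invariant and in (0, 1]", {
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(7)
    expect_equal(welch_t_test(sample(x), sample(y))$p, welch_t_test(x, y)$p)
    p1 <- wilcoxon_signed_rank(x, y)$p
    perm <- sample(7)
    expect_equal(wilcoxon_signed_rank(x[perm], y[perm])$p, p1)
    expect_true(p1 > 0 && p1 <= 1)
  }
})
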