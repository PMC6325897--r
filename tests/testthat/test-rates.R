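# Rate arithmetic, spectrum statistics and treatment tests, with
# closed-form oracles.

test_that("per-line and pooled SNM rates", {
  expect_equal(per_line_snm_rate(0, 1e7, 100), 0)
  expect_equal(per_line_snm_rate(5, 1e7, 100), 5e-9)
  expect_error(per_line_snm_rate(1, 0, 100), "positive")
  expect_error(per_line_snm_rate(1, 1e7, 0), "positive")
})

test_that("pooled rate identity: weighted mean of per-line rates", {
  set.seed(8)
  for (rep in 1:20) {
    n <- rpois(12, 20)
    C <- runif(12, 1e6, 1e8)
    g <- runif(12, 50, 150)
    p <- pooled_snm_rate(n, C, g)
    w <- C * g
    expect_equal(p$rate, sum(w * p$per_line) / sum(w),
                 tolerance = 1e-13)
    expect_equal(p$rate, sum(n) / sum(C * g), tolerance = 1e-13)
  }
})

test_that("LOH rate triple", {
  ev <- data.table::data.table(line_id = "L1", avg_size = 1000)
  summ <- data.table::data.table(line_id = "L1", treatment = "Control",
                                 generations = 100,
                                 callable_loh_bp = 1e6)
  lr <- loh_rates(ev, summ)
  expect_equal(lr$per_line$events_per_gen, 0.01)
  expect_equal(lr$per_line$bp_per_gen, 10)
  expect_equal(lr$per_line$rate_per_bp_gen, 1e-5)
  # zero events
  lr0 <- loh_rates(ev[0], summ)
  expect_equal(lr0$per_line$events_per_gen, 0)
  expect_equal(lr0$pooled$bp_per_gen, 0)
  # conservation: the bp numerator is the sum of average sizes
  ev2 <- data.table::data.table(line_id = "L1", avg_size = c(300, 700))
  expect_equal(loh_rates(ev2, summ)$per_line$bp, sum(ev2$avg_size))
})

test_that("spectrum test: AT-corrected expectations, df = 5", {
  at <- 0.5818
  tot <- 120
  expd <- tot * rep(c(at, 1 - at), each = 3) / 3
  names(expd) <- MUT_TYPES
  st <- spectrum_test(round(expd) - round(expd) + expd, at)
  expect_equal(st$statistic, 0, tolerance = 1e-12)
  expect_equal(st$df, 5L)
  # all counts in one class at AT 0.5: chi-squared = 5N by direct Pearson
  N <- 60
  st2 <- spectrum_test(c("GC>AT" = N), 0.5)
  expect_equal(st2$statistic, 5 * N, tolerance = 1e-12)
  expect_error(spectrum_test(c("GC>AT" = 0), 0.5), "no mutations")
})

test_that("spectrum homogeneity: df and Pearson oracle", {
  m <- matrix(rep(c(5, 10, 3, 20, 2, 8), 4), nrow = 6)
  rownames(m) <- MUT_TYPES
  h <- spectrum_homogeneity(m)
  expect_equal(h$statistic, 0, tolerance = 1e-12)
  expect_equal(h$df, 15L)
  m2 <- cbind(a = c(4, 6, 1, 9, 2, 3), b = c(2, 9, 3, 12, 1, 6))
  rownames(m2) <- MUT_TYPES
  h2 <- spectrum_homogeneity(m2)
  expd <- outer(rowSums(m2), colSums(m2)) / sum(m2)
  expect_equal(h2$statistic, sum((m2 - expd)^2 / expd), tolerance = 1e-12)
  expect_equal(h2$df, 5L)
  # doubling all counts doubles the statistic (proportional scaling)
  h4 <- spectrum_homogeneity(2 * m2)
  expect_equal(h4$statistic, 2 * h2$statistic, tolerance = 1e-12)
})

test_that("MNM fraction", {
  snms <- data.table::data.table(mnm_group = c(rep(NA_integer_, 620),
                                               rep(1:10, length.out = 24)))
  mf <- mnm_fraction(snms)
  expect_equal(round(mf$percent, 1), 3.7)
  expect_equal(mf$n_groups, 10L)
  expect_equal(mnm_fraction(snms[1:10])$percent, 0)
  expect_equal(mnm_fraction(snms[621:644])$percent, 100)
  expect_true(is.na(mnm_fraction(snms[0])$percent))
})

test_that("treatment tests: ANOVA/Kruskal behavior and oracles", {
  x <- rep(c(1, 2, 3), 4)
  tr <- rep(c("a", "b", "c", "d"), each = 3)
  res <- treatment_rate_tests(x, tr, test = "anova")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  # two groups: F equals the squared two-sample t statistic
  set.seed(4)
  y <- c(rnorm(8), rnorm(8, 0.7))
  g2 <- rep(c("a", "b"), each = 8)
  fa <- treatment_rate_tests(y, g2, test = "anova")
  tt <- t.test(y ~ g2, var.equal = TRUE)
  expect_equal(fa$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  # Kruskal-Wallis matches the rank formula on tie-free data
  z <- c(0.3, 1.2, 2.2, 0.9, 1.7, 2.9, 0.1, 2.4, 1.1)
  g3 <- rep(c("a", "b", "c"), each = 3)
  kw <- treatment_rate_tests(z, g3, test = "kruskal")
  rk <- rank(z); N <- length(z)
  Hor <- 12 / (N * (N + 1)) *
    sum(tapply(rk, g3, function(r) length(r) * mean(r)^2)) - 3 * (N + 1)
  expect_equal(kw$statistic, Hor, tolerance = 1e-10)
  expect_error(treatment_rate_tests(c(1, 2, 3), c("a", "a", "b"),
                                    test = "anova"), "singleton")
})

test_that("chance of same chromosome", {
  expect_equal(chance_same_chromosome(3, 12), 1 / 144)
  expect_equal(round(100 * chance_same_chromosome(3, 12), 1), 0.7)
  expect_equal(chance_same_chromosome(1, 12), 1)
  expect_equal(chance_same_chromosome(2, 2), 0.5)
})

test_that("expected Het-Hom SNM count", {
  expect_equal(expected_het_hom_snms(0, 0.007, 4e11), 0)
  e <- expected_het_hom_snms(1.61e-9, 0.007, 72163836 * 5557.9, 1 / 3)
  expect_equal(e, 1.51, tolerance = 0.01)
  expect_equal(expected_het_hom_snms(1.61e-9, 0.007, 4.011e11, 1),
               3 * expected_het_hom_snms(1.61e-9, 0.007, 4.011e11, 1 / 3),
               tolerance = 1e-12)
})

test_that("rate-on-generations regression matches the OLS oracle", {
  g <- c(80, 95, 100, 120, 133)
  y <- 2 * g
  r <- suppressWarnings(rate_vs_generations(y, g))  # exact fit
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  y2 <- c(1.2, 0.8, 1.9, 2.4, 1.1)
  r2 <- rate_vs_generations(y2, g)
  b <- sum((g - mean(g)) * (y2 - mean(y2))) / sum((g - mean(g))^2)
  a <- mean(y2) - b * mean(g)
  expect_equal(r2$slope, b, tolerance = 1e-12)
  expect_equal(r2$intercept, a, tolerance = 1e-12)
  expect_error(rate_vs_generations(y2, rep(100, 5)), "constant")
})
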