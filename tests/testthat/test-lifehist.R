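# Life tables, Euler-Lotka, anchored regression and variance-component
# parameters.

one_subline <- function(id = "s1", line = "L1", ages = c(2, 3, 4, 5),
                        sizes = c(10, 12, 12, 10), longevity = 8,
                        alive = TRUE) {
  out <- data.table::data.table(
    line_id = line, subline_id = id, treatment = "Control",
    generations = 100, body_size = 2.4, longevity = longevity,
    survived_to_assay = alive)
  for (k in 1:4) {
    out[[paste0("clutch_age_", k)]] <- ages[k]
    out[[paste0("clutch_size_", k)]] <- sizes[k]
  }
  out
}

test_that("life tables from subline records", {
  lt <- build_life_table(one_subline(ages = c(8, 11, 14, 17),
                                     sizes = c(10, 9, 9, 8),
                                     longevity = 30))
  expect_equal(lt$lx[lt$x == 8], 1)
  expect_equal(lt$mx[lt$x == 8], 10)
  # one of two sublines dead before day 8
  rec <- rbind(one_subline("a", ages = c(8, 11, 14, 17), longevity = 30),
               one_subline("b", ages = c(8, 11, 14, 17), longevity = 5))
  lt2 <- build_life_table(rec)
  expect_equal(lt2$lx[lt2$x == 8], 0.5)
  # exactly the four clutch entries
  expect_equal(nrow(lt), 4L)
  expect_error(build_life_table(one_subline(alive = FALSE)), "surviving")
})

test_that("Euler-Lotka root: closed-form cases", {
  # single age class x = 1, l*m = e  ->  r = 1
  lt <- data.frame(x = 1, lx = 1, mx = exp(1))
  expect_equal(solve_r(lt), 1, tolerance = 1e-10)
  # R0 = 1 -> r = 0
  lt0 <- data.frame(x = c(1, 2), lx = 1, mx = c(0.4, 0.6))
  expect_equal(solve_r(lt0), 0, tolerance = 1e-10)
  # l1 m1 = 1, l2 m2 = 1 -> r = ln(golden ratio)
  ltg <- data.frame(x = c(1, 2), lx = 1, mx = 1)
  expect_equal(solve_r(ltg), log((1 + sqrt(5)) / 2), tolerance = 1e-10)
  expect_error(solve_r(data.frame(x = 1, lx = 1, mx = 0)), "no growth")
})

test_that("r is monotone nondecreasing in fecundity", {
  lt <- data.frame(x = c(2, 3, 4), lx = c(1, 0.9, 0.8), mx = c(8, 10, 9))
  r0 <- solve_r(lt)
  for (k in 1:3) {
    lt2 <- lt
    lt2$mx[k] <- lt2$mx[k] + 1
    expect_gt(solve_r(lt2), r0)
  }
})

test_that("stochastic projection agrees with the Euler-Lotka root", {
  lt <- data.frame(x = c(2, 3, 4, 5), lx = c(1, 0.95, 0.9, 0.85),
                   mx = c(6, 8, 8, 6))
  re <- solve_r(lt)
  rp <- solve_r(lt, method = "projection", n0 = 500, burn = 30,
                steps = 120, cap = 20000, seed = 5)
  expect_lt(abs(rp - re), 0.02)
})

test_that("anchored weighted regression: closed form and invariances", {
  a <- 2
  dm <- delta_m(values = c(a - 1, a - 2), sds = c(1, 1),
                generations = c(100, 200), anchor_mean = a, anchor_sd = 0.5)
  expect_equal(dm$slope, -0.01, tolerance = 1e-12)
  expect_equal(dm$dm_pct, 100 * (-0.01) / a, tolerance = 1e-12)
  # passes through the anchor at generation zero exactly
  expect_identical(a + dm$slope * 0, a)
  # all lines at the anchor -> zero slope
  dm0 <- delta_m(rep(a, 5), rep(1, 5), seq(80, 120, 10), a, 0.5)
  expect_equal(dm0$slope, 0)
  # scale invariance of the standardized bias
  dm2 <- delta_m(2 * c(a - 1, a - 2), c(1, 1), c(100, 200), 2 * a, 1)
  expect_equal(dm2$dm_pct, dm$dm_pct, tolerance = 1e-12)
  # zero SDs are replaced by the median positive SD
  expect_warning(
    dmz <- delta_m(c(a - 1, a - 2, a - 1), c(1, 0, 1), c(100, 200, 150),
                   a, 0.5), "median")
  expect_true(is.finite(dmz$slope))
})

test_that("variance components against a hand-computed balanced case", {
  v <- c(1, 3, 5, 7)
  ln <- c("A", "A", "B", "B")
  vc <- mamutkit:::variance_components(v, ln)
  expect_equal(vc$ms_within, 2, tolerance = 1e-12)
  expect_equal(vc$ms_among, 16, tolerance = 1e-12)
  expect_equal(vc$v_line, 7, tolerance = 1e-12)
  cv <- cv_m(v, ln, mean_generations = 100)
  expect_equal(cv$cv_m, 100 * sqrt(7) / 4, tolerance = 1e-12)
  expect_equal(cv$dcv_m, cv$cv_m / 100, tolerance = 1e-12)
  vv <- vm_ve(v, ln, t = 7, divisor = 2)
  expect_equal(vv$v_m, 0.5, tolerance = 1e-12)
  expect_equal(vv$vm_ve, 0.25, tolerance = 1e-12)
  # identical values -> zero CV; truncation when MS_among < MS_within
  expect_equal(cv_m(rep(2, 6), rep(c("A", "B", "C"), 2), 100)$cv_m, 0)
  set.seed(2)
  vt <- rnorm(40)
  lt <- rep(letters[1:4], each = 10)
  vt <- vt - ave(vt, lt)          # remove among-line signal entirely
  expect_equal(cv_m(vt + 5, lt, 100)$v_line, 0)
})

test_that("broad-sense heritability edge cases and recovery", {
  # no within-line variance
  expect_equal(broad_sense_h2(c(1, 1, 2, 2), c("A", "A", "B", "B")), 1)
  # no among-line variance
  v <- c(1, 2, 1, 2)
  expect_equal(broad_sense_h2(v, c("A", "A", "B", "B")), 0)
  # planted 3:1 components
  set.seed(12)
  reps <- replicate(60, {
    b <- rnorm(12, 0, sqrt(3))
    val <- rep(b, each = 6) + rnorm(72, 0, 1)
    broad_sense_h2(val, rep(letters[1:12], each = 6))
  })
  expect_lt(abs(mean(reps) - 0.75), 2 * sd(reps) / sqrt(length(reps)) + 0.02)
})

test_that("treatment x generation interaction test", {
  set.seed(31)
  g <- rep(seq(90, 135, 5), 2)
  tr <- rep(c("a", "b"), each = 10)
  sds <- rep(0.5, 20)
  # strongly divergent slopes are detected
  y <- 2 + ifelse(tr == "a", -0.01, 0.01) * g + rnorm(20, 0, 0.05)
  res <- treatment_interaction_test(y, sds, g, tr, 2, 0.5)
  expect_lt(res$p_value, 0.01)
  expect_equal(unname(sign(res$slopes)), c(-1, 1))
  expect_error(treatment_interaction_test(y[1:10], sds[1:10], g[1:10],
                                          tr[1:10], 2, 0.5), ">= 2")
  # common slope: rejection rate near alpha
  rej <- replicate(60, {
    y0 <- 2 - 0.005 * g + rnorm(20, 0, 0.1)
    treatment_interaction_test(y0, sds, g, tr, 2, 0.5)$p_value < 0.05
  })
  expect_lt(mean(rej), 0.2)
})

test_that("divergence and variance tests flag a shifted line", {
  set.seed(13)
  lines <- rep(sprintf("L%d", 1:5), each = 6)
  tr <- rep("Control", 30)
  v <- rnorm(30, 10, 0.5)
  v[lines == "L3"] <- v[lines == "L3"] + 5  # 10 SD shift
  res <- divergence_and_variance_tests(v, lines, tr)
  blk <- res$per_treatment$Control
  expect_lt(blk$p_value, 1e-4)
  tuk <- blk$tukey
  l3 <- grepl("L3", rownames(tuk))
  expect_true(all(tuk[l3, "p adj"] < 0.01))
  expect_true(all(tuk[!l3, "p adj"] > 0.05))
  # Bartlett across two treatments on line means
  tr2 <- rep(c("a", "b"), each = 15)
  res2 <- divergence_and_variance_tests(rnorm(30), lines, tr2)
  expect_true(!is.null(res2$bartlett$statistic))
})

test_that("generator: anchor r and planted variance are recovered", {
  cfg <- tiny_cfg(n_lines = 10L)
  life <- simulate_life_history(line_metadata(cfg), cfg)
  rs <- subline_r(life)
  anc <- rs[treatment == "nonMA"]
  expect_gt(nrow(anc), 0L)
  se <- sd(anc$r) / sqrt(nrow(anc))
  expect_lt(abs(mean(anc$r) - 1.30), 2 * se + 0.01)
  # delta_true = vm_true = 0: among-line variance not significant in most
  # replicates
  nonsig <- 0L
  for (s in 1:30) {
    cfgz <- tiny_cfg(n_lines = 8L, seed = 100L + s, delta_true = 0,
                     vm_true = 0)
    lz <- simulate_life_history(line_metadata(cfgz), cfgz)
    rz <- subline_r(lz)[treatment != "nonMA"]
    vc <- mamutkit:::variance_components(rz$r, rz$line_id)
    nonsig <- nonsig + (vc$p_value > 0.05)
  }
  expect_gte(nonsig, 24L)   # ~95% expected; binomial floor at 30 reps
})

test_that("planted among-line variance is recovered across lines", {
  vls <- numeric(20)
  for (s in 1:20) {
    cfgv <- tiny_cfg(n_lines = 12L, seed = 300L + s, delta_true = 0,
                     vm_true = 5e-4, ve_true = 5e-4)
    lv <- simulate_life_history(line_metadata(cfgv), cfgv)
    rv <- subline_r(lv)[treatment != "nonMA"]
    vls[s] <- mamutkit:::variance_components(rv$r, rv$line_id)$v_line
  }
  target <- 100 * 5e-4       # g * vm_true
  se <- sd(vls) / sqrt(length(vls))
  expect_lt(abs(mean(vls) - target), 2 * se + 0.002)
})
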