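# Callable-site rules: the 6-read / 1-read thresholds and the LOH
# 200 bp / 6 bp-gap stretch rule, checked against a brute-force scanner.

test_that("SNM callability thresholds", {
  lines <- sprintf("L%02d", 1:4)
  tab <- mk_table(lines, scaffold_len = 100L, base_depth = 12L)
  # focal depth 6, all others 1 -> callable
  tab$depth$s1[10, ] <- c(6L, 1L, 1L, 1L)
  # focal depth 5, others 30 -> not callable
  tab$depth$s1[20, ] <- c(5L, 30L, 30L, 30L)
  # another line with zero depth -> not callable
  tab$depth$s1[30, ] <- c(20L, 0L, 12L, 12L)
  m <- callable_mask(tab, "L01")
  expect_true(in_mask_at(m$snm, "s1", 10))
  expect_false(in_mask_at(m$snm, "s1", 20))
  expect_false(in_mask_at(m$snm, "s1", 30))
  expect_equal(m$C_snm, 100 - 2)
  expect_error(callable_mask(tab, "nope"), "unknown line")
})

test_that("C equals summed interval lengths and per-site truth", {
  lines <- sprintf("L%02d", 1:5)
  set.seed(77)
  tab <- mk_table(lines, scaffold_len = 500L, base_depth = 12L)
  tab$depth$s1[] <- matrix(rpois(500 * 5, 7), 500, 5)
  m <- callable_mask(tab, "L03")
  per_site <- tab$depth$s1[, 3] >= 6L &
    apply(tab$depth$s1[, -3, drop = FALSE] >= 1L, 1, all)
  expect_equal(m$C_snm, sum(per_site))
  expect_equal(m$C_snm, sum(vapply(m$snm, function(d)
    sum(d$end - d$start), 0)))
  # multi-line fast path agrees with the single-line path
  mm <- callable_masks(tab)
  expect_equal(mm$L03$snm, m$snm)
  expect_equal(mm$L03$loh, m$loh)
})

test_that("LOH stretch rule: 200 bp minimum, gaps up to 6 bp", {
  lines <- sprintf("L%02d", 1:3)
  mk_gap_table <- function(gap, left = 100L, right = 100L) {
    tab <- mk_table(lines, scaffold_len = 400L, base_depth = 12L)
    tab$depth$s1[] <- 12L
    tab$depth$s1[(left + 1):(left + gap), 1] <- 0L       # gap for focal
    tab$depth$s1[(left + gap + right + 1):400, 1] <- 0L  # end the run
    tab
  }
  # 200 contiguous qualifying bases -> one 200 bp run
  tab <- mk_table(lines, scaffold_len = 300L, base_depth = 12L)
  tab$depth$s1[201:300, 1] <- 0L
  m <- callable_mask(tab, "L01")
  expect_equal(unname(as.matrix(m$loh$s1)), matrix(c(0, 200), 1))
  # 100 + 7 bp gap + 100 -> two sub-200 fragments, nothing callable
  m7 <- callable_mask(mk_gap_table(7L), "L01")
  expect_equal(nrow(m7$loh$s1), 0L)
  # 100 + 6 bp gap + 100 -> one 206 bp run
  m6 <- callable_mask(mk_gap_table(6L), "L01")
  expect_equal(unname(as.matrix(m6$loh$s1)), matrix(c(0, 206), 1))
})

test_that("gap-tolerant runs match a brute-force scanner", {
  brute <- function(x, max_gap, min_run) {
    # expand every candidate window: a merged run is a maximal set of TRUE
    # positions where consecutive TRUEs are <= max_gap + 1 apart
    pos <- which(x)
    if (!length(pos)) return(matrix(numeric(0), 0, 2))
    grp <- cumsum(c(1, diff(pos) > max_gap + 1))
    out <- t(vapply(split(pos, grp), function(p)
      c(min(p) - 1, max(p)), numeric(2)))
    out[out[, 2] - out[, 1] >= min_run, , drop = FALSE]
  }
  set.seed(123)
  for (rep in 1:25) {
    x <- runif(300) < 0.8
    got <- mamutkit:::gap_tolerant_runs(x, max_gap = 3L, min_run = 20L)
    want <- brute(x, 3L, 20L)
    expect_equal(unname(as.matrix(got)), unname(want))
  }
})
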