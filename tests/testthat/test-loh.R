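# LOH assembly, sizing, multi-scaffold merging and mechanism
# classification.

hh <- function(pos, sc = "s1") data.table::data.table(
  scaffold = sc, pos = as.integer(pos), retained = "A")
fh <- function(pos, sc = "s1") data.table::data.table(
  scaffold = sc, pos = as.integer(pos))

test_that("event assembly: two sites, 200 bp, interior het breaks", {
  # 1000 and 1228: span 229, no interior het -> one event
  ev <- assemble_loh_events(hh(c(1000, 1228)), fh(integer(0)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$min_span, 229L)
  expect_equal(ev$n_sites, 2L)
  # span 151 -> below the 200 bp floor
  expect_equal(nrow(assemble_loh_events(hh(c(1000, 1150)),
                                        fh(integer(0)))), 0L)
  # interior focal-het site splits the run; fragments are single-site
  ev3 <- assemble_loh_events(hh(c(1000, 1300)), fh(1100))
  expect_equal(nrow(ev3), 0L)
  # single Het-Hom site never qualifies
  expect_equal(nrow(assemble_loh_events(hh(5000), fh(integer(0)))), 0L)
})

test_that("size bounds: min, max between flanking het sites, average", {
  ev <- assemble_loh_events(hh(seq(1000, 1500, by = 100)), fh(c(900, 1600)))
  sz <- loh_size_bounds(ev, fh(c(900, 1600)), c(s1 = 10000L))
  expect_equal(sz$min_span, 501L)
  expect_equal(sz$max_span, 699L)   # positions 901..1599
  expect_equal(sz$avg_size, 600)
  expect_false(sz$whole_scaffold)
  # no flanking het: bounds extend to the scaffold edges
  sz2 <- loh_size_bounds(ev, fh(integer(0)), c(s1 = 10000L))
  expect_equal(sz2$max_span, 10000L)
  expect_true(sz2$whole_scaffold)
  # flanking het adjacent to the run: min == max == avg
  sz3 <- loh_size_bounds(ev, fh(c(999, 1501)), c(s1 = 10000L))
  expect_equal(sz3$max_span, 501L)
  expect_equal(sz3$avg_size, 501)
})

test_that("whole-scaffold events merge only within line and chromosome", {
  map <- data.table::data.table(scaffold = c("s1", "s2", "s3"),
                                chrom = c(11L, 11L, 4L))
  mk_ev <- function(sc, ws = TRUE) {
    ev <- assemble_loh_events(hh(c(1000, 1600), sc), fh(integer(0), sc))
    loh_size_bounds(ev, fh(integer(0), sc), setNames(5000L, sc))
  }
  both <- rbind(mk_ev("s1"), mk_ev("s2"))
  merged <- merge_multiscaffold(both, map)
  expect_equal(nrow(merged), 1L)
  expect_true(merged$multi_scaffold)
  expect_equal(merged$scaffold, "s1,s2")
  expect_equal(merged$min_span, 2L * 601L)
  expect_equal(merged$avg_size, 2 * 601)   # minimum estimate only
  # different chromosomes stay separate
  other <- rbind(mk_ev("s1"), mk_ev("s3"))
  expect_equal(nrow(merge_multiscaffold(other, map)), 2L)
  # scaffold missing from the map: warning, unmerged
  expect_warning(
    merge_multiscaffold(rbind(mk_ev("s1"),
                              mk_ev("sX")),
                        map), "missing")
})

test_that("classification follows the standardized relative coverage", {
  lines <- c("F", "O1", "O2")
  tab <- mk_table(lines, scaffold_len = 2000L, base_depth = 12L)
  ev <- assemble_loh_events(hh(c(501, 900)), fh(integer(0)))
  ev <- loh_size_bounds(ev, fh(integer(0)), c(s1 = 2000L))
  ev$multi_scaffold <- FALSE
  # copy-neutral: focal equals the others everywhere -> ratio 1
  cl <- classify_loh_events(ev, tab, "F")
  expect_equal(cl$std_rel_cov, 1.0)
  expect_equal(cl$mechanism, "gene_conversion")
  # halved focal depth across the event -> hemizygous deletion
  tab2 <- mk_table(lines, scaffold_len = 2000L, base_depth = 12L)
  tab2$depth$s1[501:900, 1] <- 6L
  cl2 <- classify_loh_events(ev, tab2, "F")
  oracle <- (mean(tab2$depth$s1[501:900, 1]) /
               mean(tab2$depth$s1[501:900, ])) /
    (mean(tab2$depth$s1[, 1]) / mean(tab2$depth$s1))
  expect_equal(cl2$std_rel_cov, oracle, tolerance = 1e-12)
  expect_equal(cl2$mechanism, "hemizygous_deletion")
  # the 0.75 threshold is inclusive for gene conversion
  cl3 <- classify_loh_events(ev, tab2, "F", threshold = cl2$std_rel_cov)
  expect_equal(cl3$mechanism, "gene_conversion")
})

test_that("shrinking min_span only adds events", {
  set.seed(99)
  pos <- sort(sample(1:100000, 60))
  hhs <- hh(pos)
  fhs <- fh(sort(sample(1:100000, 30)))
  e200 <- assemble_loh_events(hhs, fhs, min_span = 200L)
  e50 <- assemble_loh_events(hhs, fhs, min_span = 50L)
  key <- function(e) paste(e$scaffold, e$first, e$last)
  expect_true(all(key(e200) %in% key(e50)))
  expect_gte(nrow(e50), nrow(e200))
})

test_that("planted mechanisms are recovered on simulated data", {
  n_ok <- 0L; n_tot <- 0L
  for (s in 1:2) {
    cfg <- tiny_cfg(scaffold_lengths = 200000L, n_scaffolds = 2L,
                    n_lines = 8L, loh_rate = 0.04, seed = 60L + s,
                    loh_size_dist = c(1500, 20000))
    ex <- simulate_ma_experiment(cfg)
    masks <- callable_masks(ex$table)
    got <- call_loh(ex$table, masks)
    for (l in names(ex$truth)) {
      tr <- ex$truth[[l]]$loh
      gl <- got[got$line_id == l & !got$multi_scaffold, ]
      if (!nrow(tr) || !nrow(gl)) next
      for (j in seq_len(nrow(gl))) {
        hit <- which(tr$scaffold == gl$scaffold[j] &
                       tr$start <= gl$last[j] & tr$end >= gl$first[j])
        if (length(hit) != 1L) next   # overlapping truths are ambiguous
        n_tot <- n_tot + 1L
        n_ok <- n_ok + (tr$mechanism[hit] == gl$mechanism[j])
      }
    }
  }
  expect_gt(n_tot, 20L)
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("reported events respect the min_sites and min_span contracts", {
  cfg <- tiny_cfg(scaffold_lengths = 150000L, n_lines = 6L,
                  loh_rate = 0.03, seed = 71L, loh_size_dist = c(500, 5000))
  ex <- simulate_ma_experiment(cfg)
  got <- call_loh(ex$table)
  if (nrow(got)) {
    expect_true(all(got$n_sites >= 2L))
    expect_true(all(got$min_span >= 200L))
    single <- got[!got$multi_scaffold, ]
    expect_true(all(single$min_span <= single$avg_size &
                      single$avg_size <= single$max_span))
  }
  succeed()
})
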