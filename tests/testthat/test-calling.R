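# Candidate detection, binomial consistency filtering, Het-Hom routing,
# MNM grouping and INDEL handling.

lines10 <- sprintf("L%02d", 1:10)

test_that("candidates are single-divergent sites only", {
  tab <- mk_table(lines10, site_list = list(
    site_one_divergent(lines10, 50),                         # one 0/1
    {s <- site_one_divergent(lines10, 60)                    # two 0/1
     s$counts$L02 <- c(6L, 6L); s},
    {s <- site_one_divergent(lines10, 70)                    # all 0/1
     for (l in lines10) s$counts[[l]] <- c(6L, 6L); s}))
  cand <- detect_candidates(tab)
  expect_equal(cand$pos, 50L)
  expect_equal(cand$line_id, "L01")
  expect_equal(cand$consensus_gt, "0/0")
  tab3 <- mk_table(c("A", "B"), site_list = list())
  expect_error(detect_candidates(tab3), ">= 3 lines")
})

test_that("binomial consistency: focal and other-line tests", {
  tab <- mk_table(lines10, site_list = list(
    site_one_divergent(lines10, 10, focal_counts = c(10L, 10L)),
    site_one_divergent(lines10, 20, focal_counts = c(19L, 1L),
                       alt = "C"),
    {s <- site_one_divergent(lines10, 30, focal_counts = c(6L, 6L))
     s$counts$L05 <- c(7L, 3L); s}))
  # 19/1 does not reach the caller threshold; force the genotype so the
  # filter itself is exercised
  tab$sites[pos == 20L & line_id == "L01", gt := "0/1"]
  cand <- detect_candidates(tab)
  res <- binomial_consistency(tab, cand, alpha = 0.05, eps = 0.01)
  r10 <- res[res$pos == 10L, ]
  expect_true(r10$pass)
  expect_equal(r10$p_focal, 1.0)
  r20 <- res[res$pos == 20L, ]
  expect_false(r20$pass)
  expect_equal(r20$p_focal, 4.005432e-05, tolerance = 1e-6)
  # other line with 3 alt of 10 reads at eps = 0.01 kills the candidate
  r30 <- res[res$pos == 30L, ]
  expect_false(r30$pass)
  expect_equal(r30$p_others, 1.138e-4, tolerance = 1e-3)
  expect_true(r30$p_focal >= 0.05)
})

test_that("raising alpha never converts focal FAIL to PASS", {
  set.seed(42)
  for (rep in 1:30) {
    d <- sample(6:20, 1)
    k <- sample(0:d, 1)
    p <- binom_p_two_sided(k, d, 0.5)
    for (a_lo in c(0.01, 0.05)) {
      a_hi <- a_lo * 4
      if (p >= a_hi) expect_gte(p, a_lo)   # PASS at high stays PASS at low
      if (p < a_lo) expect_lt(p, a_hi)     # FAIL at low stays FAIL at high
    }
  }
})

test_that("Het-Hom single-site changes are routed out of the SNM set", {
  het_site <- function(pos, focal_counts, focal = "L01", alt2 = NULL) {
    counts <- setNames(rep(list(c(6L, 6L)), 10L), lines10)
    counts[[focal]] <- focal_counts
    list(pos = pos, ref = "A", alt = "C", alt2 = alt2, counts = counts)
  }
  tab <- mk_table(lines10, site_list = list(
    het_site(10, c(0L, 12L)),            # het -> hom-alt: loss
    het_site(20, c(12L, 0L)),            # het -> hom-ref: loss
    het_site(30, c(6L, 0L, 6L), alt2 = "G"),  # third allele: gain, kept
    site_one_divergent(lines10, 40, focal_counts = c(6L, 6L))))  # hom anc
  out <- call_mutations(tab)
  expect_setequal(out$het_hom$pos, c(10L, 20L))
  expect_setequal(out$calls$pos, c(30L, 40L))
  expect_equal(out$calls[pos == 40L, type], "AT>GC")
  expect_true(is.na(out$calls[pos == 30L, type]))  # no unique ancestral base
  expect_equal(out$calls[pos == 40L, zygosity], "het")
})

test_that("MNM grouping uses a 50 bp stretch per line", {
  snms <- data.table::data.table(
    line_id = c("A", "A", "A", "A", "B"),
    scaffold = "s1",
    pos = c(100L, 149L, 300L, 351L, 101L))
  g <- group_mnms(snms, window = 50L)
  expect_false(is.na(g[pos == 100L, mnm_group]))
  expect_equal(g[pos == 100L, mnm_group], g[pos == 149L, mnm_group])
  # span 52 -> two singletons
  expect_true(is.na(g[pos == 300L, mnm_group]))
  expect_true(is.na(g[pos == 351L, mnm_group]))
  # different line, adjacent positions: no group
  expect_true(is.na(g[line_id == "B", mnm_group]))
})

test_that("INDELs are called, size-bounded and shared-pattern filtered", {
  ind_site <- function(pos, ref, alt, in_lines = "L01") {
    counts <- setNames(rep(list(c(12L, 0L)), 10L), lines10)
    for (l in in_lines) counts[[l]] <- c(6L, 6L)
    list(pos = pos, ref = ref, alt = alt, counts = counts)
  }
  tab <- mk_table(lines10, scaffold_len = 2000L, site_list = list(
    ind_site(100, "ATTT", "A"),                        # 3 bp deletion
    ind_site(200, paste(rep("A", 61), collapse = ""), "A"),  # 60 bp
    ind_site(300, "G", "GTT", in_lines = c("L01", "L02"))))  # shared
  out <- call_mutations(tab)
  expect_equal(out$calls[class == "INDEL", pos], 100L)
  expect_equal(out$calls[class == "INDEL", indel_len], 3L)
  expect_equal(out$rejected[flag == "oversize_indel", pos], 200L)
  expect_false(300L %in% out$calls$pos)
  ind <- detect_indels(tab)
  expect_equal(ind$pos, 100L)
})

test_that("null tables give no calls; planted mutations are recovered", {
  cfg <- tiny_cfg(scaffold_lengths = 200000L, n_lines = 10L, seed = 51L)
  ex <- simulate_ma_experiment(cfg)
  out <- call_mutations(ex$table)
  expect_equal(nrow(out$calls), 0L)
  cfg2 <- tiny_cfg(scaffold_lengths = 200000L, n_lines = 10L,
                   mu_snm = 2e-6, seed = 52L)
  ex2 <- simulate_ma_experiment(cfg2)
  out2 <- call_mutations(ex2$table)
  expect_gt(nrow(out2$calls), 0L)
  # every call is planted (attributability)
  planted <- data.table::rbindlist(lapply(names(ex2$truth), function(l) {
    s <- ex2$truth[[l]]$snm
    data.table::data.table(line_id = l, scaffold = s$scaffold, pos = s$pos,
                           anc = s$anc_zygosity)
  }))
  expect_true(all(paste(out2$calls$line_id, out2$calls$pos) %in%
                    paste(planted$line_id, planted$pos)))
  # measured sensitivity on callable hom-ancestry sites agrees with the
  # analytic value
  ph <- planted[anc == "hom"]
  callable <- mamutkit:::site_callable_for(ex2$table, ph$scaffold, ph$pos,
                                           ph$line_id)
  n_callable <- sum(callable)
  p_hat <- sum(paste(out2$calls$line_id, out2$calls$pos) %in%
                 paste(ph$line_id[callable], ph$pos[callable])) / n_callable
  stats <- callable_stats(ex2$table)
  sens <- snm_detection_sensitivity(ex2$table, stats)
  p_exp <- mean(sens$sensitivity * sens$others_factor)
  expect_lt(abs(p_hat - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / n_callable))
})
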