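# Mutation-rate estimation and spectrum / treatment statistics.
#
# Rates are per base pair per generation with per-line callable sites C_i as
# denominators; the pooled rate is total mutations over the summed
# callable-site x generation products, identically the
# callable-generation-weighted mean of per-line rates.

#' Per-line SNM rate
#'
#' @param n mutation count
#' @param C callable sites (bp)
#' @param g generations
#' @return rate per bp per generation, `n / (C * g)`
#' @export
per_line_snm_rate <- function(n, C, g) {
  if (any(C <= 0) || any(g <= 0)) stopf("C and g must be positive")
  n / (C * g)
}

#' Pooled SNM rate with between-line uncertainty
#'
#' Pooled estimate `sum(n) / sum(C * g)` plus a normal-approximation 95%
#' confidence interval from the between-line SE of the
#' callable-generation-weighted per-line rates.
#'
#' @inheritParams per_line_snm_rate
#' @param C_eff optional per-line effective callable sites (sensitivity-
#'   corrected, see [snm_detection_sensitivity()]); adds an unbiased
#'   `rate_adj`
#' @return list: `rate`, `se`, `ci` (length 2), `per_line` rates, and
#'   `rate_adj` when `C_eff` is given
#' @export
pooled_snm_rate <- function(n, C, g, C_eff = NULL) {
  r <- per_line_snm_rate(n, C, g)
  w <- C * g
  pooled <- sum(n) / sum(w)
  # variance of the weighted mean from between-line scatter
  nl <- length(r)
  se <- if (nl > 1)
    sqrt(sum(w^2 * (r - pooled)^2) / sum(w)^2 * nl / (nl - 1)) else NA_real_
  out <- list(rate = pooled, se = se,
              ci = pooled + c(-1, 1) * qnorm(0.975) * se, per_line = r)
  if (!is.null(C_eff)) out$rate_adj <- sum(n) / sum(C_eff * g)
  out
}

#' Per-line and pooled LOH rates
#'
#' Three measures per line: events per generation, affected bp (sum of
#' average event sizes) per generation, and affected bp per callable bp per
#' generation.
#'
#' @param events LOH event table (needs `line_id`, `avg_size`)
#' @param summary per-line table with `line_id`, `generations`,
#'   `callable_loh_bp`
#' @return list: `per_line` data.table and `pooled` (events/gen, bp/gen,
#'   per-bp-per-gen, plus per-line means and SDs)
#' @export
loh_rates <- function(events, summary) {
  ev <- data.table::as.data.table(events)
  s <- data.table::as.data.table(summary)
  agg <- if (nrow(ev)) ev[, .(n_events = .N, bp = sum(avg_size)),
                          by = line_id] else
    data.table::data.table(line_id = character(), n_events = integer(),
                           bp = numeric())
  per <- merge(s, agg, by = "line_id", all.x = TRUE)
  per[is.na(n_events), n_events := 0L]
  per[is.na(bp), bp := 0]
  per[, `:=`(events_per_gen = n_events / generations,
             bp_per_gen = bp / generations,
             rate_per_bp_gen = bp / (callable_loh_bp * generations))]
  pooled <- list(
    events_per_gen = sum(per$n_events) / sum(per$generations),
    bp_per_gen = sum(per$bp) / sum(per$generations),
    rate_per_bp_gen = sum(per$bp) /
      sum(per$callable_loh_bp * per$generations),
    mean_events_per_gen = mean(per$events_per_gen),
    sd_events_per_gen = sd(per$events_per_gen),
    mean_bp_per_gen = mean(per$bp_per_gen),
    sd_bp_per_gen = sd(per$bp_per_gen),
    mean_rate_per_bp_gen = mean(per$rate_per_bp_gen),
    sd_rate_per_bp_gen = sd(per$rate_per_bp_gen))
  list(per_line = per[], pooled = pooled)
}

#' Spectrum uniformity test corrected for AT content
#'
#' Tests whether the six collapsed substitution types occur equally often
#' once the genome's AT:GC composition is accounted for: each A:T-origin
#' type expects `total * at_frac / 3` events, each G:C-origin type
#' `total * (1 - at_frac) / 3`. Pearson chi-squared with df = 5.
#'
#' @param counts named counts over [MUT_TYPES] (missing types count 0)
#' @param at_frac AT fraction of the callable genome (e.g. 0.5818)
#' @return list: `statistic`, `df`, `p_value`, `observed`, `expected`
#' @export
spectrum_test <- function(counts, at_frac) {
  stopifnot(at_frac > 0, at_frac < 1)
  obs <- setNames(numeric(6), MUT_TYPES)
  counts <- counts[!is.na(names(counts))]
  obs[names(counts)] <- counts
  total <- sum(obs)
  if (total == 0) stopf("no mutations to test")
  expd <- total * rep(c(at_frac, 1 - at_frac), each = 3) / 3
  if (any(expd == 0)) stopf("zero expected count")
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat, df = 5L, p_value = pchisq(stat, 5, lower.tail = FALSE),
       observed = obs, expected = expd)
}

#' Spectrum homogeneity across treatments
#'
#' Standard contingency chi-squared on the 6 x T table of type counts by
#' treatment; df = 5 * (T - 1) (15 for four treatments).
#'
#' @param counts_by_treatment 6 x T matrix or table (rows = types)
#' @return list: `statistic`, `df`, `p_value`
#' @export
spectrum_homogeneity <- function(counts_by_treatment) {
  m <- as.matrix(counts_by_treatment)
  keep <- colSums(m) > 0
  if (!all(keep)) {
    warnf("dropping %d empty treatment column(s)", sum(!keep))
    m <- m[, keep, drop = FALSE]
  }
  if (ncol(m) < 2L) stopf("need >= 2 non-empty treatments")
  expd <- outer(rowSums(m), colSums(m)) / sum(m)
  nz <- expd > 0
  stat <- sum((m[nz] - expd[nz])^2 / expd[nz])
  df <- (sum(rowSums(m) > 0) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Percent of SNMs inside multinucleotide mutations
#'
#' @param snms SNM call table with `mnm_group`
#' @return list: `percent`, `n_in_mnm`, `n_total`, `n_groups`
#' @export
mnm_fraction <- function(snms) {
  n <- nrow(snms)
  if (n == 0L) return(list(percent = NA_real_, n_in_mnm = 0L, n_total = 0L,
                           n_groups = 0L, flag = "no_snms"))
  k <- sum(!is.na(snms$mnm_group))
  list(percent = 100 * k / n, n_in_mnm = k, n_total = n,
       n_groups = data.table::uniqueN(stats::na.omit(snms$mnm_group)))
}

#' Treatment effect on per-line rates
#'
#' One-way ANOVA where residual normality holds (Shapiro-Wilk at
#' `normality_alpha`), otherwise Kruskal-Wallis; either can be forced.
#'
#' @param rates numeric per-line rates
#' @param treatment factor of the same length
#' @param test "auto", "anova" or "kruskal"
#' @param normality_alpha gate level for the auto choice (default 0.05)
#' @return list: `method`, `statistic`, `df` (ANOVA: c(df1, df2)),
#'   `p_value`, and for auto the `shapiro_p`
#' @export
treatment_rate_tests <- function(rates, treatment,
                                 test = c("auto", "anova", "kruskal"),
                                 normality_alpha = 0.05) {
  test <- match.arg(test)
  treatment <- factor(treatment)
  if (nlevels(treatment) < 2L) stopf("need >= 2 treatments")
  shp <- NA_real_
  if (test != "kruskal") {
    if (any(table(treatment) < 2L)) {
      if (test == "anova") stopf("singleton treatment group under ANOVA")
      test <- "kruskal"
    }
  }
  if (test == "auto") {
    fit0 <- aov(rates ~ treatment)
    shp <- tryCatch(shapiro.test(stats::residuals(fit0))$p.value,
                    error = function(e) 0)
    test <- if (shp >= normality_alpha) "anova" else "kruskal"
  }
  if (test == "anova") {
    fit <- aov(rates ~ treatment)
    s <- summary(fit)[[1]]
    list(method = "anova", statistic = s$`F value`[1],
         df = c(s$Df[1], s$Df[2]), p_value = s$`Pr(>F)`[1], shapiro_p = shp)
  } else {
    kt <- kruskal.test(rates, treatment)
    list(method = "kruskal", statistic = unname(kt$statistic),
         df = unname(kt$parameter), p_value = kt$p.value, shapiro_p = shp)
  }
}

#' Chance of k independent events sharing one chromosome
#'
#' `(1/n)^(k-1)`: the first event lands anywhere, each further event matches
#' its chromosome with probability 1/n.
#'
#' @param k number of events (>= 1)
#' @param n number of chromosomes (>= 1)
#' @return probability
#' @export
chance_same_chromosome <- function(k, n) {
  stopifnot(k >= 1, n >= 1)
  (1 / n)^(k - 1)
}

#' Expected count of true Het-Hom point mutations
#'
#' `mu * het_frac * total_callable_line_generations * allele_factor`; the
#' allele-target factor (default 1/3) is the chance a point mutation at a
#' heterozygous site hits the allele that makes it look homozygous.
#'
#' @param mu SNM rate per bp per generation
#' @param het_frac ancestral heterozygosity
#' @param total_cg summed callable-bp x generations over lines
#' @param allele_factor allele-target factor (default 1/3)
#' @return expected count
#' @export
expected_het_hom_snms <- function(mu, het_frac, total_cg,
                                  allele_factor = 1 / 3) {
  stopifnot(mu >= 0, het_frac >= 0, total_cg >= 0, allele_factor >= 0)
  mu * het_frac * total_cg * allele_factor
}

#' Regression of per-line rate on generation number
#'
#' @param rates per-line rates
#' @param generations per-line generations
#' @return list: `slope`, `intercept`, `F`, `df`, `p_value`, `r_squared`
#' @export
rate_vs_generations <- function(rates, generations) {
  if (length(rates) < 3L) stopf("need >= 3 lines")
  if (length(unique(generations)) < 2L) stopf("generations are constant")
  fit <- lm(rates ~ generations)
  s <- summary(fit)
  fs <- s$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = unname(fs[1]), df = unname(fs[2:3]),
       p_value = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       r_squared = s$r.squared)
}

#' Spectrum counts by treatment
#'
#' @param snms SNM calls with `type` and `line_id`
#' @param meta line metadata (`line_id`, `treatment`)
#' @return 6 x T matrix of counts
#' @export
spectrum_counts <- function(snms, meta) {
  dt <- data.table::as.data.table(snms)
  dt <- dt[!is.na(type)]
  dt[, treatment := meta$treatment[match(line_id, meta$line_id)]]
  tab <- table(factor(dt$type, levels = MUT_TYPES), dt$treatment)
  unclass(tab)
}

#' AT fraction of the callable genome
#'
#' Composition of reference bases over a line's SNM-callable intervals,
#' averaged across lines.
#'
#' @param genome ancestral genome
#' @param masks [callable_masks()] list
#' @return AT fraction in (0,1)
#' @export
callable_at_fraction <- function(genome, masks) {
  fr <- vapply(masks, function(m) {
    at <- tot <- 0
    for (sc in names(genome$scaffolds)) {
      iv <- m$snm[[sc]]
      if (is.null(iv) || nrow(iv) == 0L) next
      refc <- genome$scaffolds[[sc]]$ref
      for (j in seq_len(nrow(iv))) {
        seg <- refc[(iv$start[j] + 1L):iv$end[j]]
        at <- at + sum(seg == 1L | seg == 4L)
        tot <- tot + length(seg)
      }
    }
    if (tot == 0) NA_real_ else at / tot
  }, 0)
  mean(fr, na.rm = TRUE)
}
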