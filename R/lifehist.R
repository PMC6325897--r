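# Life-history analysis: partial life tables, the intrinsic rate of
# increase r (Euler-Lotka root, cross-validated by stochastic projection),
# mutational bias by anchored weighted regression, and variance-component
# based mutational parameters (CV_m, dCV_m, V_M/V_E, broad-sense H2).

#' Build a partial life table from subline records
#'
#' Survivorship l_x is the fraction of sublines alive at age x (l_0 = 1);
#' fecundity m_x is the mean clutch size released at age x among sublines
#' alive then. Ages beyond the fourth clutch are truncated (partial table).
#'
#' @param records life-history rows (one or more sublines of a line); needs
#'   `clutch_age_1..4`, `clutch_size_1..4`, `longevity`,
#'   `survived_to_assay`
#' @return object of class `life_table`: data.frame with `x`, `lx`, `mx`
#' @export
build_life_table <- function(records) {
  rec <- data.table::as.data.table(records)
  rec <- rec[survived_to_assay == TRUE]
  if (nrow(rec) == 0L) stopf("no surviving sublines with data")
  ages <- unlist(rec[, paste0("clutch_age_", 1:4), with = FALSE])
  sizes <- unlist(rec[, paste0("clutch_size_", 1:4), with = FALSE])
  keep <- !is.na(ages) & !is.na(sizes)
  if (!any(keep)) stopf("no clutch data")
  ages <- ages[keep]; sizes <- sizes[keep]
  long <- rep(rec$longevity, 4L)[keep]
  x <- sort(unique(ages))
  n <- nrow(rec)
  lx <- vapply(x, function(a) sum(rec$longevity >= a) / n, 0)
  mx <- vapply(x, function(a) {
    alive <- long >= a & ages == a
    if (!any(alive)) 0 else sum(sizes[alive]) / sum(rec$longevity >= a)
  }, 0)
  out <- data.frame(x = x, lx = lx, mx = mx)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Intrinsic rate of increase from a life table
#'
#' `method = "euler-lotka"` finds the unique root of
#' `sum_x exp(-r x) l_x m_x = 1` by bracketed root finding (residual below
#' 1e-10). `method = "projection"` runs a stochastic age-structured
#' projection (Poisson births, binomial survival) and returns the mean log
#' growth rate after burn-in; it converges to the Euler-Lotka root and is
#' provided as an independent cross-check.
#'
#' @param table a [build_life_table()] result (or data.frame with x, lx, mx)
#' @param method "euler-lotka" or "projection"
#' @param n0,burn,steps,cap projection controls: initial cohort, burn-in
#'   steps, measured steps, population cap (multinomial thinning)
#' @param seed seed for the projection method
#' @return r, in inverse units of `x`
#' @export
solve_r <- function(table, method = c("euler-lotka", "projection"),
                    n0 = 500L, burn = 30L, steps = 120L, cap = 20000L,
                    seed = 1L) {
  method <- match.arg(method)
  R0 <- sum(table$lx * table$mx)
  if (R0 <= 0) stopf("no growth: sum(lx * mx) <= 0")
  if (method == "euler-lotka") {
    f <- function(r) sum(exp(-r * table$x) * table$lx * table$mx) - 1
    lo <- -20; hi <- 20
    while (f(hi) > 0) hi <- hi * 2
    while (f(lo) < 0) lo <- lo * 2
    root <- uniroot(f, c(lo, hi), tol = 1e-14)$root
    if (abs(f(root)) > 1e-10) stopf("root polish failed")
    return(root)
  }
  project_r(table, n0, burn, steps, cap, seed)
}

# stochastic Leslie-style projection on the integer age grid
project_r <- function(table, n0, burn, steps, cap, seed) {
  x <- table$x
  if (any(x != round(x))) stopf("projection needs integer ages")
  amax <- max(x)
  lx_full <- approx_lx(table, amax)
  sx <- c(lx_full[-1] / lx_full[-length(lx_full)], 0)  # survival age a->a+1
  sx[!is.finite(sx)] <- 0
  mx_full <- numeric(amax + 1L)
  mx_full[x + 1L] <- table$mx
  with_seed(seed, {
    n <- integer(amax + 1L)
    n[1] <- n0
    loggrowth <- 0
    measured <- 0L
    for (t in seq_len(burn + steps)) {
      # survive/age first, then reproduce from the aged survivors: an
      # individual born at t first breeds exactly x steps later, matching
      # the discrete Euler-Lotka timing
      older <- rbinom(length(sx), n, pmin(1, sx))
      n_new <- integer(amax + 1L)
      if (amax >= 1L) n_new[2:(amax + 1L)] <- older[1:amax]
      n_new[1] <- sum(rpois(length(n_new), n_new * mx_full))
      tot_old <- sum(n); tot_new <- sum(n_new)
      if (tot_new == 0L) { n_new[1] <- n0; tot_new <- n0 }  # restart
      else if (t > burn) {
        loggrowth <- loggrowth + log(tot_new / tot_old)
        measured <- measured + 1L
      }
      if (tot_new > cap) {   # thin, preserving expectation
        keep <- rbinom(length(n_new), n_new, cap / tot_new)
        n_new <- keep
      }
      n <- n_new
    }
    if (measured == 0L) stopf("projection never measured growth")
    loggrowth / measured
  })
}

# survivorship on the full 0..amax grid (step interpolation; l_0 = 1)
approx_lx <- function(table, amax) {
  lx <- numeric(amax + 1L)
  cur <- 1
  for (a in 0:amax) {
    hit <- which(table$x == a)
    if (length(hit)) cur <- table$lx[hit]
    lx[a + 1L] <- cur
  }
  lx
}

#' Per-subline intrinsic rates of increase
#'
#' @param life life-history table ([simulate_life_history()] layout)
#' @param method passed to [solve_r()]
#' @return data.table with one row per surviving subline: `line_id`,
#'   `subline_id`, `treatment`, `generations`, `r`
#' @export
subline_r <- function(life, method = "euler-lotka") {
  dt <- data.table::as.data.table(life)[survived_to_assay == TRUE]
  dt[, r := {
    lt <- build_life_table(.SD)
    solve_r(lt, method)
  }, by = subline_id]
  dt[, .(line_id, subline_id, treatment, generations, r)]
}

#' Mutational bias by anchored weighted regression
#'
#' Weighted least squares of trait change on generations, forced through
#' the non-MA anchor mean at generation zero: slope =
#' `sum(w g (y - a)) / sum(w g^2)` with weights `w = 1/SD` (the anchor
#' enters as a pseudo-observation at g = 0 weighted by 1/anchor_SD, which
#' contributes to the residual df but not to the slope). The bias is
#' standardized as percent of the anchor mean per generation.
#'
#' @param values per-line trait values (r or trait mean)
#' @param sds per-line subline SDs (weights are 1/SD); zero or missing SDs
#'   are replaced by the median of the positive SDs, with a warning
#' @param generations per-line generation numbers
#' @param anchor_mean,anchor_sd non-MA population mean and SD
#' @return list: `slope`, `se`, `t`, `df`, `p_value`, `dm_pct`
#'   (percent per generation), `dm_pct_se`
#' @export
delta_m <- function(values, sds, generations, anchor_mean, anchor_sd) {
  if (length(values) < 2L) stopf("need >= 2 lines")
  bad <- is.na(sds) | sds <= 0
  if (any(bad)) {
    repl <- median(sds[!bad])
    if (!is.finite(repl)) stopf("no usable subline SDs")
    warnf("replacing %d zero/missing SD(s) with the median SD", sum(bad))
    sds[bad] <- repl
  }
  w <- 1 / sds
  g <- generations
  y0 <- values - anchor_mean
  slope <- sum(w * g * y0) / sum(w * g^2)
  # weighted residuals; the anchor pseudo-observation has residual zero by
  # construction and contributes only to the df: (n + 1) obs - 1 parameter
  res <- y0 - slope * g
  rss <- sum(w * res^2)
  sigma2 <- rss / length(values)
  se <- sqrt(sigma2 / sum(w * g^2))
  tval <- slope / se
  list(slope = slope, se = se, t = tval, df = length(values),
       p_value = 2 * pt(-abs(tval), length(values)),
       dm_pct = 100 * slope / anchor_mean,
       dm_pct_se = 100 * se / abs(anchor_mean))
}

# one-way variance components from sublines grouped by line
variance_components <- function(values, line) {
  line <- factor(line)
  if (nlevels(line) < 2L) stopf("need >= 2 lines")
  fit <- aov(values ~ line)
  s <- summary(fit)[[1]]
  ms_a <- s$`Mean Sq`[1]; ms_w <- s$`Mean Sq`[2]
  ni <- as.numeric(table(line))
  N <- sum(ni); a <- length(ni)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  vl <- max(0, (ms_a - ms_w) / n0)
  list(ms_among = ms_a, ms_within = ms_w, n0 = n0, v_line = vl,
       grand_mean = mean(values), df = s$Df, F = s$`F value`[1],
       p_value = s$`Pr(>F)`[1])
}

#' Coefficient of mutational variation
#'
#' One-way ANOVA partitions subline values into among-line (mutational) and
#' within-line (environmental) variance; the among-line component
#' `(MS_among - MS_within)/n0` (standard unbalanced-design coefficient,
#' truncated at zero) is square-rooted and scaled by the grand mean.
#'
#' @param values subline trait values
#' @param line line id per subline
#' @param mean_generations mean generation number (for the per-generation
#'   rate dCV_m)
#' @return list: `cv_m` (%), `dcv_m` (%/gen), `v_line`, `ms_within`,
#'   `grand_mean`
#' @export
cv_m <- function(values, line, mean_generations) {
  vc <- variance_components(values, line)
  cv <- 100 * sqrt(vc$v_line) / vc$grand_mean
  list(cv_m = cv, dcv_m = cv / mean_generations, v_line = vc$v_line,
       ms_within = vc$ms_within, grand_mean = vc$grand_mean)
}

#' Mutational heritability V_M / V_E
#'
#' `V_M = V_L / (divisor * t)` (divisor 2 under the diploid MA convention;
#' configurable to 1 for the clonal convention) and `V_E = MS_within`.
#'
#' @inheritParams cv_m
#' @param t generations of accumulation
#' @param divisor 2 (default) or 1
#' @return list: `vm_ve`, `v_m`, `v_e`
#' @export
vm_ve <- function(values, line, t, divisor = 2) {
  vc <- variance_components(values, line)
  if (vc$ms_within == 0) return(list(vm_ve = NA_real_, v_m = NA_real_,
                                     v_e = 0, flag = "zero_VE"))
  vm <- vc$v_line / (divisor * t)
  list(vm_ve = vm / vc$ms_within, v_m = vm, v_e = vc$ms_within)
}

#' Broad-sense heritability
#'
#' `H2 = V_L / (V_L + MS_within)`, clipped to unit interval.
#'
#' @inheritParams cv_m
#' @return H2 in [0, 1]
#' @export
broad_sense_h2 <- function(values, line) {
  vc <- variance_components(values, line)
  denom <- vc$v_line + vc$ms_within
  if (denom == 0) return(1)
  min(1, max(0, vc$v_line / denom))
}

#' Treatment x generation interaction in the anchored regression
#'
#' Compares the common-slope anchored weighted regression against one slope
#' per treatment by a nested-model F test on weighted residuals.
#'
#' @inheritParams delta_m
#' @param treatment per-line treatment labels
#' @return list: `F`, `df`, `p_value`, per-treatment slopes
#' @export
treatment_interaction_test <- function(values, sds, generations, treatment,
                                       anchor_mean, anchor_sd) {
  treatment <- factor(treatment)
  if (nlevels(treatment) < 2L) stopf("need >= 2 treatments")
  if (any(table(treatment) < 2L)) stopf("treatment with < 2 lines")
  bad <- is.na(sds) | sds <= 0
  if (any(bad)) sds[bad] <- median(sds[!bad])
  w <- 1 / sds
  y0 <- values - anchor_mean
  g <- generations
  fit_r <- lm(y0 ~ 0 + g, weights = w)
  fit_f <- lm(y0 ~ 0 + treatment:g, weights = w)
  av <- anova(fit_r, fit_f)
  slopes <- stats::coef(fit_f)
  list(F = av$F[2], df = c(av$Df[2], av$Res.Df[2]),
       p_value = av$`Pr(>F)`[2],
       slopes = setNames(as.numeric(slopes),
                         sub("^treatment", "", names(slopes))))
}

#' Line divergence and variance homogeneity tests
#'
#' Within each treatment, a single-factor ANOVA of subline values on line
#' (with Tukey HSD post-hoc contrasts); across treatments, a Bartlett test
#' of homogeneity of variance on line means.
#'
#' @param values subline trait values
#' @param line,treatment groupings per subline
#' @return list: per-treatment `anova` results (F, df, p, tukey), and
#'   `bartlett` across treatments on line means
#' @export
divergence_and_variance_tests <- function(values, line, treatment) {
  dt <- data.table::data.table(v = values, line = factor(line),
                               tr = factor(treatment))
  per <- lapply(levels(dt$tr), function(tt) {
    d <- dt[tr == tt]
    d[, line := droplevels(line)]
    if (nlevels(d$line) < 2L) return(list(treatment = tt, flag = "one_line"))
    fit <- aov(v ~ line, data = d)
    s <- summary(fit)[[1]]
    list(treatment = tt, F = s$`F value`[1], df = s$Df,
         p_value = s$`Pr(>F)`[1],
         tukey = TukeyHSD(fit)$line)
  })
  names(per) <- levels(dt$tr)
  lm_means <- dt[, .(m = mean(v)), by = .(line, tr)]
  bt <- if (nlevels(droplevels(lm_means$tr)) >= 2L)
    bartlett.test(lm_means$m, droplevels(lm_means$tr)) else NULL
  list(per_treatment = per,
       bartlett = if (!is.null(bt))
         list(statistic = unname(bt$statistic), df = unname(bt$parameter),
              p_value = bt$p.value) else NULL)
}

#' Table-1-style mutational parameter estimates
#'
#' Runs the full life-history analysis for one trait: per-subline values
#' are aggregated per line, mutational bias (anchored weighted regression),
#' CV_m, dCV_m, V_M/V_E and broad-sense H2 are computed overall and per
#' treatment.
#'
#' @param sub data.table with `line_id`, `treatment`, `generations`, and a
#'   `value` column of subline trait values
#' @param anchor_label treatment label of the anchor population
#' @param vm_divisor passed to [vm_ve()]
#' @return list with `anchor`, `overall` and per-treatment estimate blocks
#' @export
mut_param_estimates <- function(sub, anchor_label = "nonMA",
                                vm_divisor = 2) {
  sub <- data.table::as.data.table(sub)
  anc <- sub[treatment == anchor_label]
  ma <- sub[treatment != anchor_label]
  if (nrow(anc) == 0L) stopf("no anchor population rows ('%s')", anchor_label)
  anchor_mean <- mean(anc$value)
  anchor_sd <- sd(anc$value)
  per_line <- ma[, .(value = mean(value), sd = sd(value),
                     generations = generations[1], treatment = treatment[1]),
                 by = line_id]
  block <- function(d, dl) {
    dm <- delta_m(dl$value, dl$sd, dl$generations, anchor_mean, anchor_sd)
    cv <- cv_m(d$value, d$line_id, mean(dl$generations))
    vv <- vm_ve(d$value, d$line_id, mean(dl$generations), vm_divisor)
    list(n_lines = nrow(dl), mean = mean(dl$value),
         mean_generations = mean(dl$generations),
         delta_m = dm, cv_m = cv$cv_m, dcv_m = cv$dcv_m,
         vm_ve = vv$vm_ve, H2 = broad_sense_h2(d$value, d$line_id))
  }
  out <- list(anchor = list(mean = anchor_mean, sd = anchor_sd,
                            n = nrow(anc)),
              overall = block(ma, per_line))
  for (tt in unique(ma$treatment))
    out[[tt]] <- block(ma[treatment == tt], per_line[treatment == tt])
  out
}
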