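# Analytic detection sensitivity of the SNM pipeline, and the
# sensitivity-corrected effective callable denominator.
#
# At 12.4x coverage the combination of an error-aware genotype caller
# (calibrated so error pileups essentially never produce a false call over
# ~2e7 site-line trials) and the exact-binomial consistency filters has a
# per-site detection probability for a true heterozygous mutation well below
# one (~0.76 at defaults). A rate computed over the raw callable-site count
# is biased low by exactly that factor. The standard remedy is to use the
# expected number of detectable sites as the denominator:
#   C_eff,i = sum over callable sites s of P(detect | depth_i(s))
# multiplied by the probability the non-focal lines do not spoil the
# candidate, and by (1 - ancestral heterozygosity) because ancestrally
# heterozygous sites are effectively blind for single-site SNM detection in
# this design. Every term is a closed-form function of the same thresholds
# the caller and filters use — nothing is fitted.

# P(true het mutation at a covered focal site is called and passes the
# focal-genotype filter), by read depth 0..dmax
det_prob_by_depth <- function(dmax, alpha = 0.05, eps = 0.01,
                              seq_error = 0.005, p_call = 2e-9) {
  e <- seq_error
  pa <- 0.5 * (1 - 2 * e / 3)           # per-read P(observed as the new allele)
  pref <- pa
  poth <- 2 * e / 3
  out <- numeric(dmax + 1L)
  for (d in seq_len(dmax)) {
    km <- min_alt_reads(d, seq_error, p_call)
    ks <- 0:d
    p2 <- binom_p_two_sided(ks, d, 0.5)
    # P(>= 2 reference reads | new-allele count k)
    pr2 <- ifelse(d - ks >= 2L,
                  1 - pbinom(1, pmax(d - ks, 0), pref / (pref + poth)), 0)
    hom_pass <- binom_p_lower(ks, d, 1 - eps) >= alpha
    pdet <- ifelse(ks >= km, pr2 * (p2 >= alpha) + (1 - pr2) * hom_pass, 0)
    out[d + 1L] <- sum(dbinom(ks, d, pa) * pdet)
  }
  out
}

# P(a non-focal, non-mutated line fails the error-consistency filter at a
# candidate site), by its read depth; depth 0 kills the candidate outright
spoil_prob_by_depth <- function(dmax, alpha = 0.05, eps = 0.01,
                                seq_error = 0.005) {
  eb <- seq_error / 3
  out <- numeric(dmax + 1L)
  out[1L] <- 1                           # "./." drops the candidate
  for (d in seq_len(dmax)) {
    ks <- 0:d
    fail <- binom_p_upper(ks, d, eps) < alpha
    out[d + 1L] <- sum(dbinom(ks, d, eb)[fail])
  }
  out
}

#' Analytic SNM detection sensitivity and effective callable sites
#'
#' Computes, per line, the mean probability that a true heterozygous
#' mutation at a callable site would survive the whole calling chain, and
#' the corresponding effective callable denominator.
#'
#' @param table a `site_call_table`
#' @param masks [callable_masks()] list (computed when missing)
#' @param alpha,eps filter parameters as used in [call_mutations()]
#' @param ancestral_het ancestral per-site heterozygosity (such sites are
#'   blind for single-site SNM detection); 0 disables the term
#' @param min_depth callable depth threshold
#' @return data.table per line: `line_id`, `C_snm`, `sensitivity` (focal
#'   detection probability), `others_factor` (probability no other line
#'   spoils the candidate), `C_eff`
#' @export
snm_detection_sensitivity <- function(table, masks = NULL, alpha = 0.05,
                                      eps = 0.01, ancestral_het = 0,
                                      min_depth = 6L) {
  if (is.null(masks) || is.null(masks[[1]]$depth_hist_callable))
    masks <- callable_masks(table, min_depth)
  ids <- table$lines$line_id
  se <- table$params$seq_error %||% 0.005
  pc <- table$params$p_call %||% 2e-9
  dmax <- length(masks[[1]]$depth_hist_callable) - 1L
  det <- det_prob_by_depth(dmax, alpha, eps, se, pc)
  spoil <- spoil_prob_by_depth(dmax, alpha, eps, se)
  # depth histograms: callable sites (focal term) and all sites (spoiler)
  S <- qbar <- numeric(length(ids))
  for (i in seq_along(ids)) {
    hc <- masks[[ids[i]]]$depth_hist_callable
    hall <- masks[[ids[i]]]$depth_hist_all
    S[i] <- if (sum(hc) > 0) sum(hc * det) / sum(hc) else 0
    qbar[i] <- sum(hall * spoil) / sum(hall)
  }
  others <- vapply(seq_along(ids), function(i)
    prod(1 - qbar[-i]), 0)
  C <- vapply(ids, function(l) masks[[l]]$C_snm, 0)
  data.table::data.table(
    line_id = ids, C_snm = C, sensitivity = S, others_factor = others,
    C_eff = C * S * others * (1 - ancestral_het))
}
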