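# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats aov anova bartlett.test dbinom kruskal.test lm pbinom
#'   pchisq pf pt qnorm rbinom rnorm rpois runif sd shapiro.test TukeyHSD
#'   uniroot var median setNames
#' @importFrom utils modifyList packageVersion
NULL

BASES <- c("A", "C", "G", "T")

# complement under the 1..4 encoding (A=1,C=2,G=3,T=4)
comp_code <- function(x) 5L - x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seeds derived from a master seed; kept under 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %%
               2147483647)
}

# small polynomial string hash (deterministic across sessions)
str_hash <- function(x) {
  v <- utf8ToInt(x)
  as.integer(sum(v * 31^(seq_along(v) - 1)) %% 1e6)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

## ---- exact binomial tail helpers -----------------------------------------
## These are the single shared implementation of the filtering arithmetic;
## tests check them against brute-force enumeration.

# two-sided exact binomial p for H0: p = p0, as twice the smaller tail
# (capped at 1); at p0 = 0.5 this equals the symmetric tail probability.
binom_p_two_sided <- function(k, n, p0 = 0.5) {
  lo <- pbinom(k, n, p0)
  hi <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

# upper-tail exact p: P(X >= k | n, p0)
binom_p_upper <- function(k, n, p0) {
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

# lower-tail exact p: P(X <= k | n, p0)
binom_p_lower <- function(k, n, p0) {
  pbinom(k, n, p0)
}

#' Minimum alt-read support for a non-reference genotype call
#'
#' Smallest read count `k` such that `k` or more identical miscalls at one
#' site in one line is rarer than `p_call` under a per-read error rate
#' `seq_error` (miscalls spread uniformly over the three non-template bases).
#' `p_call` is calibrated genome-wide: at the default 2e-9, the expected
#' number of error-born non-reference genotypes over ~2e7 site-line pairs is
#' well below one, emulating the joint effect of a quality-aware caller and
#' strict downstream filtering.
#'
#' @param depth integer vector of read depths
#' @param seq_error per-read miscall probability
#' @param p_call per-site-line false-call budget
#' @return integer vector, same length as `depth`
#' @export
min_alt_reads <- function(depth, seq_error = 0.005, p_call = 2e-9) {
  eb <- seq_error / 3
  dmax <- max(depth, 1L)
  # threshold per unique depth 0..dmax, then index
  thr <- integer(dmax + 1L)            # thr[d + 1] = k_min(d)
  thr[1L] <- 1L                        # depth 0: no call possible
  for (d in seq_len(dmax)) {
    k <- 1L
    while (k <= d && 3 * binom_p_upper(k, d, eb) > p_call) k <- k + 1L
    thr[d + 1L] <- k
  }
  thr[depth + 1L]
}
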