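#' Configuration of a synthetic mutation-accumulation experiment
#'
#' Builds and validates the parameter set that drives the synthetic-data
#' generator. Defaults reproduce the design of a metal-exposure MA experiment
#' in *Daphnia pulex*: a diploid ancestor with 0.7% per-site heterozygosity,
#' four treatments (28 control lines at 82.3 +/- 4.7 generations; 9 lines each
#' for Ni, Cu and Ni+Cu at 120.5 +/- 10.4 generations), 12.4x mean read
#' coverage, an SNM rate of 1.61e-9 per site per generation and an LOH rate of
#' 0.012 events per line per generation.
#'
#' Rates are per diploid site per generation (a site is counted once, not per
#' haploid copy), matching the pooled-rate arithmetic used downstream.
#'
#' @param n_scaffolds number of scaffolds
#' @param scaffold_lengths integer vector of scaffold lengths (bp); recycled
#'   to `n_scaffolds`
#' @param n_chromosomes chromosomes the scaffolds map onto (round-robin)
#' @param ancestral_het per-site probability the ancestor is heterozygous
#' @param treatments data.frame with columns `treatment`, `n_lines`,
#'   `gen_mean`, `gen_sd`, `multiplier` (per-treatment mutation-rate factor)
#' @param mu_snm SNM rate, per site per generation
#' @param spectrum_weights six non-negative weights over the collapsed
#'   substitution types AT>CG, AT>GC, AT>TA, GC>AT, GC>CG, GC>TA
#' @param mu_indel small-INDEL rate, per site per generation
#' @param p_mnm probability an SNM event is a multinucleotide cluster
#' @param loh_rate LOH events per line per generation
#' @param loh_size_dist length-2 log-uniform size bounds (bp), lower >= 1
#' @param p_conversion probability an LOH event is gene-conversion-like
#'   (copy-neutral) rather than a hemizygous deletion
#' @param mean_coverage mean reads per site per line (Poisson)
#' @param seq_error per-read miscall probability
#' @param p_call per-site-line false-call budget of the emulated genotype
#'   caller (see [min_alt_reads()])
#' @param trait_anchor mean intrinsic rate of increase (r, per brood interval)
#'   of the non-MA anchor population
#' @param size_anchor mean body size (mm) of the anchor population
#' @param delta_true true proportional trait change per generation
#' @param vm_true mutational (among-line) variance input per generation, on
#'   the r scale
#' @param ve_true within-line environmental variance, on the r scale
#' @param n_sublines sublines measured per line in the life-history assay
#' @param n_anchor_lines lines of the non-MA anchor population
#' @param subline_survival probability a subline survives to measurement
#' @param seed integer master seed; all generator stages derive from it
#' @return an object of class `sim_config`
#' @export
#' @examples
#' cfg <- sim_config(scaffold_lengths = 1e5, treatments = ma_treatments(
#'   n_lines = c(4, 4), gen_mean = c(80, 120), labels = c("Control", "Ni")))
sim_config <- function(n_scaffolds = 5L,
                       scaffold_lengths = 200000L,
                       n_chromosomes = 12L,
                       ancestral_het = 0.007,
                       treatments = ma_treatments(),
                       mu_snm = 1.61e-9,
                       spectrum_weights = c(1, 2, 1, 6, 1, 2),
                       mu_indel = 4e-11,
                       p_mnm = 0.016,
                       loh_rate = 0.012,
                       loh_size_dist = c(250, 5e5),
                       p_conversion = 0.5,
                       mean_coverage = 12.4,
                       seq_error = 0.005,
                       p_call = 2e-9,
                       trait_anchor = 1.30,
                       size_anchor = 2.46,
                       delta_true = -1e-4,
                       vm_true = 5e-5,
                       ve_true = 1.3e-3,
                       n_sublines = 5L,
                       n_anchor_lines = 10L,
                       subline_survival = 0.95,
                       seed = 1L) {
  scaffold_lengths <- as.integer(rep_len(scaffold_lengths, n_scaffolds))
  cfg <- list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_lengths = scaffold_lengths,
    n_chromosomes = as.integer(n_chromosomes),
    ancestral_het = ancestral_het,
    treatments = as.data.frame(treatments),
    mu_snm = mu_snm, spectrum_weights = as.numeric(spectrum_weights),
    mu_indel = mu_indel, p_mnm = p_mnm,
    loh_rate = loh_rate, loh_size_dist = as.numeric(loh_size_dist),
    p_conversion = p_conversion,
    mean_coverage = mean_coverage, seq_error = seq_error, p_call = p_call,
    trait_anchor = trait_anchor, size_anchor = size_anchor,
    delta_true = delta_true, vm_true = vm_true, ve_true = ve_true,
    n_sublines = as.integer(n_sublines),
    n_anchor_lines = as.integer(n_anchor_lines),
    subline_survival = subline_survival,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Treatment layout helper
#'
#' @param labels treatment labels
#' @param n_lines lines per treatment
#' @param gen_mean,gen_sd per-treatment generation number (normal, truncated
#'   at 1 when lines are drawn)
#' @param multiplier per-treatment mutation-rate multipliers
#' @return data.frame consumed by [sim_config()]
#' @export
ma_treatments <- function(labels = c("Control", "Ni", "Cu", "NiCu"),
                          n_lines = c(28L, 9L, 9L, 9L),
                          gen_mean = c(82.3, 120.5, 120.5, 120.5),
                          gen_sd = c(4.7, 10.4, 10.4, 10.4),
                          multiplier = 1) {
  data.frame(treatment = labels,
             n_lines = as.integer(rep_len(n_lines, length(labels))),
             gen_mean = rep_len(gen_mean, length(labels)),
             gen_sd = rep_len(gen_sd, length(labels)),
             multiplier = rep_len(multiplier, length(labels)),
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_scaffolds < 1L) stopf("need at least one scaffold")
  if (any(!is.finite(cfg$scaffold_lengths)) || any(cfg$scaffold_lengths < 1L))
    stopf("scaffold lengths must be positive")
  probs <- c(ancestral_het = cfg$ancestral_het, p_mnm = cfg$p_mnm,
             p_conversion = cfg$p_conversion, seq_error = cfg$seq_error,
             subline_survival = cfg$subline_survival)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stopf("probabilities outside [0,1]: %s",
                      paste(names(probs)[bad], collapse = ", "))
  rates <- c(mu_snm = cfg$mu_snm, mu_indel = cfg$mu_indel,
             loh_rate = cfg$loh_rate, mean_coverage = cfg$mean_coverage,
             vm_true = cfg$vm_true, ve_true = cfg$ve_true)
  bad <- rates < 0
  if (any(bad)) stopf("rates must be >= 0: %s",
                      paste(names(rates)[bad], collapse = ", "))
  if (length(cfg$spectrum_weights) != 6L || any(cfg$spectrum_weights < 0) ||
      all(cfg$spectrum_weights == 0))
    stopf("spectrum_weights must be 6 non-negative values, not all zero")
  if (length(cfg$loh_size_dist) != 2L || cfg$loh_size_dist[1] < 1 ||
      diff(cfg$loh_size_dist) < 0)
    stopf("loh_size_dist must be increasing bounds with lower bound >= 1 bp")
  tr <- cfg$treatments
  need <- c("treatment", "n_lines", "gen_mean", "gen_sd", "multiplier")
  if (!all(need %in% names(tr)))
    stopf("treatments must have columns %s", paste(need, collapse = ", "))
  if (any(tr$n_lines < 1L) || any(tr$gen_mean <= 0) || any(tr$multiplier < 0))
    stopf("invalid treatment table")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d scaffold(s), %s bp total, het %.4g, coverage %.3gx\n",
    x$n_scaffolds, format(sum(x$scaffold_lengths), big.mark = ","),
    x$ancestral_het, x$mean_coverage))
  cat(sprintf("  mu_snm %.3g, mu_indel %.3g, loh_rate %.3g/gen, seed %d\n",
              x$mu_snm, x$mu_indel, x$loh_rate, x$seed))
  cat(sprintf("  treatments: %s\n", paste(
    sprintf("%s(n=%d, g=%.1f)", x$treatments$treatment,
            x$treatments$n_lines, x$treatments$gen_mean), collapse = ", ")))
  invisible(x)
}

#' Line metadata implied by a configuration
#'
#' Draws per-line generation numbers (normal, truncated at 1) and assigns
#' line ids and treatments. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return data.table with `line_id`, `treatment`, `generations`, `multiplier`
#' @export
line_metadata <- function(cfg) {
  tr <- cfg$treatments
  with_seed(child_seed(cfg$seed, 101L), {
    out <- lapply(seq_len(nrow(tr)), function(i) {
      g <- pmax(1, rnorm(tr$n_lines[i], tr$gen_mean[i], tr$gen_sd[i]))
      data.table::data.table(treatment = tr$treatment[i], generations = g,
                             multiplier = tr$multiplier[i])
    })
    meta <- data.table::rbindlist(out)
    meta[, line_id := sprintf("L%03d", seq_len(.N))]
    data.table::setcolorder(meta, c("line_id", "treatment", "generations",
                                    "multiplier"))
    meta[]
  })
}
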