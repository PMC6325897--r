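# Forward simulation of the mutation classes measured by the pipeline:
# SNMs (with MNM clustering), small INDELs, and LOH events.

# draw derived alleles for SNMs given ancestral base codes, honoring the
# 6-class spectrum weights; `exclude` (optional) is a base code that the
# derived allele must also avoid (the other allele at heterozygous sites)
draw_derived <- function(anc, weights, exclude = NULL) {
  n <- length(anc)
  out <- integer(n)
  # canonical strand: ancestral A or G
  flip <- anc %in% c(4L, 2L)
  anc2 <- ifelse(flip, comp_code(anc), anc)
  for (i in seq_len(n)) {
    if (anc2[i] == 1L) {               # A origin: A>C, A>G, A>T
      cand <- c(2L, 3L, 4L); w <- weights[1:3]
    } else {                           # G origin: G>A, G>C, G>T
      cand <- c(1L, 2L, 4L); w <- weights[4:6]
    }
    der2 <- cand
    der <- ifelse(rep(flip[i], 3L), comp_code(der2), der2)
    if (!is.null(exclude) && !is.na(exclude[i])) {
      keep <- der != exclude[i]
      der <- der[keep]; w <- w[keep]
    }
    if (sum(w) <= 0) w <- rep(1, length(w))
    out[i] <- der[sample.int(length(der), 1L, prob = w)]
  }
  out
}

#' Simulate the mutations accumulated by one MA line
#'
#' Plants SNMs (a fraction of which arrive as multinucleotide clusters within
#' a 50 bp window), small INDELs (1-10 bp) and LOH events on the ancestral
#' genome. Counts are Poisson with means `mu_snm * L * g`, `mu_indel * L * g`
#' and `loh_rate * g` (per-treatment multipliers applied to all three); rates
#' are per diploid site per generation. LOH spans are drawn log-uniform
#' between `cfg$loh_size_dist`, clipped to the scaffold, and re-drawn until
#' they overlap at least one ancestrally heterozygous site, so every event is
#' in principle discoverable from Het-Hom patterns.
#'
#' @param genome an [generate_ancestor()] result
#' @param line_meta single row of [line_metadata()] (needs `line_id`,
#'   `generations`, `multiplier`)
#' @param cfg the [sim_config()]
#' @return list with data.tables `snm`, `indel`, `loh` (a per-line truth set)
#' @export
simulate_line_mutations <- function(genome, line_meta, cfg) {
  g <- line_meta$generations
  if (g <= 0) stopf("generations must be positive")
  mult <- line_meta$multiplier %||% 1
  L <- genome_length(genome)
  with_seed(child_seed(cfg$seed, 1000L + str_hash(line_meta$line_id)), {
    snm <- sim_snms(genome, L, g * mult, cfg)
    indel <- sim_indels(genome, L, g * mult, cfg)
    loh <- sim_loh(genome, g * mult, cfg)
    list(snm = snm, indel = indel, loh = loh)
  })
}

sim_snms <- function(genome, L, geff, cfg) {
  n_target <- rpois(1L, cfg$mu_snm * L * geff)
  rows <- list(); gid <- 0L; n_placed <- 0L
  scaff_names <- names(genome$scaffolds)
  while (n_placed < n_target) {
    is_mnm <- runif(1) < cfg$p_mnm
    k <- if (is_mnm) sample(c(2L, 3L), 1L, prob = c(0.6, 0.4)) else 1L
    k <- min(k, n_target - n_placed + ifelse(is_mnm, 1L, 0L))
    if (k < 2L) is_mnm <- FALSE
    gpos <- sample(L, 1L)
    loc <- global_to_scaffold(genome, gpos)
    sc <- genome$scaffolds[[loc$scaffold]]
    if (is_mnm) {
      anchor <- min(loc$pos, sc$length - 49L)
      if (anchor < 1L) anchor <- 1L
      span <- min(49L, sc$length - anchor)
      pos <- anchor + sort(sample(0:span, k))
    } else pos <- loc$pos
    hp <- match(pos, sc$het_pos)
    anc1 <- sc$ref[pos]
    anc2 <- ifelse(is.na(hp), anc1, sc$het_alt[pmax(hp, 1L)])
    # mutate one homolog chosen at random
    homolog <- sample.int(2L, length(pos), replace = TRUE)
    anc_base <- ifelse(homolog == 1L, anc1, anc2)
    excl <- ifelse(homolog == 1L, anc2, anc1)
    der <- draw_derived(anc_base, cfg$spectrum_weights,
                        exclude = ifelse(excl == anc_base, NA_integer_, excl))
    der[!is.na(excl) & der == excl] <- NA_integer_   # safety; never expected
    if (is_mnm) gid <- gid + 1L
    rows[[length(rows) + 1L]] <- data.table::data.table(
      scaffold = scaff_names[loc$scaffold], pos = pos,
      anc1 = anc1, anc2 = anc2, derived = der,
      anc_zygosity = ifelse(is.na(hp), "hom", "het"),
      from_allele = homolog,
      type = mut_type(anc_base, der),
      mnm_group = if (is_mnm) gid else NA_integer_)
    n_placed <- n_placed + length(pos)
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(scaffold = character(), pos = integer(),
                           anc1 = integer(), anc2 = integer(),
                           derived = integer(), anc_zygosity = character(),
                           from_allele = integer(), type = character(),
                           mnm_group = integer())
  unique(out, by = c("scaffold", "pos"))
}

sim_indels <- function(genome, L, geff, cfg) {
  n <- rpois(1L, cfg$mu_indel * L * geff)
  if (n == 0L)
    return(data.table::data.table(scaffold = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  indel_len = integer(), kind = character()))
  gpos <- sample(L, n)
  loc <- global_to_scaffold(genome, gpos)
  scaff_names <- names(genome$scaffolds)
  len <- sample(1:10, n, replace = TRUE, prob = 0.5^(1:10))
  kind <- sample(c("ins", "del"), n, replace = TRUE)
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    sc <- genome$scaffolds[[loc$scaffold[i]]]
    p <- min(loc$pos[i], sc$length - len[i])  # room for deleted bases
    loc$pos[i] <- max(1L, p)
    base <- BASES[sc$ref[loc$pos[i]]]
    if (kind[i] == "del") {
      tail_codes <- sc$ref[(loc$pos[i] + 1L):(loc$pos[i] + len[i])]
      ref[i] <- paste0(base, paste(BASES[tail_codes], collapse = ""))
      alt[i] <- base
    } else {
      ref[i] <- base
      alt[i] <- paste0(base, paste(BASES[sample.int(4L, len[i],
                                                    replace = TRUE)],
                                   collapse = ""))
    }
  }
  data.table::data.table(scaffold = scaff_names[loc$scaffold], pos = loc$pos,
                         ref = ref, alt = alt, indel_len = len, kind = kind)
}

sim_loh <- function(genome, geff, cfg) {
  n <- rpois(1L, cfg$loh_rate * geff)
  cols <- data.table::data.table(scaffold = character(), start = integer(),
                                 end = integer(), mechanism = character(),
                                 retained = integer())
  if (n == 0L) return(cols)
  lens <- vapply(genome$scaffolds, function(s) s$length, 0L)
  scaff_names <- names(genome$scaffolds)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      s <- sample(length(lens), 1L, prob = lens)
      size <- round(exp(runif(1, log(cfg$loh_size_dist[1]),
                              log(cfg$loh_size_dist[2]))))
      size <- min(size, lens[s])
      start <- sample(lens[s] - size + 1L, 1L)
      end <- start + size - 1L
      hp <- genome$scaffolds[[s]]$het_pos
      if (length(hp) == 0L || any(hp >= start & hp <= end)) break
    }
    rows[[i]] <- data.table::data.table(
      scaffold = scaff_names[s], start = as.integer(start),
      end = as.integer(end),
      mechanism = if (runif(1) < cfg$p_conversion) "gene_conversion"
                  else "hemizygous_deletion",
      retained = sample.int(2L, 1L))
  }
  data.table::rbindlist(rows)
}

#' Simulate truth sets for every line of an experiment
#'
#' @param genome ancestral genome
#' @param meta [line_metadata()] table
#' @param cfg the configuration
#' @return named list (one truth set per line), class `truth_set`
#' @export
simulate_truth <- function(genome, meta, cfg) {
  out <- lapply(seq_len(nrow(meta)), function(i)
    simulate_line_mutations(genome, meta[i, ], cfg))
  names(out) <- meta$line_id
  class(out) <- "truth_set"
  out
}
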