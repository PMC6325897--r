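# Shared fixtures: small configurations and hand-built site-call tables.

tiny_treatments <- function(n_lines = 6L, gen_mean = 100, labels = "Control",
                            gen_sd = 0.1) {
  ma_treatments(labels = labels, n_lines = n_lines, gen_mean = gen_mean,
                gen_sd = gen_sd)
}

tiny_cfg <- function(scaffold_lengths = 20000L, n_scaffolds = 1L,
                     n_lines = 6L, gen_mean = 100, mu_snm = 0,
                     mu_indel = 0, loh_rate = 0, seed = 1L, ...) {
  sim_config(n_scaffolds = n_scaffolds, scaffold_lengths = scaffold_lengths,
             treatments = tiny_treatments(n_lines, gen_mean),
             mu_snm = mu_snm, mu_indel = mu_indel, loh_rate = loh_rate,
             seed = seed, ...)
}

# Hand-built site_call_table. `site_list` is a list of lists with fields:
# scaffold (default "s1"), pos, ref, alt, alt2 (optional), counts: a named
# list line_id -> c(rc, ac[, a2c]). Lines absent from counts get clean
# reference reads at `base_depth`. Genotypes are computed by call_genotype
# unless a `gt` named list overrides them.
mk_table <- function(lines, scaffold_len = 1000L, base_depth = 12L,
                     site_list = list(), seq_error = 0.005, p_call = 2e-9,
                     scaffolds = "s1", chrom = NULL) {
  lens <- setNames(rep_len(as.integer(scaffold_len), length(scaffolds)),
                   scaffolds)
  depth <- lapply(lens, function(L) matrix(as.integer(base_depth), L,
                                           length(lines)))
  names(depth) <- scaffolds
  rows <- list()
  for (s in site_list) {
    sc <- s$scaffold %||% scaffolds[1]
    for (i in seq_along(lines)) {
      l <- lines[i]
      cc <- s$counts[[l]]
      if (is.null(cc)) cc <- c(base_depth, 0L, 0L)
      if (length(cc) == 2L) cc <- c(cc, 0L)
      gt <- if (!is.null(s$gt) && !is.null(s$gt[[l]])) s$gt[[l]] else
        call_genotype(cc[1], cc[2], cc[3], seq_error, p_call)
      depth[[sc]][s$pos, i] <- sum(cc)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        scaffold = sc, pos = as.integer(s$pos), ref = s$ref,
        alt = s$alt %||% NA_character_, alt2 = s$alt2 %||% NA_character_,
        line_id = l, ref_count = as.integer(cc[1]),
        alt_count = as.integer(cc[2]), alt2_count = as.integer(cc[3]),
        gt = gt)
    }
  }
  sites <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(scaffold = character(), pos = integer(),
                           ref = character(), alt = character(),
                           alt2 = character(), line_id = character(),
                           ref_count = integer(), alt_count = integer(),
                           alt2_count = integer(), gt = character())
  data.table::setorder(sites, scaffold, pos, line_id)
  meta <- data.table::data.table(line_id = lines, treatment = "Control",
                                 generations = 100, multiplier = 1)
  out <- list(
    genome_meta = list(scaffolds = scaffolds, lengths = unname(lens),
                       chrom_map = data.table::data.table(
                         scaffold = scaffolds,
                         chrom = chrom %||% seq_along(scaffolds))),
    lines = meta, depth = depth,
    line_mean_depth = setNames(
      as.numeric(Reduce(`+`, lapply(depth, colSums)) / sum(lens)), lines),
    sites = sites,
    params = list(seq_error = seq_error, p_call = p_call,
                  mean_coverage = base_depth))
  class(out) <- "site_call_table"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

in_mask_at <- function(iv_list, sc, pos)
  mamutkit:::in_mask(iv_list, sc, pos)

# counts helper: n-line site where one focal line diverges
site_one_divergent <- function(lines, pos, ref = "A", alt = "G",
                               focal = lines[1], focal_counts = c(6L, 6L),
                               other_counts = c(12L, 0L)) {
  counts <- setNames(rep(list(other_counts), length(lines)), lines)
  counts[[focal]] <- focal_counts
  list(pos = pos, ref = ref, alt = alt, counts = counts)
}
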