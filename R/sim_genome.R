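# Diploid ancestor simulation. Sequence context is abstract: sites carry
# alleles from {A,C,G,T} with no k-mer context model.

#' Collapsed substitution-type labels
#'
#' The six strand-symmetric substitution classes, keyed by the ancestral base
#' pair (A:T or G:C origin).
#' @export
MUT_TYPES <- c("AT>CG", "AT>GC", "AT>TA", "GC>AT", "GC>CG", "GC>TA")

#' Collapse a substitution to one of the six strand-symmetric classes
#'
#' @param anc,der ancestral and derived base codes (1..4 = A,C,G,T) or
#'   characters
#' @return character vector of labels from [MUT_TYPES]
#' @export
mut_type <- function(anc, der) {
  if (is.character(anc)) anc <- match(anc, BASES)
  if (is.character(der)) der <- match(der, BASES)
  stopifnot(all(anc != der))
  # put ancestral base on the A (or G) strand
  flip <- anc %in% c(4L, 2L)            # T -> A, C -> G by complementing
  anc2 <- ifelse(flip, comp_code(anc), anc)
  der2 <- ifelse(flip, comp_code(der), der)
  out <- character(length(anc2))
  at <- anc2 == 1L
  out[at & der2 == 2L] <- "AT>CG"
  out[at & der2 == 3L] <- "AT>GC"
  out[at & der2 == 4L] <- "AT>TA"
  gc <- anc2 == 3L
  out[gc & der2 == 1L] <- "GC>AT"
  out[gc & der2 == 2L] <- "GC>CG"      # G>C == C>G on the other strand
  out[gc & der2 == 4L] <- "GC>TA"
  out
}

#' Simulate the diploid ancestral genome
#'
#' Every site carries two allele slots. Heterozygous sites are placed by
#' independent Bernoulli(`ancestral_het`) draws; at a heterozygous site the
#' second allele is uniform over the three non-reference bases. Scaffolds are
#' assigned round-robin to `n_chromosomes` chromosomes.
#'
#' @param cfg a [sim_config()]
#' @return object of class `ancestral_genome`: per-scaffold reference allele
#'   codes (`ref`), heterozygous positions (`het_pos`) with second alleles
#'   (`het_alt`), plus a scaffold-to-chromosome map
#' @export
generate_ancestor <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(child_seed(cfg$seed, 1L), {
    scaffolds <- lapply(seq_len(cfg$n_scaffolds), function(s) {
      L <- cfg$scaffold_lengths[s]
      ref <- sample.int(4L, L, replace = TRUE)
      het_pos <- which(runif(L) < cfg$ancestral_het)
      # second allele: uniform over the 3 bases differing from ref
      shift <- sample.int(3L, length(het_pos), replace = TRUE)
      het_alt <- ((ref[het_pos] - 1L + shift) %% 4L) + 1L
      list(length = L, ref = ref, het_pos = het_pos, het_alt = het_alt)
    })
    names(scaffolds) <- sprintf("scaffold_%d", seq_len(cfg$n_scaffolds))
    chrom_map <- data.table::data.table(
      scaffold = names(scaffolds),
      chrom = ((seq_len(cfg$n_scaffolds) - 1L) %% cfg$n_chromosomes) + 1L)
    out <- list(scaffolds = scaffolds, chrom_map = chrom_map,
                ancestral_het = cfg$ancestral_het)
    class(out) <- "ancestral_genome"
    out
  })
}

#' @export
print.ancestral_genome <- function(x, ...) {
  nh <- sum(vapply(x$scaffolds, function(s) length(s$het_pos), 0L))
  L <- sum(vapply(x$scaffolds, function(s) s$length, 0L))
  cat(sprintf("ancestral_genome: %d scaffold(s), %s bp, %s het sites (%.3f%%)\n",
              length(x$scaffolds), format(L, big.mark = ","),
              format(nh, big.mark = ","), 100 * nh / L))
  invisible(x)
}

genome_length <- function(genome) {
  sum(vapply(genome$scaffolds, function(s) s$length, 0L))
}

# map global 1..L coordinates to (scaffold index, position)
global_to_scaffold <- function(genome, gpos) {
  lens <- vapply(genome$scaffolds, function(s) s$length, 0L)
  ends <- cumsum(as.numeric(lens))
  sidx <- findInterval(gpos - 0.5, c(0, ends)) # 1-based scaffold index
  pos <- as.integer(gpos - c(0, ends)[sidx])
  list(scaffold = sidx, pos = pos)
}
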