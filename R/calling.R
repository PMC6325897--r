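# De novo mutation identification: candidate detection by genotype pattern,
# exact-binomial consistency filtering, Het-Hom routing, MNM grouping.
#
# The MA design is its own control: the ancestral genotype at a site is the
# consensus of the non-focal lines, and a candidate exists only where exactly
# one line departs from a consensus shared by all others (two or more
# divergent lines indicate ancestral polymorphism or a shared artifact, which
# cannot be de novo under the single-origin assumption).

gt_alleles <- function(gt) lapply(strsplit(gt, "/", fixed = TRUE), unique)

allele_count <- function(rows, allele_idx) {
  cols <- c("ref_count", "alt_count", "alt2_count")
  rows[[cols[allele_idx + 1L]]]
}

#' Detect candidate mutation sites
#'
#' @param table a `site_call_table`
#' @return data.table of (scaffold, pos, line_id, gt, consensus_gt) rows, one
#'   per candidate; sites with two or more divergent lines are excluded
#' @export
detect_candidates <- function(table) {
  sites <- table$sites
  if (nrow(table$lines) < 3L) stopf("candidate detection needs >= 3 lines")
  empty <- data.table::data.table(
    scaffold = character(), pos = integer(), ref = character(),
    alt = character(), alt2 = character(), line_id = character(),
    gt = character(), consensus_gt = character())
  if (nrow(sites) == 0L) return(empty)
  ids <- table$lines$line_id
  nl <- length(ids)
  wide <- data.table::dcast(sites, scaffold + pos + ref + alt + alt2
                            ~ line_id, value.var = "gt")
  G <- as.matrix(wide[, ids, with = FALSE])
  top <- integer(nrow(G)); topv <- character(nrow(G))
  for (v in unique(as.vector(G))) {
    cv <- rowSums(G == v)
    upd <- cv > top
    top[upd] <- cv[upd]; topv[upd] <- v
  }
  miss <- rowSums(G == "./.")
  rows <- which(top == nl - 1L & miss == 0L)
  if (!length(rows)) return(empty)
  div <- max.col(G[rows, , drop = FALSE] != topv[rows], ties.method = "first")
  out <- wide[rows, .(scaffold, pos, ref, alt, alt2)]
  out[, line_id := ids[div]]
  out[, gt := G[cbind(rows, div)]]
  out[, consensus_gt := topv[rows]]
  out[]
}

#' Exact-binomial consistency filter
#'
#' A candidate passes when (a) the focal line's divergent-allele read count
#' is consistent with its called genotype — two-sided exact binomial test at
#' p = 0.5 for a heterozygous call, one-sided test against 1 - `eps` for a
#' homozygous call — and (b) every other line's count of that allele is
#' consistent with sequencing error (one-sided upper-tail test against
#' `eps`). All tests pass at p >= `alpha`. Candidates where the focal line
#' lost an allele relative to a heterozygous consensus (Het-Hom candidates)
#' are tagged `kind = "loss"` and tested for homozygous consistency instead.
#'
#' @param table a `site_call_table`
#' @param candidates output of [detect_candidates()]
#' @param alpha test level (default 0.05)
#' @param eps assumed per-read error rate for the filter (default 0.01)
#' @return `candidates` with columns `kind`, `new_allele`, `zygosity`,
#'   `p_focal`, `p_others`, `pass`, `flag`
#' @export
binomial_consistency <- function(table, candidates, alpha = 0.05,
                                 eps = 0.01) {
  stopifnot(alpha > 0, alpha < 1, eps > 0, eps < 0.5)
  n <- nrow(candidates)
  out <- candidates
  out$kind <- out$zygosity <- out$flag <- NA_character_
  out$new_allele <- NA_integer_
  out$p_focal <- out$p_others <- NA_real_
  out$pass <- FALSE
  if (n == 0L) return(out)
  sites <- data.table::copy(table$sites)
  data.table::setkey(sites, scaffold, pos)
  for (i in seq_len(n)) {
    rows <- sites[.(candidates$scaffold[i], candidates$pos[i])]
    foc <- rows[line_id == candidates$line_id[i]]
    oth <- rows[line_id != candidates$line_id[i]]
    af <- gt_alleles(foc$gt)[[1]]
    ac_ <- gt_alleles(candidates$consensus_gt[i])[[1]]
    dtot <- foc$ref_count + foc$alt_count + foc$alt2_count
    if (dtot == 0L) { out$flag[i] <- "zero_depth"; next }
    gained <- setdiff(af, ac_)
    if (length(gained) == 0L) {
      # allele loss: Het-Hom candidate; focal must be hom-consistent
      out$kind[i] <- "loss"
      out$zygosity[i] <- "hom"
      kept <- as.integer(af[1])
      minor <- dtot - allele_count(foc, kept)
      out$p_focal[i] <- binom_p_upper(minor, dtot, eps)
      out$p_others[i] <- 1
      out$pass[i] <- out$p_focal[i] >= alpha
      next
    }
    new_allele <- as.integer(gained[1])
    out$kind[i] <- "gain"
    out$new_allele[i] <- new_allele
    k <- allele_count(foc, new_allele)
    if (length(af) >= 2L) {
      out$zygosity[i] <- "het"
      out$p_focal[i] <- binom_p_two_sided(k, dtot, 0.5)
    } else {
      out$zygosity[i] <- "hom"
      out$p_focal[i] <- binom_p_lower(k, dtot, 1 - eps)
    }
    ko <- allele_count(oth, new_allele)
    do <- oth$ref_count + oth$alt_count + oth$alt2_count
    po <- binom_p_upper(ko, do, eps)
    out$p_others[i] <- if (length(po)) min(po) else 1
    out$pass[i] <- out$p_focal[i] >= alpha && out$p_others[i] >= alpha
  }
  out
}

#' Remove single-site Het-Hom changes from the SNM set
#'
#' Sites that changed from the ancestrally heterozygous to a homozygous state
#' are far more likely products of gene conversion or hemizygous deletion
#' than of point mutation; they are only considered as parts of LOH events.
#'
#' @param calls filtered candidates from [binomial_consistency()]
#' @return list with `snm_like` (retained) and `het_hom` (routed to the LOH
#'   module)
#' @export
exclude_het_hom_snms <- function(calls) {
  loss <- calls$kind == "loss" & !is.na(calls$kind)
  list(snm_like = calls[!loss], het_hom = calls[loss])
}

#' Group SNMs into multinucleotide mutations
#'
#' Greedy left-to-right clustering per line and scaffold: a cluster grows
#' while every member lies within one `window`-bp stretch (max position -
#' min position <= window - 1). Clusters of two or more SNMs receive an MNM
#' group id.
#'
#' @param snms data.table with `line_id`, `scaffold`, `pos`
#' @param window stretch size in bp (default 50)
#' @return `snms` with an added `mnm_group` column (NA for singletons)
#' @export
group_mnms <- function(snms, window = 50L) {
  out <- data.table::as.data.table(snms)
  if (nrow(out) == 0L) { out[, mnm_group := integer(0)]; return(out[]) }
  data.table::setorder(out, line_id, scaffold, pos)
  out[, cl_ := {
    grp <- integer(.N); cur <- 1L; start <- pos[1]
    if (.N > 1L) for (j in 2:.N) {
      if (pos[j] - start > window - 1L) { cur <- cur + 1L; start <- pos[j] }
      grp[j] <- cur - 1L
    }
    grp + 1L
  }, by = .(line_id, scaffold)]
  out[, csize_ := .N, by = .(line_id, scaffold, cl_)]
  out[, mnm_group := NA_integer_]
  out[csize_ >= 2L, mnm_group := .GRP, by = .(line_id, scaffold, cl_)]
  out[, c("cl_", "csize_") := NULL]
  out[]
}

#' Call de novo mutations from a site-call table
#'
#' Full SNM/INDEL pipeline: candidate detection, callable-site gating (focal
#' depth >= `min_depth`, every other line >= 1 read), exact-binomial
#' consistency filtering, Het-Hom routing, INDEL size bounds (< `max_indel`
#' bp) and MNM grouping.
#'
#' @inheritParams binomial_consistency
#' @param min_depth focal callable depth (default 6)
#' @param mnm_window MNM stretch size (default 50)
#' @param max_indel INDEL length bound, exclusive (default 50)
#' @return list: `calls` (passing SNM/INDEL calls with class, zygosity,
#'   collapsed `type`, `mnm_group`, p-values), `het_hom` (routed loss
#'   candidates), `rejected` (failed candidates with reasons)
#' @export
call_mutations <- function(table, alpha = 0.05, eps = 0.01, min_depth = 6L,
                           mnm_window = 50L, max_indel = 50L) {
  cand <- detect_candidates(table)
  if (nrow(cand)) {
    callable <- site_callable_for(table, cand$scaffold, cand$pos,
                                  cand$line_id, min_depth)
    gated <- cand[callable]
  } else gated <- cand
  tested <- binomial_consistency(table, gated, alpha, eps)
  routed <- exclude_het_hom_snms(tested)
  keep <- routed$snm_like[pass == TRUE]
  gained_allele <- function(dt)
    data.table::fifelse(dt$new_allele == 1L, dt$alt, dt$alt2)
  keep[, is_indel := nchar(ref) > 1L |
         nchar(data.table::fifelse(is.na(alt), "N", alt)) > 1L |
         nchar(data.table::fifelse(is.na(alt2), "N", alt2)) > 1L]
  keep$indel_len <- 0L
  sel <- keep$is_indel
  if (any(sel)) {
    a <- gained_allele(keep)
    keep$indel_len[sel] <- abs(nchar(a[sel]) - nchar(keep$ref[sel]))
  }
  oversize <- keep[is_indel == TRUE & indel_len >= max_indel]
  keep <- keep[is_indel == FALSE | indel_len < max_indel]
  keep[, class := ifelse(is_indel, "INDEL", "SNM")]
  # collapsed substitution type relative to the homozygous ancestral base;
  # third-allele gains at heterozygous ancestral sites have no unique
  # ancestral base and get NA
  keep[, type := NA_character_]
  snm_hom <- keep$class == "SNM" & keep$consensus_gt %in% c("0/0")
  if (any(snm_hom)) {
    der <- data.table::fifelse(keep$new_allele == 1L, keep$alt, keep$alt2)
    keep$type[snm_hom] <- mut_type(keep$ref[snm_hom], der[snm_hom])
  }
  snms <- keep[class == "SNM"]
  if (nrow(snms)) {
    snms <- group_mnms(snms, mnm_window)
    keep <- rbind(snms, keep[class == "INDEL"][, mnm_group := NA_integer_])
  } else keep[, mnm_group := NA_integer_]
  data.table::setorder(keep, line_id, scaffold, pos)
  if (nrow(oversize)) oversize[, flag := "oversize_indel"]
  list(calls = keep[],
       het_hom = routed$het_hom[pass == TRUE],
       rejected = rbind(routed$snm_like[pass == FALSE],
                        routed$het_hom[pass == FALSE], oversize,
                        fill = TRUE))
}

#' Candidate INDEL calls only
#'
#' @inheritParams call_mutations
#' @return data.table of INDEL calls
#' @export
detect_indels <- function(table, alpha = 0.05, eps = 0.01, min_depth = 6L,
                          max_indel = 50L) {
  call_mutations(table, alpha, eps, min_depth,
                 max_indel = max_indel)$calls[class == "INDEL"]
}

# vectorized callable query straight off the depth matrices
site_callable_for <- function(table, scaffold, pos, line_id,
                              min_depth = 6L) {
  li <- match(line_id, table$lines$line_id)
  vapply(seq_along(pos), function(i) {
    m <- table$depth[[scaffold[i]]]
    d <- m[pos[i], ]
    d[li[i]] >= min_depth && all(d[-li[i]] >= 1L)
  }, logical(1))
}

#' Per-line call summary
#'
#' @param calls `calls` table from [call_mutations()]
#' @param masks [callable_masks()] list
#' @param meta line metadata
#' @return data.table: per line `n_snm`, `n_indel`, `n_mnm_groups`,
#'   `callable_bp`, `callable_loh_bp`, `generations`
#' @export
summarize_calls <- function(calls, masks, meta) {
  dt <- data.table::as.data.table(meta)[, .(line_id, treatment, generations)]
  cc <- data.table::as.data.table(calls)[, .(
    n_snm = sum(class == "SNM"), n_indel = sum(class == "INDEL"),
    n_mnm_groups = data.table::uniqueN(stats::na.omit(mnm_group))),
    by = line_id]
  dt <- merge(dt, cc, by = "line_id", all.x = TRUE)
  for (col in c("n_snm", "n_indel", "n_mnm_groups"))
    dt[is.na(get(col)), (col) := 0L]
  dt[, callable_bp := vapply(line_id, function(l) masks[[l]]$C_snm, 0)]
  dt[, callable_loh_bp := vapply(line_id, function(l) masks[[l]]$C_loh, 0)]
  dt[]
}

#' @rdname callable_mask
#' @export
snm_callable_mask <- function(table, focal, min_depth = 6L) {
  m <- callable_mask(table, focal, min_depth)
  m$loh <- NULL; m$C_loh <- NULL
  m
}

#' @rdname callable_mask
#' @export
loh_callable_mask <- function(table, focal, min_depth = 6L, max_gap = 6L,
                              min_run = 200L) {
  callable_mask(table, focal, min_depth, max_gap, min_run)
}
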