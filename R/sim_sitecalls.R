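# Emulation of post-alignment, quality-filtered allele counts and genotype
# calls. The table is sparse by construction: rows exist only at "tracked"
# sites (ancestrally heterozygous sites, sites carrying planted mutations,
# and sites that received two or more identical sequencing-error reads in
# some line). Under the error-aware genotype caller no other site can ever be
# genotyped non-reference, so sparsity loses no candidate; per-site depths
# for every line are kept densely for callable-mask and coverage work.

#' Genotype call from allele read counts
#'
#' Emulates an upstream error-aware caller: a non-reference allele is part of
#' the genotype only when its read support reaches [min_alt_reads()] for the
#' site's depth; the reference allele needs two supporting reads to appear in
#' a heterozygous call.
#'
#' @param rc,ac,a2c reference / alt / second-alt read counts
#' @param seq_error per-read miscall rate assumed by the caller
#' @param p_call per-site-line false-call budget
#' @return character vector of genotypes (`"0/0"`, `"0/1"`, `"1/1"`, `"0/2"`,
#'   `"2/2"`, `"1/2"`, `"./."`)
#' @export
call_genotype <- function(rc, ac, a2c = 0L, seq_error = 0.005,
                          p_call = 2e-9) {
  a2c <- rep_len(a2c, length(rc))
  d <- rc + ac + a2c
  kmin <- min_alt_reads(d, seq_error, p_call)
  s1 <- ac >= kmin
  s2 <- a2c >= kmin
  refok <- rc >= 2L
  gt <- rep("0/0", length(rc))
  gt[s1 & !s2] <- ifelse(refok[s1 & !s2], "0/1", "1/1")
  gt[!s1 & s2] <- ifelse(refok[!s1 & s2], "0/2", "2/2")
  gt[s1 & s2] <- "1/2"
  gt[d == 0L] <- "./."
  gt
}

# c_obs = c - Binom(c, e) + Binom(d - c, e/3): reads leave a category by
# miscall and enter it from the other template bases
perturb_counts <- function(count, depth, e) {
  if (e <= 0) return(count)
  count - rbinom(length(count), count, e) +
    rbinom(length(count), depth - count, e / 3)
}

#' Simulate per-site, per-line allele counts and genotypes
#'
#' Depth is Poisson(`mean_coverage`) per site and line; hemizygous-deletion
#' LOH spans are binomially thinned to half depth, gene-conversion spans keep
#' full depth with homozygous reads. At heterozygous sites reads split
#' Binomial(depth, 0.5) between alleles; every category is then perturbed by
#' per-read miscalls at `seq_error`.
#'
#' @param genome ancestral genome
#' @param truth [simulate_truth()] result covering all lines
#' @param meta line metadata
#' @param cfg the configuration
#' @return object of class `site_call_table`: sparse `sites` data.table
#'   (scaffold, pos, ref, alt, alt2, line_id, ref_count, alt_count,
#'   alt2_count, gt), dense per-scaffold `depth` matrices, line metadata and
#'   caller parameters
#' @export
simulate_site_calls <- function(genome, truth, meta, cfg) {
  stopifnot(all(meta$line_id %in% names(truth)))
  n_lines <- nrow(meta)
  scaff_names <- names(genome$scaffolds)
  lens <- vapply(genome$scaffolds, function(s) s$length, 0L)
  Ltot <- sum(lens)

  depth <- lapply(lens, function(L) matrix(0L, L, n_lines))
  names(depth) <- scaff_names
  spurious <- vector("list", n_lines)

  for (i in seq_len(n_lines)) {
    lid <- meta$line_id[i]
    with_seed(child_seed(cfg$seed, 2000L + str_hash(lid)), {
      loh <- truth[[lid]]$loh
      for (s in seq_along(lens)) {
        d <- rpois(lens[s], cfg$mean_coverage)
        hemi <- loh[loh$scaffold == scaff_names[s] &
                      loh$mechanism == "hemizygous_deletion", ]
        if (nrow(hemi)) for (j in seq_len(nrow(hemi))) {
          idx <- hemi$start[j]:hemi$end[j]
          d[idx] <- rbinom(length(idx), d[idx], 0.5)
        }
        depth[[s]][, i] <- d
      }
      # same-base sequencing-error pileups at untracked sites. Under the
      # error-aware caller only sites with >= 2 identical wrong-base reads
      # can ever be genotyped non-reference, so pileups are drawn per class
      # k with their exact per-site probability 3 C(d,k)(e/3)^k(1-e/3)^(d-k)
      # marginalized over the depth distribution; each landing site's depth
      # is set to the conditioning depth.
      if (cfg$seq_error > 0) {
        eb <- cfg$seq_error / 3
        dmax <- max(20, stats::qpois(1 - 1e-12, cfg$mean_coverage) + 10)
        ds <- 0:dmax
        pdep <- stats::dpois(ds, cfg$mean_coverage)
        rows <- list()
        # pileups below the caller's global minimum alt support can never
        # change a genotype at any depth; tracking them would be dead weight
        kfloor <- max(2L, min(min_alt_reads(1:dmax, cfg$seq_error,
                                            cfg$p_call)))
        for (k in kfloor:12) {
          pik <- 3 * choose(ds, k) * eb^k * (1 - eb)^(pmax(ds - k, 0))
          pik[ds < k] <- 0
          lam <- Ltot * sum(pdep * pik)
          if (lam < 1e-5) break
          nk <- rpois(1L, lam)
          if (nk == 0L) next
          gpos <- sample(Ltot, nk)
          loc <- global_to_scaffold(genome, gpos)
          rows[[length(rows) + 1L]] <- data.table::data.table(
            line_id = lid, scaffold = scaff_names[loc$scaffold],
            pos = loc$pos, shift = sample.int(3L, nk, replace = TRUE),
            n_err = k,
            d_over = sample(ds, nk, replace = TRUE, prob = pdep * pik))
        }
        if (length(rows)) {
          sp <- unique(data.table::rbindlist(rows),
                       by = c("scaffold", "pos"))
          for (s in unique(sp$scaffold)) {
            sel <- sp$scaffold == s
            depth[[s]][sp$pos[sel], i] <- sp$d_over[sel]
          }
          spurious[[i]] <- sp[, .(line_id, scaffold, pos, shift, n_err)]
        }
      }
    })
  }
  spurious <- data.table::rbindlist(spurious)

  site_index <- build_site_index(genome, truth, meta, spurious)
  sites <- build_counts(genome, truth, meta, cfg, depth, site_index, spurious)

  out <- list(genome_meta = list(scaffolds = scaff_names, lengths = lens,
                                 chrom_map = genome$chrom_map),
              lines = data.table::as.data.table(meta),
              depth = depth,
              line_mean_depth = setNames(
                as.numeric(Reduce(`+`, lapply(depth, colSums)) / Ltot),
                meta$line_id),
              sites = sites,
              params = list(seq_error = cfg$seq_error, p_call = cfg$p_call,
                            mean_coverage = cfg$mean_coverage))
  class(out) <- "site_call_table"
  out
}

# union of tracked sites with their site-level allele designation
build_site_index <- function(genome, truth, meta, spurious) {
  scaff_names <- names(genome$scaffolds)
  pieces <- list()
  for (s in seq_along(scaff_names)) {
    sc <- genome$scaffolds[[s]]
    if (length(sc$het_pos))
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        scaffold = scaff_names[s], pos = sc$het_pos,
        ref = BASES[sc$ref[sc$het_pos]], alt = BASES[sc$het_alt],
        alt2 = NA_character_, priority = 1L)
  }
  for (lid in meta$line_id) {
    tr <- truth[[lid]]
    if (nrow(tr$snm)) {
      hom <- tr$snm[tr$snm$anc_zygosity == "hom", ]
      if (nrow(hom))
        pieces[[length(pieces) + 1L]] <- data.table::data.table(
          scaffold = hom$scaffold, pos = hom$pos, ref = BASES[hom$anc1],
          alt = BASES[hom$derived], alt2 = NA_character_, priority = 2L)
      het <- tr$snm[tr$snm$anc_zygosity == "het", ]
      if (nrow(het))  # third allele at an ancestrally het site
        pieces[[length(pieces) + 1L]] <- data.table::data.table(
          scaffold = het$scaffold, pos = het$pos, ref = BASES[het$anc1],
          alt = BASES[het$anc2], alt2 = BASES[het$derived], priority = 1L)
    }
    if (nrow(tr$indel))
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        scaffold = tr$indel$scaffold, pos = tr$indel$pos, ref = tr$indel$ref,
        alt = tr$indel$alt, alt2 = NA_character_, priority = 2L)
  }
  if (nrow(spurious)) {
    refc <- mapply(function(sf, p) genome$scaffolds[[sf]]$ref[p],
                   match(spurious$scaffold, scaff_names), spurious$pos)
    errbase <- ((refc - 1L + spurious$shift) %% 4L) + 1L
    pieces[[length(pieces) + 1L]] <- data.table::data.table(
      scaffold = spurious$scaffold, pos = spurious$pos, ref = BASES[refc],
      alt = BASES[errbase], alt2 = NA_character_, priority = 3L)
  }
  idx <- data.table::rbindlist(pieces)
  if (nrow(idx) == 0L) return(idx)
  data.table::setorder(idx, scaffold, pos, priority)
  # site-level designation: lowest priority row wins; a second distinct alt
  # at the same site fills the alt2 slot
  first <- idx[!duplicated(idx, by = c("scaffold", "pos"))]
  extra <- idx[duplicated(idx, by = c("scaffold", "pos"))]
  if (nrow(extra)) {
    extra <- extra[!duplicated(extra, by = c("scaffold", "pos"))]
    first[extra, on = c("scaffold", "pos"),
          alt2 := ifelse(is.na(x.alt2) & i.alt != x.alt, i.alt, x.alt2)]
  }
  first[, priority := NULL]
  data.table::setorder(first, scaffold, pos)
  first[]
}

build_counts <- function(genome, truth, meta, cfg, depth, site_index,
                         spurious) {
  if (nrow(site_index) == 0L)
    return(data.table::data.table(
      scaffold = character(), pos = integer(), ref = character(),
      alt = character(), alt2 = character(), line_id = character(),
      ref_count = integer(), alt_count = integer(), alt2_count = integer(),
      gt = character()))
  scaff_names <- names(genome$scaffolds)
  ns <- nrow(site_index)
  sidx <- match(site_index$scaffold, scaff_names)
  out <- vector("list", nrow(meta))

  for (i in seq_len(nrow(meta))) {
    lid <- meta$line_id[i]
    tr <- truth[[lid]]
    with_seed(child_seed(cfg$seed, 3000L + str_hash(lid)), {
      d <- integer(ns)
      for (s in unique(sidx)) {
        sel <- sidx == s
        d[sel] <- depth[[s]][site_index$pos[sel], i]
      }
      # true diploid state, starting from the ancestor
      A1 <- site_index$ref
      A2 <- A1
      het0 <- logical(ns)
      for (s in unique(sidx)) {
        sel <- which(sidx == s)
        hp <- genome$scaffolds[[s]]$het_pos
        m <- match(site_index$pos[sel], hp)
        is_het <- !is.na(m)
        A2[sel[is_het]] <- BASES[genome$scaffolds[[s]]$het_alt[m[is_het]]]
        het0[sel[is_het]] <- TRUE
      }
      hemi <- logical(ns)
      if (nrow(tr$loh)) for (j in seq_len(nrow(tr$loh))) {
        ev <- tr$loh[j, ]
        sel <- which(site_index$scaffold == ev$scaffold &
                       site_index$pos >= ev$start & site_index$pos <= ev$end)
        if (!length(sel)) next
        keep <- ifelse(rep(ev$retained == 1L, length(sel)),
                       A1[sel], A2[sel])
        if (ev$mechanism == "hemizygous_deletion") hemi[sel] <- TRUE
        A1[sel] <- keep
        A2[sel] <- keep
      }
      site_key <- match(site_index$scaffold, scaff_names) * 2^32 +
        site_index$pos
      if (nrow(tr$snm)) {
        m <- match(match(tr$snm$scaffold, scaff_names) * 2^32 + tr$snm$pos,
                   site_key)
        der <- BASES[tr$snm$derived]
        swap1 <- tr$snm$from_allele == 1L
        A1[m[swap1]] <- der[swap1]
        A2[m[!swap1]] <- der[!swap1]
        # on a hemizygous background keep a single derived copy
        one <- hemi[m]
        A1[m[one]] <- ifelse(swap1[one], der[one], A1[m[one]])
        A2[m[one]] <- A1[m[one]]
      }
      if (nrow(tr$indel)) {
        m <- match(match(tr$indel$scaffold, scaff_names) * 2^32 +
                     tr$indel$pos, site_key)
        A2[m] <- tr$indel$alt
        A1[m] <- tr$indel$ref
      }
      # read sampling
      is_het_state <- A1 != A2 & !hemi
      x1 <- d
      x1[is_het_state] <- rbinom(sum(is_het_state), d[is_het_state], 0.5)
      x2 <- d - x1
      x2[!is_het_state] <- 0L
      # map allele reads onto the site's count columns
      rc <- ac <- a2c <- integer(ns)
      add_to <- function(cnt, allele) {
        rc <<- rc + cnt * (allele == site_index$ref)
        ac <<- ac + cnt * (!is.na(site_index$alt) & allele == site_index$alt)
        a2c <<- a2c + cnt * (!is.na(site_index$alt2) &
                               allele == site_index$alt2)
      }
      add_to(x1, A1)
      add_to(x2, A2)
      rc <- perturb_counts(rc, d, cfg$seq_error)
      ac <- perturb_counts(ac, d, cfg$seq_error)
      a2c <- perturb_counts(a2c, d, cfg$seq_error)
      rc <- pmax(0L, pmin(rc, d)); ac <- pmax(0L, pmin(ac, d))
      a2c <- pmax(0L, pmin(a2c, d))
      # the three categories are perturbed marginally; on the rare occasion
      # incoming error draws overflow the site depth, trim the excess from
      # the largest category so counts stay a partition of the reads
      over <- rc + ac + a2c - d
      for (ix in which(over > 0L)) {
        v <- c(rc[ix], ac[ix], a2c[ix])
        o <- over[ix]
        while (o > 0L) {
          b <- which.max(v)
          take <- min(o, v[b])
          v[b] <- v[b] - take
          o <- o - take
        }
        rc[ix] <- v[1]; ac[ix] <- v[2]; a2c[ix] <- v[3]
      }
      # planted same-base error pileups for this line
      sp <- spurious[spurious$line_id == lid, ]
      if (nrow(sp)) {
        m <- match(match(sp$scaffold, scaff_names) * 2^32 + sp$pos,
                   site_key)
        ok <- !is.na(m) & !het0[m] & A1[m] == site_index$ref[m] &
          A2[m] == site_index$ref[m]
        mm <- m[ok]
        ac[mm] <- pmin(sp$n_err[ok], d[mm])
        rc[mm] <- d[mm] - ac[mm]
      }
      gt <- call_genotype(rc, ac, a2c, cfg$seq_error, cfg$p_call)
      out[[i]] <- data.table::data.table(
        scaffold = site_index$scaffold, pos = site_index$pos,
        ref = site_index$ref, alt = site_index$alt,
        alt2 = site_index$alt2, line_id = lid,
        ref_count = rc, alt_count = ac, alt2_count = a2c, gt = gt)
    })
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, scaffold, pos, line_id)
  res[]
}

#' @export
print.site_call_table <- function(x, ...) {
  cat(sprintf(
    "site_call_table: %d line(s), %s bp genome, %s tracked site(s)\n",
    nrow(x$lines), format(sum(x$genome_meta$lengths), big.mark = ","),
    format(length(unique(paste(x$sites$scaffold, x$sites$pos))),
           big.mark = ",")))
  cat(sprintf("  mean depth %.2fx, seq_error %.3g\n",
              mean(x$line_mean_depth), x$params$seq_error))
  invisible(x)
}
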