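# Loss-of-heterozygosity detection: Het-Hom site calling, event assembly
# with interior-het exclusion, min/max/average size bounds, multi-scaffold
# merging via the chromosome map, and mechanism classification from
# standardized relative read depth.
#
# Zygosity here deliberately does not reuse the conservative genotype
# caller: a line is "hom-consistent" at a site when its minor-allele count
# is explainable by sequencing error (upper-tail exact binomial against
# `eps` at level `alpha`), and "het-evident" otherwise. A Het-Hom site is an
# ancestrally heterozygous site (every other line het-evident) where the
# focal line is hom-consistent.

zygosity_class <- function(rc, ac, a2c, alpha, eps) {
  d <- rc + ac + a2c
  minor <- d - pmax(rc, ac, a2c)
  hom <- binom_p_upper(minor, d, eps) >= alpha
  out <- rep("none", length(d))
  out[d > 0L & hom] <- "hom"
  out[d > 0L & !hom] <- "het"
  out
}

#' Find Het-Hom sites for a focal line
#'
#' A site counts as ancestrally heterozygous when at least `anc_het_frac`
#' of the non-focal lines with coverage show heterozygous evidence; a
#' majority rather than unanimity, because LOH events are allowed to
#' overlap among lines, making some non-focal lines legitimately homozygous
#' inside another line's event.
#'
#' @param table a `site_call_table`
#' @param focal focal line id
#' @param alpha,eps binomial filter parameters
#' @param mask optional [callable_mask()] for the focal line; when given,
#'   sites are restricted to its LOH-callable intervals
#' @param anc_het_frac minimum fraction of covered non-focal lines with
#'   heterozygous evidence (default 0.5)
#' @return data.table of Het-Hom sites (`scaffold`, `pos`, `retained`
#'   allele character) plus attribute `"focal_het"`: the focal line's
#'   unaffected heterozygous sites used for event bounding
#' @export
find_het_hom_sites <- function(table, focal, alpha = 0.05, eps = 0.01,
                               mask = NULL, anc_het_frac = 0.5) {
  sites <- table$sites
  z <- sites[, .(scaffold, pos, line_id, ref_count, alt_count, alt2_count,
                 ref, alt)]
  z[, zyg := zygosity_class(ref_count, alt_count, alt2_count, alpha, eps)]
  bysite <- z[, {
    f <- line_id == focal
    oth <- zyg[!f]
    nd <- sum(oth != "none")
    .(focal_zyg = zyg[f][1],
      anc_het = nd > 0L && sum(oth == "het") >= anc_het_frac * nd,
      retained = {
        cols <- c(ref_count[f], alt_count[f], alt2_count[f])
        c(ref[f], alt[f], NA_character_)[which.max(cols)]
      })
  }, by = .(scaffold, pos)]
  hh <- bysite[focal_zyg == "hom" & anc_het == TRUE]
  fh <- bysite[focal_zyg == "het" & anc_het == TRUE]
  if (!is.null(mask)) {
    if (nrow(hh)) hh <- hh[in_mask(mask$loh, scaffold, pos)]
    if (nrow(fh)) fh <- fh[in_mask(mask$loh, scaffold, pos)]
  }
  out <- hh[, .(scaffold, pos, retained)]
  data.table::setattr(out, "focal_het", fh[, .(scaffold, pos)])
  out[]
}

#' Assemble LOH events from Het-Hom sites
#'
#' Maximal runs of consecutive Het-Hom sites uninterrupted by any unaffected
#' focal heterozygous site; runs with fewer than `min_sites` sites or a
#' minimum span below `min_span` bp are dropped (shorter stretches could not
#' be validated reliably).
#'
#' @param het_hom Het-Hom site table ([find_het_hom_sites()])
#' @param focal_het unaffected focal het sites (`scaffold`, `pos`)
#' @param min_sites minimum Het-Hom sites per event (default 2)
#' @param min_span minimum span in bp (default 200)
#' @return data.table of events: `scaffold`, `first`, `last`, `n_sites`,
#'   `min_span`
#' @export
assemble_loh_events <- function(het_hom, focal_het, min_sites = 2L,
                                min_span = 200L) {
  empty <- data.table::data.table(scaffold = character(), first = integer(),
                                  last = integer(), n_sites = integer(),
                                  min_span = integer())
  if (nrow(het_hom) == 0L) return(empty)
  out <- list()
  for (sc in unique(het_hom$scaffold)) {
    hp <- sort(het_hom$pos[het_hom$scaffold == sc])
    brk <- sort(focal_het$pos[focal_het$scaffold == sc])
    # run id increments whenever an unaffected het site falls in between
    seg <- findInterval(hp, brk)
    r <- rle(seg)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    ev <- data.table::data.table(scaffold = sc, first = hp[idx_start],
                                 last = hp[idx_end], n_sites = r$lengths)
    out[[length(out) + 1L]] <- ev
  }
  ev <- data.table::rbindlist(out)
  ev[, min_span := last - first + 1L]
  ev <- ev[n_sites >= min_sites & min_span >= min_span_req,
           env = list(min_span_req = min_span)]
  data.table::setorder(ev, scaffold, first)
  ev[]
}

#' Size bounds for an assembled event
#'
#' Minimum span is last - first + 1 over the Het-Hom sites. Maximum span is
#' the gap between the nearest unaffected focal het sites flanking the run
#' (exclusive of those sites); where no flanking het site exists the bound
#' extends to the scaffold edge. Average size is the mean of the two.
#'
#' @param events [assemble_loh_events()] output
#' @param focal_het focal unaffected het sites
#' @param scaffold_lengths named vector of scaffold lengths
#' @return `events` with `max_span`, `avg_size`, `whole_scaffold`
#' @export
loh_size_bounds <- function(events, focal_het, scaffold_lengths) {
  if (nrow(events) == 0L) {
    events[, `:=`(max_span = integer(), avg_size = numeric(),
                  whole_scaffold = logical())]
    return(events[])
  }
  out <- data.table::copy(events)
  out[, `:=`(max_span = NA_integer_, avg_size = NA_real_,
             whole_scaffold = FALSE)]
  for (i in seq_len(nrow(out))) {
    sc <- out$scaffold[i]
    L <- scaffold_lengths[[sc]]
    brk <- sort(focal_het$pos[focal_het$scaffold == sc])
    prev <- suppressWarnings(max(brk[brk < out$first[i]]))
    nxt <- suppressWarnings(min(brk[brk > out$last[i]]))
    lo <- if (is.finite(prev)) prev + 1L else 1L
    hi <- if (is.finite(nxt)) nxt - 1L else L
    out$max_span[i] <- hi - lo + 1L
    out$whole_scaffold[i] <- !is.finite(prev) && !is.finite(nxt)
  }
  out[, avg_size := (min_span + max_span) / 2]
  out[]
}

#' Merge whole-scaffold events that share a chromosome
#'
#' Same-line events occupying entire scaffolds whose scaffolds are mapped to
#' one chromosome are one physical event; scaffold order and orientation
#' being unknown, the merged event keeps only the (summed) minimum size
#' estimate, which also becomes its average size.
#'
#' @param events sized events for one line (with `whole_scaffold`)
#' @param chrom_map data.table `scaffold` -> `chrom`
#' @return events with merged multi-scaffold rows; merged rows carry a
#'   comma-separated scaffold list and `multi_scaffold = TRUE`
#' @export
merge_multiscaffold <- function(events, chrom_map) {
  if (nrow(events) == 0L) {
    out <- data.table::copy(events)
    out[, multi_scaffold := logical()]
    return(out[])
  }
  out <- data.table::copy(events)
  out[, multi_scaffold := FALSE]
  out[, chrom := chrom_map$chrom[match(scaffold, chrom_map$scaffold)]]
  unknown <- out$whole_scaffold & is.na(out$chrom)
  if (any(unknown))
    warnf("%d whole-scaffold event(s) on scaffolds missing from the map",
          sum(unknown))
  ws <- which(out$whole_scaffold & !is.na(out$chrom))
  if (length(ws) > 1L) {
    grp <- split(ws, out$chrom[ws])
    for (g in grp) {
      if (length(g) < 2L) next
      k <- g[1]
      out$scaffold[k] <- paste(out$scaffold[g], collapse = ",")
      out$n_sites[k] <- sum(out$n_sites[g])
      out$min_span[k] <- sum(out$min_span[g])
      out$max_span[k] <- NA_integer_
      out$avg_size[k] <- out$min_span[k]
      out$multi_scaffold[k] <- TRUE
      out <- out[-g[-1]]
    }
  }
  out[, chrom := NULL]
  out[]
}

#' Classify an event as gene conversion or hemizygous deletion
#'
#' Standardized relative coverage: mean focal depth over the event divided
#' by the all-lines mean over the same region, corrected by the ratio of
#' genome-wide means. Values >= `threshold` (default 0.75) indicate a
#' copy-neutral, gene-conversion-like event; lower values a hemizygous
#' deletion. Multi-scaffold events are classified on their largest member
#' scaffold.
#'
#' @param events sized (possibly merged) events
#' @param table the `site_call_table`
#' @param focal focal line id
#' @param threshold classification threshold (default 0.75)
#' @return events with `std_rel_cov` and `mechanism`
#' @export
classify_loh_events <- function(events, table, focal, threshold = 0.75) {
  out <- data.table::copy(events)
  out[, `:=`(std_rel_cov = NA_real_, mechanism = NA_character_)]
  if (nrow(out) == 0L) return(out[])
  li <- match(focal, table$lines$line_id)
  # genome-wide means recomputed from the depth matrices (robust to tables
  # whose cached means are stale)
  gw <- Reduce(`+`, lapply(table$depth, colSums)) /
    sum(table$genome_meta$lengths)
  gw_focal <- gw[li]
  gw_all <- mean(gw)
  for (i in seq_len(nrow(out))) {
    scs <- strsplit(out$scaffold[i], ",", fixed = TRUE)[[1]]
    sc <- if (length(scs) > 1L) {
      lens <- table$genome_meta$lengths[match(scs, table$genome_meta$scaffolds)]
      scs[which.max(lens)]
    } else scs
    m <- table$depth[[sc]]
    span <- if (length(scs) > 1L) seq_len(nrow(m)) else
      out$first[i]:out$last[i]
    ev_focal <- mean(m[span, li])
    ev_all <- mean(m[span, , drop = FALSE])
    if (ev_all == 0) { out$mechanism[i] <- "unclassifiable"; next }
    src <- (ev_focal / ev_all) / (gw_focal / gw_all)
    out$std_rel_cov[i] <- src
    out$mechanism[i] <- if (src >= threshold) "gene_conversion"
                        else "hemizygous_deletion"
  }
  out[]
}

#' Full LOH pipeline for all lines
#'
#' @param table a `site_call_table`
#' @param masks optional [callable_masks()] (computed when missing)
#' @param alpha,eps binomial filter parameters
#' @param min_sites,min_span event assembly thresholds
#' @param threshold mechanism classification threshold
#' @return data.table of events across lines with spans, mechanism and
#'   standardized relative coverage
#' @export
call_loh <- function(table, masks = NULL, alpha = 0.05, eps = 0.01,
                     min_sites = 2L, min_span = 200L, threshold = 0.75) {
  if (is.null(masks)) masks <- callable_masks(table)
  lens <- setNames(as.list(table$genome_meta$lengths),
                   table$genome_meta$scaffolds)
  out <- list()
  for (l in table$lines$line_id) {
    hh <- find_het_hom_sites(table, l, alpha, eps, mask = masks[[l]])
    fh <- attr(hh, "focal_het")
    ev <- assemble_loh_events(hh, fh, min_sites, min_span)
    ev <- loh_size_bounds(ev, fh, lens)
    ev <- merge_multiscaffold(ev, table$genome_meta$chrom_map)
    ev <- classify_loh_events(ev, table, l, threshold)
    if (nrow(ev)) { ev[, line_id := l]; out[[length(out) + 1L]] <- ev }
  }
  if (!length(out))
    return(data.table::data.table(
      scaffold = character(), first = integer(), last = integer(),
      n_sites = integer(), min_span = integer(), max_span = integer(),
      avg_size = numeric(), whole_scaffold = logical(),
      multi_scaffold = logical(), std_rel_cov = numeric(),
      mechanism = character(), line_id = character()))
  res <- data.table::rbindlist(out)
  res[, event_id := sprintf("%s:e%d", line_id,
                            seq_len(.N)), by = line_id]
  data.table::setcolorder(res, "line_id")
  res[]
}
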