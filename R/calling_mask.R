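# Callable-site masks: the denominators of every rate estimate.
#
# A site is SNM-callable for a focal line when that line has >= `min_depth`
# quality-passing reads and every other line has at least one. LOH-callable
# sites additionally have to sit in stretches of SNM-callable sites at least
# `min_run` bp long, interrupted by no more than `max_gap` consecutive
# non-qualifying bases (gaps tolerate small INDELs between the ancestor and
# the reference).

# logical vector -> data.table of 0-based half-open intervals
runs_to_intervals <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.table::data.table(start = starts[r$values], end = ends[r$values])
}

# merge TRUE runs separated by gaps <= max_gap, then drop runs < min_run bp;
# returns intervals spanning the merged runs (gap bases included in C)
gap_tolerant_runs <- function(x, max_gap = 6L, min_run = 200L) {
  iv <- runs_to_intervals(x)
  if (nrow(iv) == 0L) return(iv)
  gap <- c(Inf, iv$start[-1L] - iv$end[-nrow(iv)])
  grp <- cumsum(gap > max_gap)
  r <- rle(grp)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  out <- data.table::data.table(start = iv$start[first],
                                end = iv$end[last])
  out[out$end - out$start >= min_run]
}

per_site_callable <- function(table, focal, min_depth = 6L) {
  i <- match(focal, table$lines$line_id)
  if (is.na(i)) stopf("unknown line id '%s'", focal)
  lapply(table$depth, function(m) {
    nz <- integer(nrow(m))
    for (j in seq_len(ncol(m))) if (j != i) nz <- nz + (m[, j] == 0L)
    m[, i] >= min_depth & nz == 0L
  })
}

#' Callable mask for a focal line
#'
#' @param table a `site_call_table`
#' @param focal focal line id
#' @param min_depth minimum focal read depth (default 6)
#' @param max_gap,min_run LOH stretch rule (defaults 6 bp gaps, 200 bp runs)
#' @return object of class `callable_mask`: per-scaffold interval tables
#'   (0-based half-open) for the SNM and LOH categories with total callable
#'   bp `C_snm` and `C_loh`
#' @export
callable_mask <- function(table, focal, min_depth = 6L, max_gap = 6L,
                          min_run = 200L) {
  call_by_scaffold <- per_site_callable(table, focal, min_depth)
  snm <- lapply(call_by_scaffold, runs_to_intervals)
  loh <- lapply(call_by_scaffold, gap_tolerant_runs, max_gap = max_gap,
                min_run = min_run)
  out <- list(line_id = focal,
              snm = snm, loh = loh,
              C_snm = sum(vapply(snm, function(d) sum(d$end - d$start), 0)),
              C_loh = sum(vapply(loh, function(d) sum(d$end - d$start), 0)),
              min_depth = min_depth, max_gap = max_gap, min_run = min_run)
  class(out) <- "callable_mask"
  out
}

#' @export
print.callable_mask <- function(x, ...) {
  cat(sprintf("callable_mask [%s]: C_snm = %s bp, C_loh = %s bp\n",
              x$line_id, format(x$C_snm, big.mark = ","),
              format(x$C_loh, big.mark = ",")))
  invisible(x)
}

# membership query, 1-based positions against 0-based half-open intervals
in_mask <- function(iv_list, scaffold, pos) {
  vapply(seq_along(pos), function(i) {
    iv <- iv_list[[scaffold[i]]]
    if (is.null(iv) || nrow(iv) == 0L) return(FALSE)
    any(pos[i] > iv$start & pos[i] <= iv$end)
  }, logical(1))
}

#' Per-line callable-site counts and depth histograms, without intervals
#'
#' Fast path for rate estimation: everything [snm_detection_sensitivity()]
#' and the pooled-rate denominator need, skipping interval construction.
#'
#' @inheritParams callable_mask
#' @return named list per line with `C_snm`, `depth_hist_callable`,
#'   `depth_hist_all`
#' @export
callable_stats <- function(table, min_depth = 6L) {
  ids <- table$lines$line_id
  dmax <- max(vapply(table$depth, max, 0L)) + 1L
  hcall <- hall <- matrix(0, dmax + 1L, length(ids))
  for (sc in names(table$depth)) {
    m <- table$depth[[sc]]
    nz <- integer(nrow(m))
    for (j in seq_len(ncol(m))) nz <- nz + (m[, j] == 0L)
    ok_all <- nz == 0L
    for (j in seq_len(ncol(m))) {
      dcol <- m[, j]
      hcall[, j] <- hcall[, j] +
        tabulate(dcol[dcol >= min_depth & ok_all] + 1L, dmax + 1L)
      hall[, j] <- hall[, j] + tabulate(dcol + 1L, dmax + 1L)
    }
  }
  out <- lapply(seq_along(ids), function(i)
    list(line_id = ids[i], C_snm = sum(hcall[, i]),
         depth_hist_callable = hcall[, i], depth_hist_all = hall[, i]))
  names(out) <- ids
  out
}

#' Callable masks for every line
#'
#' Single pass over the depth matrices: the count of zero-depth lines per
#' site is computed once and shared across focal lines.
#'
#' @inheritParams callable_mask
#' @return named list of [callable_mask()] objects
#' @export
callable_masks <- function(table, min_depth = 6L, max_gap = 6L,
                           min_run = 200L) {
  ids <- table$lines$line_id
  snm <- loh <- lapply(ids, function(l) list())
  names(snm) <- names(loh) <- ids
  dmax <- max(vapply(table$depth, max, 0L)) + 1L
  hcall <- matrix(0, dmax + 1L, length(ids))   # callable-site depth histogram
  hall <- matrix(0, dmax + 1L, length(ids))
  for (sc in names(table$depth)) {
    m <- table$depth[[sc]]
    nz <- integer(nrow(m))
    for (j in seq_len(ncol(m))) nz <- nz + (m[, j] == 0L)
    ok_all <- nz == 0L   # min_depth >= 1, so focal zero fails anyway
    for (j in seq_len(ncol(m))) {
      dcol <- m[, j]
      callable <- dcol >= min_depth & ok_all
      snm[[j]][[sc]] <- runs_to_intervals(callable)
      loh[[j]][[sc]] <- gap_tolerant_runs(callable, max_gap, min_run)
      hcall[, j] <- hcall[, j] + tabulate(dcol[callable] + 1L, dmax + 1L)
      hall[, j] <- hall[, j] + tabulate(dcol + 1L, dmax + 1L)
    }
  }
  out <- lapply(seq_along(ids), function(i) {
    l <- ids[i]
    o <- list(line_id = l, snm = snm[[l]], loh = loh[[l]],
              C_snm = sum(vapply(snm[[l]], function(d)
                sum(d$end - d$start), 0)),
              C_loh = sum(vapply(loh[[l]], function(d)
                sum(d$end - d$start), 0)),
              depth_hist_callable = hcall[, i], depth_hist_all = hall[, i],
              min_depth = min_depth, max_gap = max_gap, min_run = min_run)
    class(o) <- "callable_mask"
    o
  })
  names(out) <- ids
  out
}
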