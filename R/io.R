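# File formats. TSVs are tab-delimited UTF-8 with a header; BED is 0-based
# half-open; the VCF export is minimal v4.2 with GT:AD:DP; truth sets and
# reports are JSON. Every writer has a paired reader (round-trip tested).

# fread for .gz without the R.utils dependency: stream through a gzfile
# connection
fread_gz <- function(path, ...) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  data.table::fread(text = readLines(con), ...)
}

#' Write a site-call table to a directory
#'
#' Produces `sites.tsv.gz` (wide: scaffold, pos 1-based, ref_allele,
#' alt_allele, alt2_allele, then `<line>.ref_count`, `<line>.alt_count`,
#' `<line>.alt2_count`, `<line>.gt` per line), `depth.tsv.gz` (dense per-site
#' per-line depths), `lines.tsv` and `genome.json`.
#'
#' @param table a `site_call_table`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_site_calls <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- data.table::dcast(
    table$sites, scaffold + pos + ref + alt + alt2 ~ line_id,
    value.var = c("ref_count", "alt_count", "alt2_count", "gt"))
  data.table::setnames(wide, c("ref", "alt", "alt2"),
                       c("ref_allele", "alt_allele", "alt2_allele"))
  data.table::fwrite(wide, file.path(dir, "sites.tsv.gz"), sep = "\t")
  dep <- data.table::data.table(
    scaffold = rep(table$genome_meta$scaffolds, table$genome_meta$lengths),
    pos = unlist(lapply(table$genome_meta$lengths, seq_len)))
  dmat <- do.call(rbind, table$depth)
  colnames(dmat) <- table$lines$line_id
  dep <- cbind(dep, data.table::as.data.table(dmat))
  data.table::fwrite(dep, file.path(dir, "depth.tsv.gz"), sep = "\t")
  data.table::fwrite(table$lines, file.path(dir, "lines.tsv"), sep = "\t")
  jsonlite::write_json(
    list(scaffolds = table$genome_meta$scaffolds,
         lengths = table$genome_meta$lengths,
         chrom_map = table$genome_meta$chrom_map,
         params = table$params),
    file.path(dir, "genome.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a site-call table written by [write_site_calls()]
#'
#' @param dir directory
#' @return a `site_call_table`
#' @export
read_site_calls <- function(dir) {
  gj <- jsonlite::read_json(file.path(dir, "genome.json"),
                            simplifyVector = TRUE)
  lines <- data.table::fread(file.path(dir, "lines.tsv"))
  wide <- fread_gz(file.path(dir, "sites.tsv.gz"))
  dep <- fread_gz(file.path(dir, "depth.tsv.gz"))
  ids <- lines$line_id
  long <- data.table::melt(
    wide, id.vars = c("scaffold", "pos", "ref_allele", "alt_allele",
                      "alt2_allele"),
    measure.vars = patterns(ref_count = "^ref_count_",
                            alt_count = "^alt_count_",
                            alt2_count = "^alt2_count_", gt = "^gt_"),
    variable.name = "line_idx")
  long[, line_id := ids[as.integer(line_idx)]]
  long[, line_idx := NULL]
  data.table::setnames(long, c("ref_allele", "alt_allele", "alt2_allele"),
                       c("ref", "alt", "alt2"))
  for (col in c("ref", "alt", "alt2"))   # all-NA columns read back logical
    long[, (col) := as.character(get(col))]
  long[alt2 == "" | is.na(alt2), alt2 := NA_character_]
  long[alt == "" | is.na(alt), alt := NA_character_]
  data.table::setorder(long, scaffold, pos, line_id)
  depth <- lapply(seq_along(gj$scaffolds), function(s) {
    m <- as.matrix(dep[scaffold == gj$scaffolds[s], ..ids])
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  })
  names(depth) <- gj$scaffolds
  Ltot <- sum(gj$lengths)
  out <- list(
    genome_meta = list(scaffolds = gj$scaffolds,
                       lengths = as.integer(gj$lengths),
                       chrom_map = data.table::as.data.table(gj$chrom_map)),
    lines = lines, depth = depth,
    line_mean_depth = setNames(vapply(seq_along(ids), function(i)
      sum(vapply(depth, function(m) sum(as.numeric(m[, i])), 0)) / Ltot, 0),
      ids),
    sites = long[], params = gj$params)
  class(out) <- "site_call_table"
  out
}

#' Minimal multi-sample VCF 4.2 export of the tracked sites
#'
#' @param table a `site_call_table`
#' @param path output path (plain text)
#' @return `path`, invisibly
#' @export
write_vcf <- function(table, path) {
  wide <- data.table::dcast(table$sites,
                            scaffold + pos + ref + alt + alt2 ~ line_id,
                            value.var = c("ref_count", "alt_count",
                                          "alt2_count", "gt"))
  ids <- table$lines$line_id
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=mamutkit-%s", utils::packageVersion("mamutkit")),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  altcol <- ifelse(is.na(wide$alt2) | wide$alt2 == "", wide$alt,
                   paste(wide$alt, wide$alt2, sep = ","))
  altcol[is.na(altcol)] <- "."
  body <- vapply(seq_len(nrow(wide)), function(i) {
    smp <- vapply(ids, function(l) {
      rc <- wide[[paste0("ref_count_", l)]][i]
      ac <- wide[[paste0("alt_count_", l)]][i]
      a2 <- wide[[paste0("alt2_count_", l)]][i]
      gt <- wide[[paste0("gt_", l)]][i]
      ad <- if (is.na(wide$alt2[i]) || wide$alt2[i] == "")
        paste(rc, ac, sep = ",") else paste(rc, ac, a2, sep = ",")
      sprintf("%s:%s:%d", gt, ad, rc + ac + a2)
    }, "")
    paste(c(wide$scaffold[i], wide$pos[i], ".", wide$ref[i], altcol[i],
            ".", "PASS", ".", "GT:AD:DP", smp), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read truth sets as JSON
#' @param truth a `truth_set`
#' @param path file path
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(lapply(unclass(truth), function(tr)
    lapply(tr, function(d) as.data.frame(d))), path, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(tr) lapply(tr, data.table::as.data.table))
  class(out) <- "truth_set"
  out
}

#' Write LOH events as BED plus a detail TSV
#'
#' BED intervals are 0-based half-open, the average-size span anchored at
#' the minimum-span midpoint; name is `line_id:event_id`, score the number
#' of supporting Het-Hom sites.
#'
#' @param events [call_loh()] output
#' @param bed_path,tsv_path output paths
#' @export
write_loh_bed <- function(events, bed_path, tsv_path = NULL) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev)) {
    mid <- (ev$first + ev$last) / 2
    start0 <- pmax(0, round(mid - ev$avg_size / 2) - 1)
    bed <- data.table::data.table(
      chrom = vapply(strsplit(ev$scaffold, ",", fixed = TRUE), `[`, "", 1),
      start = as.integer(start0),
      end = as.integer(start0 + round(ev$avg_size)),
      name = sprintf("%s:%s", ev$line_id, ev$event_id),
      score = ev$n_sites)
  } else bed <- data.table::data.table(chrom = character(),
                                       start = integer(), end = integer(),
                                       name = character(), score = integer())
  data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  if (!is.null(tsv_path)) data.table::fwrite(ev, tsv_path, sep = "\t")
  invisible(bed_path)
}

#' Write / read life-history records
#' @param life records table
#' @param path CSV path
#' @export
write_life_csv <- function(life, path) {
  data.table::fwrite(life, path)
  invisible(path)
}

#' @rdname write_life_csv
#' @export
read_life_csv <- function(path) data.table::fread(path)
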