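# End-to-end report: simulate -> call -> rates -> lifehist, with a JSON
# report and a short human-readable summary. Structured one-line logs per
# stage keep filter attrition auditable.

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[mamutkit] ", fmt), ...))
}

#' Run the complete pipeline on a synthetic experiment
#'
#' @param run a `run_config` ([load_config()]); its `sim` entry parameterizes
#'   [sim_config()], and `run$seed` overrides the simulation seed
#' @param out_dir optional directory for file outputs (site calls, call
#'   tables, BED, report JSON and summary text)
#' @param verbose log one line per stage
#' @return list with all stage outputs and the `report` list
#' @export
run_report <- function(run = load_config(), out_dir = NULL, verbose = TRUE) {
  sim_args <- run$sim
  sim_args$seed <- run$seed
  cfg <- do.call(sim_config, sim_args)
  log_stage(verbose, "simulate: seed %d, %s bp genome", cfg$seed,
            format(sum(cfg$scaffold_lengths), big.mark = ","))
  ex <- simulate_ma_experiment(cfg)
  log_stage(verbose, "simulate: %d lines, %d tracked sites", nrow(ex$meta),
            data.table::uniqueN(ex$table$sites, by = c("scaffold", "pos")))

  masks <- callable_masks(ex$table, run$min_depth, run$max_gap, run$min_span)
  calls <- call_mutations(ex$table, run$alpha, run$eps, run$min_depth,
                          run$mnm_window, run$max_indel)
  log_stage(verbose, "call-snm: %d calls (%d rejected, %d het-hom routed)",
            nrow(calls$calls), nrow(calls$rejected), nrow(calls$het_hom))
  loh <- call_loh(ex$table, masks, run$alpha, run$eps, run$min_sites,
                  run$min_span, run$cov_ratio)
  log_stage(verbose, "call-loh: %d events", nrow(loh))

  summ <- summarize_calls(calls$calls, masks, ex$meta)
  snms <- calls$calls[calls$calls$class == "SNM", ]
  sens <- snm_detection_sensitivity(ex$table, masks, run$alpha, run$eps,
                                    ancestral_het = cfg$ancestral_het,
                                    min_depth = run$min_depth)
  pooled <- pooled_snm_rate(summ$n_snm, summ$callable_bp, summ$generations,
                            C_eff = sens$C_eff[match(summ$line_id,
                                                     sens$line_id)])
  lrates <- loh_rates(loh, summ)
  at_frac <- callable_at_fraction(ex$genome, masks)
  spec_tab <- spectrum_counts(snms, ex$meta)
  spect <- if (sum(spec_tab) > 0)
    spectrum_test(rowSums(spec_tab), at_frac) else NULL
  homog <- if (sum(spec_tab) > 0 && sum(colSums(spec_tab) > 0) >= 2)
    spectrum_homogeneity(spec_tab) else NULL
  mnm <- mnm_fraction(snms)
  trt <- tryCatch(
    treatment_rate_tests(summ$n_snm / (summ$callable_bp * summ$generations),
                         summ$treatment, run$rate_test),
    error = function(e) list(error = conditionMessage(e)))
  log_stage(verbose, "rates: pooled SNM %.3g /bp/gen, LOH %.3g events/gen",
            pooled$rate, lrates$pooled$events_per_gen)

  life_block <- tryCatch({
    rs <- subline_r(ex$life, run$r_method)
    rs[, value := r]
    size <- data.table::as.data.table(ex$life)[
      survived_to_assay == TRUE,
      .(line_id, subline_id, treatment, generations, value = body_size)]
    list(r = mut_param_estimates(rs, vm_divisor = run$vm_divisor),
         body_size = mut_param_estimates(size, vm_divisor = run$vm_divisor))
  }, error = function(e) list(error = conditionMessage(e)))
  log_stage(verbose, "lifehist: %s",
            if (is.null(life_block$error)) "ok" else life_block$error)

  report <- list(
    software = list(package = "mamutkit",
                    version = as.character(utils::packageVersion("mamutkit")),
                    config_hash = config_hash(run)),
    config = unclass(run),
    genomic = list(
      n_lines = nrow(ex$meta),
      mean_callable_bp = mean(summ$callable_bp),
      mean_callable_loh_bp = mean(summ$callable_loh_bp),
      at_fraction = at_frac,
      n_snm = sum(summ$n_snm), n_indel = sum(summ$n_indel),
      n_loh_events = nrow(loh),
      mean_detection_sensitivity = mean(sens$sensitivity),
      pooled_snm_rate = pooled[c("rate", "se", "ci", "rate_adj")],
      loh_rates = lrates$pooled,
      mnm = mnm,
      spectrum = if (!is.null(spect))
        spect[c("statistic", "df", "p_value")] else "absent",
      spectrum_homogeneity = if (!is.null(homog)) homog else "absent",
      treatment_test = trt),
    life_history = if (is.null(life_block$error)) life_block
      else list(absent = life_block$error))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_site_calls(ex$table, file.path(out_dir, "site_calls"))
    write_truth_json(ex$truth, file.path(out_dir, "truth.json"))
    data.table::fwrite(calls$calls, file.path(out_dir, "calls.tsv"),
                       sep = "\t")
    data.table::fwrite(summ, file.path(out_dir, "call_summary.tsv"),
                       sep = "\t")
    write_loh_bed(loh, file.path(out_dir, "loh.bed"),
                  file.path(out_dir, "loh.tsv"))
    write_life_csv(ex$life, file.path(out_dir, "life_history.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
    writeLines(render_summary(report), file.path(out_dir, "summary.txt"))
  }
  invisible(list(experiment = ex, masks = masks, calls = calls, loh = loh,
                 summary = summ, pooled_snm = pooled, loh_rates = lrates,
                 report = report))
}

render_summary <- function(report) {
  g <- report$genomic
  c(sprintf("mamutkit %s report (config %s)", report$software$version,
            report$software$config_hash),
    sprintf("lines: %d; mean callable %.0f bp (SNM), %.0f bp (LOH); AT %.4f",
            g$n_lines, g$mean_callable_bp, g$mean_callable_loh_bp,
            g$at_fraction),
    sprintf("calls: %d SNM, %d INDEL, %d LOH events", g$n_snm, g$n_indel,
            g$n_loh_events),
    sprintf("pooled SNM rate: %.3g /bp/gen (sensitivity-adjusted %.3g)",
            g$pooled_snm_rate$rate, g$pooled_snm_rate$rate_adj),
    sprintf("LOH: %.4g events/gen, %.4g bp/gen, %.3g /bp/gen",
            g$loh_rates$events_per_gen, g$loh_rates$bp_per_gen,
            g$loh_rates$rate_per_bp_gen),
    if (!identical(g$spectrum, "absent"))
      sprintf("spectrum chi2(df=%d) = %.2f, p = %.3g", g$spectrum$df,
              g$spectrum$statistic, g$spectrum$p_value) else
        "spectrum: absent",
    if (is.null(report$life_history$absent))
      sprintf("life history: r anchor %.3f, overall dM %.4g %%/gen",
              report$life_history$r$anchor$mean,
              report$life_history$r$overall$delta_m$dm_pct) else
        sprintf("life history: absent (%s)", report$life_history$absent))
}
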