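# Run configuration. JSON on disk; defaults are the thresholds the pipeline
# is built around: 6 reads of focal depth, 200 bp minimum LOH stretch/span,
# 6 bp tolerated gaps, 0.75 coverage-ratio classification threshold, 50 bp
# MNM window and INDEL size bound.

default_run_config <- function() {
  list(alpha = 0.05, eps = 0.01, min_depth = 6L, min_span = 200L,
       min_sites = 2L, max_gap = 6L, cov_ratio = 0.75, mnm_window = 50L,
       max_indel = 50L, rate_test = "auto", vm_divisor = 2,
       r_method = "euler-lotka", allele_factor = 1 / 3, seed = 1L,
       sim = list())
}

#' Load and validate a run configuration
#'
#' Reads a JSON file, fills defaults, rejects unknown keys and out-of-range
#' values. The `sim` sub-object takes [sim_config()] arguments.
#'
#' @param path JSON file; `NULL` or a missing file field yields all defaults
#' @return validated named list of class `run_config`
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    txt <- readLines(path, warn = FALSE)
    user <- if (length(txt) == 0L || all(!nzchar(trimws(txt)))) list()
      else jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) stopf("invalid config: %s", what)
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0,1)")
  chk(cfg$eps > 0 && cfg$eps < 0.5, "eps must be in (0,0.5)")
  chk(cfg$min_depth >= 1, "min_depth must be >= 1")
  chk(cfg$min_span >= 1, "min_span must be >= 1")
  chk(cfg$min_sites >= 1, "min_sites must be >= 1")
  chk(cfg$max_gap >= 0, "max_gap must be >= 0")
  chk(cfg$cov_ratio > 0, "cov_ratio must be > 0")
  chk(cfg$mnm_window >= 2, "mnm_window must be >= 2")
  chk(cfg$max_indel >= 1, "max_indel must be >= 1")
  chk(cfg$rate_test %in% c("auto", "anova", "kruskal"), "rate_test")
  chk(cfg$vm_divisor %in% c(1, 2), "vm_divisor must be 1 or 2")
  chk(cfg$r_method %in% c("euler-lotka", "projection"), "r_method")
  chk(cfg$allele_factor >= 0, "allele_factor must be >= 0")
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
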