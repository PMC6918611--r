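#' Default pipeline thresholds
#'
#' Every numeric threshold used by the analysis lives in a single
#' `pipeline_config` list so that each stage draws its cut-offs from one
#' provenanced home. Each field carries a provenance string (attribute
#' `"provenance"`) stating, in words, the rule it encodes.
#'
#' Inequality conventions are deliberate and asymmetric: domain calling uses
#' strict `> 70`% / `< 30`%; CGI classes use strict `> 70`% / `< 20`%;
#' maintenance inclusion uses non-strict `>= 20`% residual oocyte methylation;
#' hypomethylated regions use strict ratio `< 0.65` with non-strict
#' `>= 10` covered CpGs.
#'
#' @return A named list of class `pipeline_config` with fields:
#'
#' * `tile_kb_array`, `min_cpg_array` — 20-kb tiles with >= 3 informative
#'   probes for methylation-array window quantification.
#' * `tile_kb_sc`, `min_sites_sc` — 50-kb tiles with >= 5 observed CpGs for
#'   single-cell libraries.
#' * `tile_kb_grouped`, `min_sites_grouped` — 20-kb tiles with >= 10
#'   observed CpGs for grouped (pooled) libraries.
#' * `qc_window_kb`, `qc_step_kb` — 100-kb sliding QC windows, 10-kb step.
#' * `domain_tile_kb`, `domain_hi_pct`, `domain_lo_pct`, `domain_min_kb` —
#'   10-kb tiles merged into methylated (> 70\%) / unmethylated (< 30\%)
#'   domains, kept at >= 50 kb.
#' * `cgi_meth_pct`, `cgi_unmeth_pct` — CGI classes from the reference
#'   methylome: methylated > 70\%, unmethylated < 20\%.
#' * `hypo_ratio`, `hypo_min_cpg` — mole/control ratio < 0.65 with >= 10
#'   covered CpGs per 20-kb window.
#' * `maintenance_min_oocyte_pct`, `perfect_maintenance_ratio` — features
#'   need >= 20\% residual oocyte methylation; perfect maintenance is a
#'   ratio of 0.5 (one methylated allele out of two).
#' * `zfp57_motifs` — the ZFP57 binding hexamers TGCCGC and GGCCGC.
#' * `random_window_n_cpg` — random genome-wide windows contain exactly 50
#'   consecutive CpGs.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$hypo_ratio
#' attr(cfg, "provenance")[["hypo_ratio"]]
default_config <- function() {
  cfg <- list(
    tile_kb_array = 20, min_cpg_array = 3,
    tile_kb_sc = 50, min_sites_sc = 5,
    tile_kb_grouped = 20, min_sites_grouped = 10,
    qc_window_kb = 100, qc_step_kb = 10,
    domain_tile_kb = 10, domain_hi_pct = 70, domain_lo_pct = 30,
    domain_min_kb = 50,
    cgi_meth_pct = 70, cgi_unmeth_pct = 20,
    hypo_ratio = 0.65, hypo_min_cpg = 10,
    maintenance_min_oocyte_pct = 20, perfect_maintenance_ratio = 0.5,
    zfp57_motifs = c("TGCCGC", "GGCCGC"),
    random_window_n_cpg = 50
  )
  attr(cfg, "provenance") <- c(
    tile_kb_array = "fixed 20-kb consecutive genome windows for array quantification",
    min_cpg_array = "minimum of 3 informative array probes per 20-kb window",
    tile_kb_sc = "50-kb tiles for single-cell library quantification",
    min_sites_sc = "minimum of 5 observed CpGs per window in single-cell data",
    tile_kb_grouped = "20-kb tiles for grouped (pooled) library quantification",
    min_sites_grouped = "minimum of 10 observed CpGs per window in grouped data",
    qc_window_kb = "100-kb overlapping windows for initial per-cell QC profiles",
    qc_step_kb = "10-kb step size of the sliding QC windows",
    domain_tile_kb = "10-kb tiles underlying domain segmentation",
    domain_hi_pct = "adjacent windows > 70% methylation merge into methylated domains (strict)",
    domain_lo_pct = "adjacent windows < 30% methylation merge into unmethylated domains (strict)",
    domain_min_kb = "merged domains are kept only at a size of >= 50 kb",
    cgi_meth_pct = "reference-methylated CGIs exceed 70% methylation (strict)",
    cgi_unmeth_pct = "reference-unmethylated CGIs fall below 20% methylation (strict)",
    hypo_ratio = "hypomethylated regions have a mole/control methylation ratio < 0.65 (strict)",
    hypo_min_cpg = "hypomethylated-region windows need at least 10 covered CpGs",
    maintenance_min_oocyte_pct = "maintenance analysis keeps features with >= 20% residual oocyte methylation",
    perfect_maintenance_ratio = "perfect maternal-allele maintenance in a diploid gives an embryo/oocyte ratio of 0.5",
    zfp57_motifs = "ZFP57 binds the hexanucleotide TGCCGC and the alternative site GGCCGC",
    random_window_n_cpg = "variability baseline uses random genome-wide windows of 50 consecutive CpGs"
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg a `pipeline_config` list.
#' @return `cfg`, invisibly usable, after range checks; errors name the
#'   offending field and bound.
#' @export
validate_config <- function(cfg) {
  pct_fields <- c("domain_hi_pct", "domain_lo_pct", "cgi_meth_pct",
                  "cgi_unmeth_pct", "maintenance_min_oocyte_pct")
  for (f in pct_fields) assert_scalar_number(cfg[[f]], f, 0, 100, lo_open = TRUE)
  for (f in c("tile_kb_array", "tile_kb_sc", "tile_kb_grouped", "qc_window_kb",
              "qc_step_kb", "domain_tile_kb", "domain_min_kb"))
    assert_scalar_number(cfg[[f]], f, 0, Inf, lo_open = TRUE)
  for (f in c("min_cpg_array", "min_sites_sc", "min_sites_grouped",
              "hypo_min_cpg", "random_window_n_cpg"))
    assert_scalar_number(cfg[[f]], f, 1, Inf)
  assert_scalar_number(cfg$hypo_ratio, "hypo_ratio", 0, 1,
                       lo_open = TRUE, hi_open = TRUE)
  assert_scalar_number(cfg$perfect_maintenance_ratio,
                       "perfect_maintenance_ratio", 0, 1, lo_open = TRUE)
  if (cfg$domain_lo_pct >= cfg$domain_hi_pct)
    stop_mi("domain_lo_pct (%s) must be below domain_hi_pct (%s)",
            cfg$domain_lo_pct, cfg$domain_hi_pct)
  if (cfg$qc_step_kb > cfg$qc_window_kb)
    stop_mi("qc_step_kb must not exceed qc_window_kb")
  if (!is.character(cfg$zfp57_motifs) || length(cfg$zfp57_motifs) < 1 ||
      any(!grepl("^[ACGT]+$", cfg$zfp57_motifs)))
    stop_mi("zfp57_motifs must be DNA strings over A/C/G/T")
  prov <- attr(cfg, "provenance")
  missing_prov <- setdiff(names(unclass(cfg)), names(prov))
  if (length(missing_prov))
    stop_mi("fields without provenance: %s", paste(missing_prov, collapse = ", "))
  cfg
}

#' Load a configuration with overrides from a key = value file
#'
#' Lines of the form `key = value` override the defaults of
#' [default_config()]; blank lines and lines starting with `#` are ignored.
#' `zfp57_motifs` takes a comma-separated list. Unknown keys and out-of-range
#' values are errors.
#'
#' @param path path to a plain-text config file.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop_mi("malformed config line: '%s'", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(unclass(cfg)))
      stop_mi("unknown config key: '%s'", key)
    if (key == "zfp57_motifs") {
      cfg[[key]] <- toupper(trimws(strsplit(val, ",")[[1]]))
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop_mi("non-numeric value for '%s': '%s'", key, val)
      cfg[[key]] <- num
    }
  }
  validate_config(cfg)
}
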