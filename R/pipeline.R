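#' Write a full synthetic study to disk
#'
#' Generates the toy genome and every simulated input the pipeline consumes
#' (single cells, pooled calls, bulk reference oocyte and sperm, embryo,
#' mole/placenta betas, feature annotations) and writes them under `dir` in
#' the standard formats (FASTA, BED, coverage text, TSV).
#'
#' @param sim a [sim_config()].
#' @param dir output directory (created if missing).
#' @param n_cells single cells per genotype (default 5).
#' @return the input manifest: a named list of file paths (`genome`,
#'   `features`, `cells_control`, `cells_mutant`, `pooled_control`,
#'   `pooled_mutant`, `ref_oocyte`, `ref_sperm`, `embryo`, `betas`).
#' @export
simulate_study <- function(sim, dir, n_cells = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- build_toy_genome(sim)
  true <- simulate_oocyte(sim, toy$genome, toy$features)
  p <- function(...) file.path(dir, paste0(...))
  write_genome(toy$genome, p("genome.fa"))
  write_features(toy$features, p("features.bed"))
  man <- list(genome = p("genome.fa"), features = p("features.bed"))
  for (track in c("control", "mutant")) {
    cells <- lapply(seq_len(n_cells), function(i)
      sample_cell(true, track, cell_index = i))
    paths <- vapply(seq_len(n_cells), function(i) {
      write_cpg_calls(cells[[i]], p(track, "_cell", i, ".cov"))
      p(track, "_cell", i, ".cov")
    }, character(1))
    man[[paste0("cells_", track)]] <- paths
    pooled <- pool_cells(cells, library_id = paste0("pooled_", track))
    write_cpg_calls(pooled, p("pooled_", track, ".cov"))
    man[[paste0("pooled_", track)]] <- p("pooled_", track, ".cov")
  }
  write_cpg_calls(sample_bulk(true, "control"), p("ref_oocyte.cov"))
  write_cpg_calls(sample_bulk(true, "sperm"), p("ref_sperm.cov"))
  write_cpg_calls(simulate_embryo(true), p("embryo.cov"))
  write_beta_table(simulate_mole_betas(true), p("betas.tsv"))
  man$ref_oocyte <- p("ref_oocyte.cov")
  man$ref_sperm <- p("ref_sperm.cov")
  man$embryo <- p("embryo.cov")
  man$betas <- p("betas.tsv")
  man
}

#' Run the whole analysis pipeline
#'
#' Orchestrates the stages end to end from an input manifest: window
#' quantification of cells and pooled libraries (with the all-samples
#' coverage intersection), domain segmentation of the reference germline
#' methylomes and parental-unique filtering, gDMR/CGI feature scoring and
#' deltas, hypomethylated-region calling on the array data, the
#' embryo-to-oocyte maintenance ratio, ZFP57 motif methylation per cell, and
#' the mapped statistical comparisons. Stages whose inputs are missing from
#' the manifest are skipped, and the run report records why.
#'
#' @param manifest named list of input paths as produced by
#'   [simulate_study()]; recognised roles: `genome`, `features`,
#'   `cells_control`, `cells_mutant`, `pooled_control`, `pooled_mutant`,
#'   `ref_oocyte`, `ref_sperm`, `embryo`, `betas`.
#' @param cfg a [default_config()] list.
#' @param outdir output directory for stage tables and the JSON run report.
#' @return the run report (also written to `outdir/report.json`): thresholds
#'   with provenance, per-stage input/output counts and skip reasons, and the
#'   headline statistics.
#' @export
run_pipeline <- function(manifest, cfg = default_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  need <- c("genome", "features", "cells_control", "cells_mutant",
            "pooled_control", "pooled_mutant", "ref_oocyte", "ref_sperm")
  missing_roles <- setdiff(need, names(manifest))
  if (length(missing_roles))
    stop_mi("manifest is missing required role(s): %s",
            paste(missing_roles, collapse = ", "))
  prov <- attr(cfg, "provenance")
  report <- list(thresholds = lapply(stats::setNames(nm = names(unclass(cfg))),
                                     function(f) list(value = cfg[[f]],
                                                      provenance = unname(prov[f]))),
                 stages = list())
  genome <- read_genome(manifest$genome)
  features <- read_features(manifest$features)
  cells_control <- lapply(manifest$cells_control, read_cpg_calls)
  cells_mutant <- lapply(manifest$cells_mutant, read_cpg_calls)
  pooled_control <- read_cpg_calls(manifest$pooled_control, "pooled_control")
  pooled_mutant <- read_cpg_calls(manifest$pooled_mutant, "pooled_mutant")
  ref_oocyte <- read_cpg_calls(manifest$ref_oocyte, "ref_oocyte")
  ref_sperm <- read_cpg_calls(manifest$ref_sperm, "ref_sperm")

  # stage: grouped window quantification with all-samples intersection
  tiles <- make_tiles(genome, cfg$tile_kb_grouped)
  q_ctrl <- quantify(pooled_control, tiles, cfg$min_sites_grouped)
  q_mut <- quantify(pooled_mutant, tiles, cfg$min_sites_grouped)
  ic <- intersect_covered(list(q_ctrl, q_mut))
  readr::write_tsv(ic$tables[[1]], file.path(outdir, "windows_control.tsv"),
                   progress = FALSE)
  readr::write_tsv(ic$tables[[2]], file.path(outdir, "windows_mutant.tsv"),
                   progress = FALSE)
  report$stages$window_quant <- list(
    windows_total = ic$n_total, windows_retained = ic$n_kept,
    retention_pct = ic$retention_pct,
    global_meth_control = global_methylation(pooled_control),
    global_meth_mutant = global_methylation(pooled_mutant))

  # stage: domain segmentation of the reference germlines
  tiles10 <- make_tiles(genome, cfg$domain_tile_kb)
  dom_oocyte <- call_domains(quantify(ref_oocyte, tiles10,
                                      cfg$min_sites_grouped), cfg)
  dom_sperm <- call_domains(quantify(ref_sperm, tiles10,
                                     cfg$min_sites_grouped), cfg)
  uniq <- parental_unique(dom_oocyte, dom_sperm)
  for (nm in c("dom_oocyte", "dom_sperm"))
    readr::write_tsv(as_tibble(get(nm)), file.path(outdir, paste0(nm, ".tsv")),
                     progress = FALSE)
  report$stages$domains <- list(
    oocyte_domains = nrow(dom_oocyte), sperm_domains = nrow(dom_sperm),
    maternal_unique = nrow(uniq$maternal_only),
    paternal_unique = nrow(uniq$paternal_only))

  # stage: feature scoring and deltas
  gdmrs <- filter(features, .data$category == "maternal_gDMR")
  fm_ctrl <- feature_methylation(pooled_control, features, min_sites = 10)
  fm_mut <- feature_methylation(pooled_mutant, features, min_sites = 10)
  deltas <- delta_table(fm_mut, fm_ctrl)
  readr::write_tsv(deltas$by_category,
                   file.path(outdir, "feature_deltas.tsv"), progress = FALSE)
  cgis <- filter(features, .data$category == "CGI")
  cgi_ref <- classify_cgis(feature_methylation(ref_oocyte, cgis,
                                               min_sites = 10),
                           hi = cfg$cgi_meth_pct, lo = cfg$cgi_unmeth_pct)
  report$stages$features <- list(
    features_scored = nrow(deltas$features),
    features_used = sum(!is.na(deltas$features$delta)),
    cgi_classes = as.list(table(cgi_ref$cgi_class)))

  # stage: mole hypomethylated regions (skippable)
  if (!is.null(manifest$betas)) {
    betas <- read_beta_table(manifest$betas)
    tiles20 <- make_tiles(genome, cfg$tile_kb_array)
    aw <- array_quantify(betas, tiles20, min_probes = cfg$min_cpg_array)
    mole_t <- aw[["mole"]]
    ctrl_t <- aw[setdiff(names(aw), "mole")]
    if (is.null(mole_t)) {
      report$stages$mole <- list(skipped = "no sample named 'mole' in betas")
    } else {
      hypo <- hypomethylated_regions(mole_t, ctrl_t, cfg)
      ann <- annotate_overlaps(hypo[hypo$flagged, ], features)
      readr::write_tsv(hypo, file.path(outdir, "hypomethylated_windows.tsv"),
                       progress = FALSE)
      report$stages$mole <- list(
        windows_analysable = attr(hypo, "n_analysable"),
        windows_flagged = attr(hypo, "n_flagged"),
        pct_flagged = attr(hypo, "pct_flagged"),
        overlaps = stats::setNames(as.list(ann$counts$n_regions),
                                   ann$counts$category))
    }
  } else {
    report$stages$mole <- list(skipped = "no array betas in manifest")
  }

  # stage: maintenance ratio (skippable without an embryo library)
  if (!is.null(manifest$embryo)) {
    embryo <- read_cpg_calls(manifest$embryo, "embryo")
    fm_oo <- feature_methylation(pooled_mutant, gdmrs, min_sites = 10)
    fm_em <- feature_methylation(embryo, gdmrs, min_sites = 10)
    mt <- maintenance_ratio(fm_oo, fm_em, cfg)
    cs <- class_summary(mt)
    readr::write_tsv(as_tibble(mt), file.path(outdir, "maintenance.tsv"),
                     progress = FALSE)
    report$stages$maintenance <- list(
      features_in = nrow(gdmrs), features_retained = nrow(mt),
      class_medians = stats::setNames(as.list(cs$median_ratio), cs$class))
  } else {
    report$stages$maintenance <-
      list(skipped = "no embryo library in manifest")
  }

  # stage: ZFP57 motif methylation per cell
  sites <- scan_motifs(genome, features, motifs = cfg$zfp57_motifs)
  per_cell <- bind_rows(lapply(c(cells_control, cells_mutant), function(cell) {
    r <- cell_motif_methylation(cell, sites)
    tibble(cell = attr(cell, "library_id"), meth_pct = r$meth_pct,
           n_observed = r$n_observed)
  }))
  readr::write_tsv(per_cell, file.path(outdir, "zfp57_per_cell.tsv"),
                   progress = FALSE)
  report$stages$zfp57 <- list(n_sites = nrow(sites),
                              cells_scored = sum(!is.na(per_cell$meth_pct)))

  # stage: statistics mapped to their comparisons
  glob_ctrl <- vapply(cells_control, global_methylation, numeric(1))
  glob_mut <- vapply(cells_mutant, global_methylation, numeric(1))
  tt <- unpaired_t(glob_mut, glob_ctrl)
  dd <- deltas$features[!is.na(deltas$features$delta), ]
  wt <- paired_feature_test(dd$case_pct, dd$control_pct)
  report$stages$stats <- list(
    global_meth_t = list(statistic = tt$statistic, p_value = tt$p_value),
    feature_wilcoxon = list(statistic = wt$statistic, p_value = wt$p_value,
                            n_pairs = wt$n_pairs))

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
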