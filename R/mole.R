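#' Call hypomethylated regions in molar tissue
#'
#' Flags 20-kb windows whose mole/control methylation ratio is strictly below
#' `cfg$hypo_ratio` (0.65) among windows with at least `cfg$hypo_min_cpg`
#' (10) covered probes in the mole and in every control sample. The control
#' value per window is the mean across the control samples. Windows whose
#' control value is 0 while the mole value is positive are skipped with a
#' warning (undefined ratio).
#'
#' @param mole window methylation tibble of the molar sample.
#' @param controls list of window methylation tibbles of control placentas,
#'   built on the identical tiling.
#' @param cfg a [default_config()] list.
#' @return tibble of analysable windows with `mole_pct`, `control_pct`,
#'   `ratio`, `n_sites`, `flagged`; attributes `n_analysable`, `n_flagged`
#'   and `pct_flagged` summarise the call.
#' @export
hypomethylated_regions <- function(mole, controls, cfg = default_config()) {
  stopifnot(length(controls) >= 1)
  key <- paste(mole$chrom, mole$start, mole$end)
  for (t in controls)
    if (!identical(paste(t$chrom, t$start, t$end), key))
      stop_mi("mole and control tables are not on the same tiling")
  ctrl_mat <- vapply(controls, function(t) t$meth_pct, numeric(nrow(mole)))
  ctrl_mat <- matrix(ctrl_mat, nrow = nrow(mole))
  ctrl_n <- vapply(controls, function(t) t$n_sites, integer(nrow(mole)))
  ctrl_n <- matrix(ctrl_n, nrow = nrow(mole))
  control_pct <- rowMeans(ctrl_mat)
  covered <- mole$n_sites >= cfg$hypo_min_cpg &
    apply(ctrl_n >= cfg$hypo_min_cpg, 1, all) &
    !is.na(mole$meth_pct) & !is.na(control_pct)
  undef <- covered & control_pct == 0 & mole$meth_pct > 0
  if (any(undef))
    warn_mi("%d window(s) skipped: control methylation 0 with mole > 0",
            sum(undef))
  # control = mole = 0 is perfect retention, ratio 1 by convention
  keep <- covered & !undef
  out <- tibble(chrom = mole$chrom[keep], start = mole$start[keep],
                end = mole$end[keep],
                mole_pct = mole$meth_pct[keep],
                control_pct = control_pct[keep],
                n_sites = mole$n_sites[keep])
  out$ratio <- ifelse(out$control_pct == 0, 1, out$mole_pct / out$control_pct)
  out$flagged <- out$ratio < cfg$hypo_ratio
  attr(out, "n_analysable") <- nrow(out)
  attr(out, "n_flagged") <- sum(out$flagged)
  attr(out, "pct_flagged") <- 100 * sum(out$flagged) / max(nrow(out), 1)
  out
}

#' Annotate hypomethylated regions with imprinted-DMR overlaps
#'
#' A region overlaps a feature iff their half-open intervals share at least
#' one base pair; adjacent intervals (0-bp gap) do not overlap. Each region
#' counts once per category however many features of that category it hits.
#'
#' @param regions tibble of regions (`chrom`, `start`, `end`), e.g. the
#'   flagged rows of [hypomethylated_regions()].
#' @param gdmrs a [feature_table()] of imprinted DMRs (any categories).
#' @return list with `per_region` (regions plus a comma-separated
#'   `categories` column) and `counts` (regions overlapped per category).
#' @export
annotate_overlaps <- function(regions, gdmrs) {
  lv <- chrom_universe(regions, gdmrs)
  gr_r <- gr_intervals(regions, lv)
  gr_g <- gr_intervals(gdmrs, lv)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g, minoverlap = 1L)
  q <- S4Vectors::queryHits(hits)
  cat <- gdmrs$category[S4Vectors::subjectHits(hits)]
  cats_per_region <- tapply(cat, q, function(x) sort(unique(x)))
  categories <- rep("", nrow(regions))
  if (length(cats_per_region))
    categories[as.integer(names(cats_per_region))] <-
      vapply(cats_per_region, paste, character(1), collapse = ",")
  counts_by_cat <- if (length(hits)) {
    pairs <- distinct(tibble(region = q, category = cat))
    summarise(group_by(pairs, .data$category),
              n_regions = dplyr::n(), .groups = "drop")
  } else {
    tibble(category = character(), n_regions = integer())
  }
  per_region <- as_tibble(regions)
  per_region$categories <- categories
  list(per_region = per_region, counts = counts_by_cat)
}
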