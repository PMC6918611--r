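#' Feature-level methylation scoring
#'
#' Scores each feature interval as the unweighted mean of per-CpG methylation
#' percentages (sequencing calls) or `100 *` mean beta (array probes) of the
#' sites inside it. Features observing fewer than `min_sites` sites get a
#' missing value. This is [quantify()] with windows equal to the feature
#' intervals.
#'
#' @param x a [cpg_calls()] table or a [beta_table()].
#' @param features a [feature_table()].
#' @param min_sites minimum observed sites per feature (e.g. 10 CpGs per gDMR
#'   for single-cell calls).
#' @return a feature methylation tibble: `name`, `category`, `chrom`,
#'   `start`, `end`, `meth_pct`, `n_sites`, `sample_id`; one row per feature
#'   (and per sample for beta tables).
#' @export
feature_methylation <- function(x, features, min_sites = 1) {
  win <- features[, c("chrom", "start", "end")]
  if (inherits(x, "beta_table")) {
    per_sample <- array_quantify(x, win, min_probes = min_sites)
    out <- bind_rows(lapply(per_sample, function(t) {
      tibble(name = features$name, category = features$category,
             chrom = t$chrom, start = t$start, end = t$end,
             meth_pct = t$meth_pct, n_sites = t$n_sites,
             sample_id = t$sample_id)
    }))
  } else {
    t <- quantify(x, win, min_sites = min_sites)
    out <- tibble(name = features$name, category = features$category,
                  chrom = t$chrom, start = t$start, end = t$end,
                  meth_pct = t$meth_pct, n_sites = t$n_sites,
                  sample_id = t$sample_id)
  }
  out
}

#' Classify CpG islands from a reference methylome
#'
#' Labels CGIs `"methylated"` above `hi` (strictly `> 70`\%),
#' `"unmethylated"` below `lo` (strictly `< 20`\%), `"intermediate"`
#' otherwise and `"unclassified"` where the reference value is missing.
#'
#' @param reference feature methylation tibble (from [feature_methylation()])
#'   of the CGIs in the reference (control oocyte) methylome.
#' @param hi,lo class thresholds in percent.
#' @return `reference` with a `cgi_class` column.
#' @export
classify_cgis <- function(reference, hi = 70, lo = 20) {
  cls <- ifelse(is.na(reference$meth_pct), "unclassified",
                ifelse(reference$meth_pct > hi, "methylated",
                       ifelse(reference$meth_pct < lo, "unmethylated",
                              "intermediate")))
  mutate(reference, cgi_class = cls)
}

#' Per-feature and per-category methylation change
#'
#' Change is `control - case` per feature (positive = loss of methylation in
#' the case sample). Features missing either value are dropped and counted.
#'
#' @param case,control feature methylation tibbles over a shared feature set.
#' @return list with `features` (per-feature deltas) and `by_category`
#'   (unweighted mean and median change, n used, n dropped).
#' @export
delta_table <- function(case, control) {
  shared <- intersect(case$name, control$name)
  if (length(shared) == 0) stop_mi("case and control share no features")
  ca <- case[match(shared, case$name), ]
  co <- control[match(shared, control$name), ]
  feats <- tibble(name = shared, category = ca$category,
                  control_pct = co$meth_pct, case_pct = ca$meth_pct,
                  delta = co$meth_pct - ca$meth_pct)
  used <- filter(feats, !is.na(.data$delta))
  by_cat <- summarise(group_by(used, .data$category),
                      mean_delta = mean(.data$delta),
                      median_delta = stats::median(.data$delta),
                      n = dplyr::n(), .groups = "drop")
  dropped <- summarise(group_by(filter(feats, is.na(.data$delta)),
                                .data$category),
                       n_dropped = dplyr::n(), .groups = "drop")
  by_cat <- left_join(by_cat, dropped, by = "category")
  by_cat$n_dropped[is.na(by_cat$n_dropped)] <- 0L
  list(features = feats, by_category = by_cat)
}

#' Match control regions to gDMRs by methylation and CpG density
#'
#' For each gDMR, samples candidate windows whose reference methylation is
#' within `tol_meth` percentage points and whose CpG density (observed
#' CpGs/kb in the reference calls) is within a relative `tol_density` band of
#' the gDMR's. Candidates overlapping any gDMR are excluded. Deterministic
#' given `seed`.
#'
#' @param gdmrs feature methylation tibble of the gDMRs in the reference
#'   methylome (needs `meth_pct` and `n_sites`).
#' @param candidates window tibble (`chrom`, `start`, `end`) of candidate
#'   regions.
#' @param reference_calls [cpg_calls()] of the reference methylome, used to
#'   score candidate methylation and density.
#' @param tol_meth tolerance in percentage points (default 5).
#' @param tol_density relative CpG-density tolerance (default 0.2).
#' @param n_per_gdmr matched regions sampled per gDMR (default 10).
#' @param min_sites minimum observed CpGs for a candidate to be scored.
#' @param seed RNG seed for the sampling.
#' @return list with `matched` (a [feature_table()] of matched regions, names
#'   `<gdmr>_match<i>`) and `unmatched` (gDMR names with no eligible
#'   candidate).
#' @export
match_control_regions <- function(gdmrs, candidates, reference_calls,
                                  tol_meth = 5, tol_density = 0.2,
                                  n_per_gdmr = 10, min_sites = 5, seed = 1) {
  lv <- chrom_universe(candidates, gdmrs)
  gr_cand <- gr_intervals(candidates, lv)
  gr_gdmr <- gr_intervals(gdmrs, lv)
  ov <- GenomicRanges::countOverlaps(gr_cand, gr_gdmr)
  candidates <- candidates[ov == 0, , drop = FALSE]
  cand_q <- quantify(reference_calls, candidates, min_sites = min_sites)
  cand_q$density <- cand_q$n_sites / ((cand_q$end - cand_q$start) / 1000)
  g_density <- gdmrs$n_sites / ((gdmrs$end - gdmrs$start) / 1000)
  matched <- list(); unmatched <- character()
  with_derived_seed(seed, 0, {
    for (i in seq_len(nrow(gdmrs))) {
      if (is.na(gdmrs$meth_pct[i])) { unmatched <- c(unmatched, gdmrs$name[i]); next }
      ok <- !is.na(cand_q$meth_pct) &
        abs(cand_q$meth_pct - gdmrs$meth_pct[i]) <= tol_meth &
        abs(cand_q$density - g_density[i]) <= tol_density * g_density[i]
      idx <- which(ok)
      if (length(idx) == 0) {
        warn_mi("no matched control region for gDMR '%s'", gdmrs$name[i])
        unmatched <- c(unmatched, gdmrs$name[i])
        next
      }
      take <- if (length(idx) <= n_per_gdmr) idx else sample(idx, n_per_gdmr)
      matched[[gdmrs$name[i]]] <- tibble(
        chrom = cand_q$chrom[take], start = cand_q$start[take],
        end = cand_q$end[take],
        name = paste0(gdmrs$name[i], "_match", seq_along(take)),
        category = "other")
    }
  })
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), category = character())
  list(matched = feature_table(if (length(matched)) bind_rows(matched)
                               else empty),
       unmatched = unmatched)
}

#' Loss-of-methylation variability over genes vs random CpG windows
#'
#' Computes per-gene loss of methylation (LoM = control - case) and its
#' standard deviation, and the same over random genome-wide windows spanning
#' exactly `n_cpg` consecutive CpGs of the reference CpG universe (the CpGs
#' observed in the control calls). A smaller gene-level s.d. than
#' window-level s.d. indicates that LoM is coherent within genes.
#'
#' @param case,control [cpg_calls()] tables.
#' @param genes [feature_table()] of genes.
#' @param n_windows number of random CpG windows (default 200).
#' @param n_cpg CpGs per random window (default 50).
#' @param min_sites minimum observed CpGs per region in each sample.
#' @param seed RNG seed for the random windows.
#' @return list with `gene_lom` (per-gene tibble), `gene_sd`, `window_lom`,
#'   `window_sd`.
#' @export
variability_profile <- function(case, control, genes, n_windows = 200,
                                n_cpg = 50, min_sites = 10, seed = 1) {
  g_case <- feature_methylation(case, genes, min_sites = min_sites)
  g_ctrl <- feature_methylation(control, genes, min_sites = min_sites)
  gene_lom <- tibble(name = genes$name,
                     lom = g_ctrl$meth_pct - g_case$meth_pct)
  gene_lom <- filter(gene_lom, !is.na(.data$lom))
  universe <- as_tibble(control)[, c("chrom", "pos")]
  wins <- with_derived_seed(seed, 1, {
    by_chrom <- split(universe$pos, universe$chrom)
    starts <- list()
    for (ch in names(by_chrom)) {
      pos <- sort(by_chrom[[ch]])
      if (length(pos) < n_cpg) next
      starts[[ch]] <- tibble(chrom = ch,
                             i = seq_len(length(pos) - n_cpg + 1),
                             start = pos[seq_len(length(pos) - n_cpg + 1)] - 1L,
                             end = pos[seq_len(length(pos) - n_cpg + 1) + n_cpg - 1L] + 1L)
    }
    all_starts <- bind_rows(starts)
    if (nrow(all_starts) == 0) stop_mi("too few CpGs for %d-CpG windows", n_cpg)
    take <- sample(nrow(all_starts), min(n_windows, nrow(all_starts)))
    all_starts[take, c("chrom", "start", "end")]
  })
  w_case <- quantify(case, wins, min_sites = min_sites)
  w_ctrl <- quantify(control, wins, min_sites = min_sites)
  window_lom <- w_ctrl$meth_pct - w_case$meth_pct
  window_lom <- window_lom[!is.na(window_lom)]
  list(gene_lom = gene_lom,
       gene_sd = stats::sd(gene_lom$lom),
       window_lom = window_lom,
       window_sd = stats::sd(window_lom))
}

#' Correlation between loss of methylation and expression
#'
#' Rank (Spearman) correlation by default, since expression levels span
#' orders of magnitude; switchable to Pearson.
#'
#' @param delta_by_gene tibble with `name` and `delta` (per-gene LoM).
#' @param expression tibble with `name` and `expression`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `estimate`, `p_value`, `n`, `method`.
#' @export
expression_correlation <- function(delta_by_gene, expression,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  joined <- inner_join(delta_by_gene, expression, by = "name")
  joined <- filter(joined, !is.na(.data$delta) & !is.na(.data$expression))
  if (nrow(joined) < 3)
    stop_mi("fewer than 3 genes with both LoM and expression")
  if (stats::sd(joined$expression) == 0 || stats::sd(joined$delta) == 0)
    stop_mi("correlation undefined: constant %s",
            if (stats::sd(joined$expression) == 0) "expression" else "LoM")
  ct <- suppressWarnings(
    stats::cor.test(joined$delta, joined$expression, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = nrow(joined), method = method)
}
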