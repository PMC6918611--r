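#' Fixed genome tiles
#'
#' Consecutive, non-overlapping windows of fixed width covering each
#' chromosome; the final window per chromosome is truncated at the chromosome
#' end. Coordinates are 0-based half-open.
#'
#' @param genome a [genome_ref()] or a named vector of chromosome lengths.
#' @param width_kb tile width in kilobases.
#' @return tibble with `chrom`, `start`, `end`.
#' @export
make_tiles <- function(genome, width_kb) {
  assert_scalar_number(width_kb, "width_kb", 0, Inf, lo_open = TRUE)
  lens <- if (inherits(genome, "genome_ref")) genome$lengths else genome
  w <- as.integer(round(width_kb * 1000))
  out <- lapply(names(lens), function(ch) {
    starts <- seq.int(0L, lens[[ch]] - 1L, by = w)
    tibble(chrom = ch, start = starts, end = pmin(starts + w, lens[[ch]]))
  })
  bind_rows(out)
}

#' Sliding genome windows
#'
#' Overlapping windows with starts on a step grid, used for per-cell QC
#' profiles. With `step_kb == width_kb` this degenerates to [make_tiles()].
#'
#' @param genome a [genome_ref()] or named chromosome-length vector.
#' @param width_kb window width in kb (default 100).
#' @param step_kb step size in kb (default 10); must not exceed the width.
#' @return tibble with `chrom`, `start`, `end` (ends clipped at chromosome
#'   ends).
#' @export
make_sliding <- function(genome, width_kb = 100, step_kb = 10) {
  assert_scalar_number(width_kb, "width_kb", 0, Inf, lo_open = TRUE)
  assert_scalar_number(step_kb, "step_kb", 0, width_kb, lo_open = TRUE)
  lens <- if (inherits(genome, "genome_ref")) genome$lengths else genome
  w <- as.integer(round(width_kb * 1000))
  s <- as.integer(round(step_kb * 1000))
  out <- lapply(names(lens), function(ch) {
    starts <- seq.int(0L, lens[[ch]] - 1L, by = s)
    tibble(chrom = ch, start = starts, end = pmin(starts + w, lens[[ch]]))
  })
  bind_rows(out)
}

#' Windowed methylation quantification
#'
#' Computes per-CpG methylation percentages (`100 * meth / (meth + unmeth)`)
#' and averages them, unweighted, within each window ("per-base then
#' average"). Windows observing fewer than `min_sites` CpGs get a missing
#' methylation value; their site count is still reported. A CpG on a tile
#' boundary belongs to the window whose half-open interval contains its
#' 0-based position.
#'
#' @param calls a [cpg_calls()] table.
#' @param windows tibble of windows (`chrom`, `start`, `end`), e.g. from
#'   [make_tiles()] or [make_sliding()]; overlapping windows each receive
#'   every CpG they contain.
#' @param min_sites minimum observed CpGs for a window value.
#' @param sample_id sample label for the output, default the calls' library id.
#' @return a window methylation tibble: `chrom`, `start`, `end`, `meth_pct`
#'   (`NA` below `min_sites`), `n_sites`, `sample_id`.
#' @export
quantify <- function(calls, windows, min_sites,
                     sample_id = attr(calls, "library_id") %||% "sample") {
  assert_scalar_number(min_sites, "min_sites", 1, Inf)
  lv <- chrom_universe(windows, calls)
  gr_w <- gr_intervals(windows, lv)
  gr_c <- gr_positions(calls, lv)
  hits <- GenomicRanges::findOverlaps(gr_w, gr_c)
  pct <- 100 * calls$meth / (calls$meth + calls$unmeth)
  q <- S4Vectors::queryHits(hits)
  p <- pct[S4Vectors::subjectHits(hits)]
  n_sites <- integer(nrow(windows))
  sum_pct <- numeric(nrow(windows))
  if (length(q)) {
    tab <- tapply(p, q, function(v) c(length(v), sum(v)))
    idx <- as.integer(names(tab))
    n_sites[idx] <- vapply(tab, `[`, numeric(1), 1)
    sum_pct[idx] <- vapply(tab, `[`, numeric(1), 2)
  }
  meth_pct <- ifelse(n_sites >= min_sites, sum_pct / pmax(n_sites, 1), NA_real_)
  tibble(chrom = windows$chrom, start = windows$start, end = windows$end,
         meth_pct = meth_pct, n_sites = as.integer(n_sites),
         sample_id = sample_id)
}

#' Intersection of covered windows across samples
#'
#' Keeps only windows with the required minimal coverage (a non-missing
#' value) in all samples, and reports the retention.
#'
#' @param tables list of window methylation tables built on identical window
#'   lists.
#' @return list with `tables` (each filtered to the common windows, same
#'   order), `windows` (the retained window keys), `n_total`, `n_kept` and
#'   `retention_pct`.
#' @export
intersect_covered <- function(tables) {
  stopifnot(length(tables) >= 1)
  key <- function(t) paste(t$chrom, t$start, t$end)
  k0 <- key(tables[[1]])
  for (t in tables[-1]) {
    if (!identical(key(t), k0))
      stop_mi("window lists differ between tables; build them on one tiling")
  }
  ok <- Reduce(`&`, lapply(tables, function(t) !is.na(t$meth_pct)))
  list(tables = lapply(tables, function(t) t[ok, , drop = FALSE]),
       windows = tables[[1]][ok, c("chrom", "start", "end")],
       n_total = length(ok),
       n_kept = sum(ok),
       retention_pct = 100 * sum(ok) / length(ok))
}

#' Pool single-cell call tables
#'
#' Sums methylated/unmethylated counts per CpG across cells, the grouping
#' used to increase genome-wide CpG coverage before 20-kb quantification.
#'
#' @param cells list of [cpg_calls()] tables (>= 1).
#' @param library_id id for the pooled table.
#' @return a [cpg_calls()] table covering the union of observed CpGs.
#' @export
pool_cells <- function(cells, library_id = "pooled") {
  stopifnot(length(cells) >= 1)
  all <- bind_rows(lapply(cells, function(c) as_tibble(c)))
  pooled <- summarise(group_by(all, .data$chrom, .data$pos),
                      meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                      .groups = "drop")
  cpg_calls(pooled, library_id = library_id)
}

#' Global CpG methylation of a library
#'
#' Unweighted mean of per-CpG methylation percentages over all observed CpGs,
#' i.e. the single-window limit of [quantify()].
#'
#' @param calls a [cpg_calls()] table with >= 1 record.
#' @return global methylation percentage.
#' @export
global_methylation <- function(calls) {
  if (nrow(calls) == 0) stop_mi("no CpG records; global methylation undefined")
  mean(100 * calls$meth / (calls$meth + calls$unmeth))
}

#' Windowed quantification of array beta values
#'
#' Window value is `100 *` the mean beta of informative (non-missing) probes
#' inside the window; windows with fewer than `min_probes` informative probes
#' are missing. Returns one table per sample so that [intersect_covered()]
#' applies across samples.
#'
#' @param betas a [beta_table()].
#' @param windows window tibble (`chrom`, `start`, `end`).
#' @param min_probes minimum informative probes per window (default 3).
#' @return named list of window methylation tibbles, one per sample.
#' @export
array_quantify <- function(betas, windows, min_probes = 3) {
  assert_scalar_number(min_probes, "min_probes", 1, Inf)
  lv <- chrom_universe(windows, betas)
  gr_w <- gr_intervals(windows, lv)
  gr_p <- gr_positions(betas, lv)
  hits <- GenomicRanges::findOverlaps(gr_w, gr_p)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  samples <- attr(betas, "samples")
  out <- lapply(samples, function(smp) {
    v <- betas[[smp]][s]
    keep <- !is.na(v)
    n_sites <- integer(nrow(windows))
    mean_b <- rep(NA_real_, nrow(windows))
    if (any(keep)) {
      tb <- tapply(v[keep], q[keep], function(x) c(length(x), mean(x)))
      idx <- as.integer(names(tb))
      n_sites[idx] <- vapply(tb, `[`, numeric(1), 1)
      mean_b[idx] <- vapply(tb, `[`, numeric(1), 2)
    }
    tibble(chrom = windows$chrom, start = windows$start, end = windows$end,
           meth_pct = ifelse(n_sites >= min_probes, 100 * mean_b, NA_real_),
           n_sites = as.integer(n_sites), sample_id = smp)
  })
  stats::setNames(out, samples)
}
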