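#' Scan maternal gDMRs for ZFP57 binding motifs
#'
#' Exact-match scan of both strands for the ZFP57 hexamers (TGCCGC and the
#' alternative site GGCCGC) within each gDMR interval; occurrences must lie
#' wholly inside the interval. Each hexamer contains exactly one CpG
#' dinucleotide, whose plus-strand C position is recorded; occurrences on the
#' two strands marking the same CpG dyad are deduplicated by
#' `(chrom, cpg_pos)`.
#'
#' @param genome a [genome_ref()].
#' @param gdmrs a [feature_table()]; only rows whose category is in
#'   `categories` are scanned.
#' @param motifs hexamer motifs (default the two ZFP57 sites).
#' @param strand `"both"` (default) scans plus and minus strands; `"plus"`
#'   scans the plus strand only.
#' @param categories gDMR categories to scan (default maternal gDMRs).
#' @return a `zfp57_sites` tibble: `chrom`, `start` (0-based motif start),
#'   `end`, `strand`, `motif`, `gdmr`, `cpg_pos` (1-based plus-strand C of
#'   the motif's CpG dyad).
#' @export
scan_motifs <- function(genome, gdmrs,
                        motifs = default_config()$zfp57_motifs,
                        strand = c("both", "plus"),
                        categories = "maternal_gDMR") {
  strand <- match.arg(strand)
  use <- filter(as_tibble(gdmrs), .data$category %in% categories)
  rows <- list()
  for (i in seq_len(nrow(use))) {
    ch <- use$chrom[i]
    if (use$end[i] > genome$lengths[[ch]])
      stop_mi("gDMR '%s' extends beyond %s", use$name[i], ch)
    seq <- Biostrings::DNAString(genome_seq(genome, ch, use$start[i], use$end[i]))
    for (motif in motifs) {
      cpg_off <- as.integer(regexpr("CG", motif)) # 1-based offset inside motif
      if (cpg_off < 1 || length(gregexpr("CG", motif)[[1]]) != 1)
        stop_mi("motif '%s' must contain exactly one CpG", motif)
      plus <- Biostrings::matchPattern(Biostrings::DNAString(motif), seq)
      if (length(plus)) {
        m <- BiocGenerics::start(plus) # 1-based within gDMR
        rows[[length(rows) + 1]] <- tibble(
          chrom = ch, start = use$start[i] + m - 1L,
          end = use$start[i] + m - 1L + nchar(motif),
          strand = "+", motif = motif, gdmr = use$name[i],
          cpg_pos = use$start[i] + m - 1L + cpg_off)
      }
      if (strand == "both") {
        rc <- Biostrings::reverseComplement(Biostrings::DNAString(motif))
        minus <- Biostrings::matchPattern(rc, seq)
        if (length(minus)) {
          m <- BiocGenerics::start(minus)
          # motif offset j (1-based) maps to plus-strand position
          # start + m - 1 + (width - j); the dyad's plus-strand C sits at
          # the motif's G (offset cpg_off + 1)
          rows[[length(rows) + 1]] <- tibble(
            chrom = ch, start = use$start[i] + m - 1L,
            end = use$start[i] + m - 1L + nchar(motif),
            strand = "-", motif = motif, gdmr = use$name[i],
            cpg_pos = use$start[i] + m - 1L + nchar(motif) - cpg_off)
        }
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), motif = character(),
                  gdmr = character(), cpg_pos = integer())
  out <- arrange(out, .data$chrom, .data$cpg_pos, .data$strand)
  out <- distinct(out, .data$chrom, .data$cpg_pos, .keep_all = TRUE)
  class(out) <- c("zfp57_sites", class(tibble()))
  out
}

#' Per-cell methylation of ZFP57 motif CpGs
#'
#' The default statistic is the mean per-CpG methylation percentage over the
#' motif CpGs observed in the cell. The `"site-level"` variant instead counts
#' each observed binding site as methylated when its CpG is more than 50\%
#' methylated and reports the percentage of methylated sites; for binary
#' depth-1 single-cell calls the two coincide.
#'
#' @param cell a [cpg_calls()] table for one cell.
#' @param sites a `zfp57_sites` tibble from [scan_motifs()].
#' @param statistic `"per-cpg"` (default) or `"site-level"`.
#' @return list with `meth_pct` (`NA` with a warning when the cell observes
#'   no site CpG), `n_observed`, `n_sites`, `statistic`.
#' @export
cell_motif_methylation <- function(cell, sites,
                                   statistic = c("per-cpg", "site-level")) {
  statistic <- match.arg(statistic)
  key_sites <- paste(sites$chrom, sites$cpg_pos)
  idx <- match(paste(cell$chrom, cell$pos), key_sites)
  obs <- which(!is.na(idx))
  if (length(obs) == 0) {
    warn_mi("cell '%s' observes no ZFP57 motif CpG",
            attr(cell, "library_id") %||% "cell")
    return(list(meth_pct = NA_real_, n_observed = 0L,
                n_sites = nrow(sites), statistic = statistic))
  }
  pct <- 100 * cell$meth[obs] / (cell$meth[obs] + cell$unmeth[obs])
  value <- if (statistic == "per-cpg") mean(pct) else 100 * mean(pct > 50)
  list(meth_pct = value, n_observed = length(obs),
       n_sites = nrow(sites), statistic = statistic)
}
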