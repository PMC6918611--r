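#' Call methylated and unmethylated domains from a reference track
#'
#' Runs of adjacent 10-kb windows that are all above `domain_hi_pct` (strictly
#' `> 70`\%) merge into methylated domains; runs all below `domain_lo_pct`
#' (strictly `< 30`\%) merge into unmethylated domains. Merged intervals
#' shorter than `domain_min_kb` (50 kb) are discarded. Windows with missing
#' values, intermediate values or a coordinate gap break adjacency: unobserved
#' territory is never bridged.
#'
#' @param track window methylation tibble built with [quantify()] on fixed
#'   tiles of width `cfg$domain_tile_kb` from a reference (bulk oocyte or
#'   sperm) methylome.
#' @param cfg a [default_config()] list.
#' @return a `domain_set` tibble: `chrom`, `start`, `end`,
#'   `state` (`"methylated"` / `"unmethylated"`), `source` (the track's
#'   sample id).
#' @export
call_domains <- function(track, cfg = default_config()) {
  w <- cfg$domain_tile_kb * 1000
  widths <- track$end - track$start
  # every non-terminal tile must have the configured width
  full <- widths == w
  if (!all(full | widths < w))
    stop_mi("track is not on %d-kb tiles", cfg$domain_tile_kb)
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (idx in by_chrom) {
    if (any(widths[idx][-length(idx)] != w))
      stop_mi("track is not on %d-kb tiles", cfg$domain_tile_kb)
  }
  d <- arrange(as_tibble(track), .data$chrom, .data$start)
  state <- ifelse(is.na(d$meth_pct), NA_character_,
                  ifelse(d$meth_pct > cfg$domain_hi_pct, "methylated",
                         ifelse(d$meth_pct < cfg$domain_lo_pct,
                                "unmethylated", NA_character_)))
  d$state <- state
  new_run <- d$chrom != dplyr::lag(d$chrom, default = "") |
    d$start != dplyr::lag(d$end, default = -1L) |
    !vapply(seq_len(nrow(d)), function(i) {
      i > 1 && identical(state[i], state[i - 1]) && !is.na(state[i])
    }, logical(1))
  d$run <- cumsum(new_run)
  d <- filter(d, !is.na(.data$state))
  if (nrow(d) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  state = character())
    attr(out, "source") <- track$sample_id[1] %||% "track"
    class(out) <- c("domain_set", class(tibble()))
    return(out)
  }
  runs <- summarise(group_by(d, .data$run),
                    chrom = .data$chrom[1], start = min(.data$start),
                    end = max(.data$end), state = .data$state[1],
                    .groups = "drop")
  runs <- filter(runs, .data$end - .data$start >= cfg$domain_min_kb * 1000)
  out <- arrange(runs[, c("chrom", "start", "end", "state")],
                 .data$chrom, .data$start)
  attr(out, "source") <- track$sample_id[1] %||% "track"
  class(out) <- c("domain_set", class(tibble()))
  out
}

#' Parental-unique methylated domains
#'
#' Filters each parent's methylated domains for those uniquely methylated in
#' that germline: under the default `"zero-overlap"` rule a domain is unique
#' iff it shares no base pair with any methylated domain of the other parent
#' (the strictest reading); `"majority"` instead drops a domain only when
#' more than half of it is covered by the other parent's methylated domains.
#'
#' @param maternal,paternal `domain_set` tibbles from [call_domains()] on the
#'   oocyte and sperm reference tracks.
#' @param unique_mode `"zero-overlap"` (default) or `"majority"`.
#' @return list with `maternal_only` and `paternal_only` domain sets
#'   (methylated domains only).
#' @export
parental_unique <- function(maternal, paternal,
                            unique_mode = c("zero-overlap", "majority")) {
  unique_mode <- match.arg(unique_mode)
  mat <- filter(as_tibble(maternal), .data$state == "methylated")
  pat <- filter(as_tibble(paternal), .data$state == "methylated")
  keep_unique <- function(a, b) {
    if (nrow(a) == 0) return(a)
    if (nrow(b) == 0) return(a)
    lv <- chrom_universe(a, b)
    gr_a <- gr_intervals(a, lv)
    gr_b <- gr_intervals(b, lv)
    if (unique_mode == "zero-overlap") {
      ov <- GenomicRanges::countOverlaps(gr_a, gr_b, minoverlap = 1L)
      a[ov == 0, , drop = FALSE]
    } else {
      cov <- rep(0, nrow(a))
      hits <- GenomicRanges::findOverlaps(gr_a, gr_b)
      if (length(hits)) {
        inter <- IRanges::pintersect(gr_a[S4Vectors::queryHits(hits)],
                                     gr_b[S4Vectors::subjectHits(hits)])
        ovw <- tapply(BiocGenerics::width(inter), S4Vectors::queryHits(hits), sum)
        cov[as.integer(names(ovw))] <- ovw
      }
      a[cov <= (a$end - a$start) / 2, , drop = FALSE]
    }
  }
  list(maternal_only = keep_unique(mat, pat),
       paternal_only = keep_unique(pat, mat))
}

#' Convert a domain set to a feature table
#'
#' @param domains a `domain_set` tibble (typically one parent's unique
#'   methylated domains).
#' @param category feature category to assign, e.g. `"other"`; the maintenance
#'   workflow labels classes separately.
#' @param prefix name prefix for the generated feature names.
#' @return a [feature_table()].
#' @export
domains_as_features <- function(domains, category = "other",
                                prefix = "domain") {
  feature_table(tibble(chrom = domains$chrom, start = domains$start,
                       end = domains$end,
                       name = paste0(prefix, "_", seq_len(nrow(domains))),
                       category = category))
}
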