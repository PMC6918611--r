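#' @importFrom rlang .data
#' @importFrom dplyr arrange group_by summarise mutate filter select left_join
#'   inner_join bind_rows ungroup n distinct rename across all_of
#' @importFrom tibble tibble as_tibble
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mi <- function(...) stop(sprintf(...), call. = FALSE)
warn_mi <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf,
                                 lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_mi("'%s' must be a single number", name)
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop_mi("'%s' = %s is out of range %s%s, %s%s", name, format(x),
            if (lo_open) "(" else "[", format(lo), format(hi),
            if (hi_open) ")" else "]")
  invisible(x)
}

# "chr" prefix is the internal chromosome naming convention
normalise_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  miss <- !startsWith(chrom, "chr")
  chrom[miss] <- paste0("chr", chrom[miss])
  chrom
}

# 0-based half-open intervals -> GRanges (1-based closed); an explicit
# seqlevel universe avoids spurious seqlevel warnings when two objects
# cover different chromosome subsets
gr_intervals <- function(df, levels = NULL) {
  levels <- levels %||% sort(unique(df$chrom))
  GenomicRanges::GRanges(factor(df$chrom, levels = levels),
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# 1-based CpG positions -> width-1 GRanges
gr_positions <- function(df, levels = NULL) {
  levels <- levels %||% sort(unique(df$chrom))
  GenomicRanges::GRanges(factor(df$chrom, levels = levels),
                         IRanges::IRanges(start = df$pos, width = 1L))
}

chrom_universe <- function(...) {
  sort(unique(unlist(lapply(list(...), function(d) unique(d$chrom)))))
}

# run `expr` under a derived RNG seed without disturbing the caller's RNG state
with_derived_seed <- function(seed, offset, expr) {
  s <- (as.numeric(seed) + as.numeric(offset)) %% 2147483647
  withr::with_seed(as.integer(s), expr)
}
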