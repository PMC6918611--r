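#' Per-CpG methylation call table
#'
#' The core container for bisulphite methylation calls: one row per CpG with
#' methylated and unmethylated read counts. Positions are 1-based positions of
#' the C of the CpG dyad on the plus strand (the convention of
#' Bismark-coverage files); all interval containers in the package are
#' 0-based half-open, and the overlap machinery converts between the two.
#'
#' @param df data frame with columns `chrom`, `pos`, `meth`, `unmeth`.
#' @param library_id identifier of the library the calls come from.
#' @return a `cpg_calls` tibble sorted by chromosome and position, with the
#'   library id stored as attribute `"library_id"`.
#' @export
cpg_calls <- function(df, library_id = "library") {
  df <- as_tibble(df)[, c("chrom", "pos", "meth", "unmeth")]
  df$chrom <- normalise_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  df$meth <- as.integer(df$meth)
  df$unmeth <- as.integer(df$unmeth)
  if (any(df$meth < 0 | df$unmeth < 0, na.rm = TRUE))
    stop_mi("negative counts in CpG call table")
  if (anyNA(df$pos) || anyNA(df$meth) || anyNA(df$unmeth))
    stop_mi("NA values in CpG call table")
  if (any(df$meth + df$unmeth < 1))
    stop_mi("records with meth + unmeth = 0 are not storable; drop them on read")
  df <- arrange(df, .data$chrom, .data$pos)
  if (anyDuplicated(df[, c("chrom", "pos")]))
    stop_mi("duplicate (chrom, pos) records in CpG call table")
  attr(df, "library_id") <- library_id
  class(df) <- c("cpg_calls", class(tibble()))
  df
}

#' Read CpG methylation calls
#'
#' Auto-detects the dialect by column count: 4 columns are the internal
#' `(chrom, pos, meth, unmeth)` layout; 5 or 6 columns are Bismark-coverage
#' style `(chrom, pos[, end], pct, meth, unmeth)` whose percentage column is
#' ignored and recomputed from the counts. Records with zero total coverage
#' are dropped with a warning. Chromosome names get the internal `chr` prefix.
#'
#' @param path tab-separated input file.
#' @param library_id library identifier, default the file name.
#' @return a [cpg_calls()] table.
#' @export
read_cpg_calls <- function(path, library_id = basename(path)) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0)
    return(cpg_calls(tibble(chrom = character(), pos = integer(),
                            meth = integer(), unmeth = integer()), library_id))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1)
    stop_mi("parse error at line %d: expected %d tab-separated fields, found %d",
            which(ncols != ncols[1])[1], ncols[1],
            ncols[which(ncols != ncols[1])[1]])
  nc <- ncols[1]
  m <- do.call(rbind, parts)
  pick <- switch(as.character(nc),
    "4" = c(pos = 2, meth = 3, unmeth = 4),
    "5" = c(pos = 2, meth = 4, unmeth = 5),   # chrom pos pct meth unmeth
    "6" = c(pos = 2, meth = 5, unmeth = 6),   # chrom start end pct meth unmeth
    stop_mi("unrecognised CpG call dialect: %d columns", nc))
  num <- suppressWarnings(
    cbind(pos = as.numeric(m[, pick["pos"]]),
          meth = as.numeric(m[, pick["meth"]]),
          unmeth = as.numeric(m[, pick["unmeth"]])))
  bad <- which(!stats::complete.cases(num))
  if (length(bad))
    stop_mi("parse error at line %d: non-numeric field in '%s'",
            bad[1], raw[bad[1]])
  zero <- num[, "meth"] + num[, "unmeth"] == 0
  if (any(zero)) {
    warn_mi("%d record(s) with zero coverage dropped on read", sum(zero))
    m <- m[!zero, , drop = FALSE]; num <- num[!zero, , drop = FALSE]
  }
  cpg_calls(tibble(chrom = m[, 1], pos = num[, "pos"],
                   meth = num[, "meth"], unmeth = num[, "unmeth"]),
            library_id = library_id)
}

#' Write CpG methylation calls
#'
#' @param calls a [cpg_calls()] table.
#' @param path output path.
#' @param dialect `"internal"` writes 4 columns `(chrom, pos, meth, unmeth)`;
#'   `"coverage"` writes the 5-column Bismark-coverage-style layout with the
#'   percentage recomputed from the counts.
#' @return `path`, invisibly.
#' @export
write_cpg_calls <- function(calls, path, dialect = c("internal", "coverage")) {
  dialect <- match.arg(dialect)
  out <- if (dialect == "internal") {
    calls[, c("chrom", "pos", "meth", "unmeth")]
  } else {
    tibble(chrom = calls$chrom, pos = calls$pos,
           pct = format(100 * calls$meth / (calls$meth + calls$unmeth)),
           meth = calls$meth, unmeth = calls$unmeth)
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

feature_categories <- c("gene", "promoter", "exon", "intron", "intergenic",
                        "CGI", "maternal_gDMR", "paternal_gDMR",
                        "placenta_gDMR", "secondary_DMR", "other")

#' Genomic feature table
#'
#' Named, categorised intervals (genes, CGIs, imprinted gDMRs, ...) stored
#' 0-based half-open as in BED.
#'
#' @param df data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `category`, `strand`.
#' @return a `feature_table` tibble.
#' @export
feature_table <- function(df) {
  df <- as_tibble(df)
  df$chrom <- normalise_chrom(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (is.null(df[["name"]])) df$name <- paste0("feature_", seq_len(nrow(df)))
  if (is.null(df[["category"]])) df$category <- "other"
  if (is.null(df[["strand"]])) df$strand <- "."
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop_mi("feature %s has start >= end (%d >= %d)",
            df$name[bad[1]], df$start[bad[1]], df$end[bad[1]])
  if (any(df$start < 0)) stop_mi("negative feature start")
  unknown <- setdiff(unique(df$category), feature_categories)
  if (length(unknown))
    stop_mi("unknown feature category: %s", paste(unknown, collapse = ", "))
  if (!all(df$strand %in% c("+", "-", ".")))
    stop_mi("strand must be one of '+', '-', '.'")
  df <- df[, c("chrom", "start", "end", "name", "category", "strand")]
  class(df) <- c("feature_table", class(tibble()))
  df
}

#' Read a BED file of genomic features
#'
#' BED3+ input, 0-based half-open coordinates kept as such. Column 4 is the
#' name, column 5 (when present) the feature category from the package's
#' closed vocabulary, column 6 the strand.
#'
#' @param path BED file.
#' @return a [feature_table()].
#' @export
read_features <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw) & !startsWith(raw, "track") & !startsWith(raw, "#")]
  if (length(raw) == 0)
    return(feature_table(tibble(chrom = character(), start = integer(),
                                end = integer())))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nc <- min(lengths(parts))
  if (nc < 3) stop_mi("BED input needs at least 3 columns")
  g <- function(i) vapply(parts, function(p) p[i], character(1))
  df <- tibble(chrom = g(1),
               start = as.integer(g(2)),
               end = as.integer(g(3)))
  if (nc >= 4) df$name <- g(4)
  if (nc >= 5) df$category <- g(5)
  if (nc >= 6) df$strand <- g(6)
  feature_table(df)
}

#' Write features as BED
#'
#' @param features a [feature_table()].
#' @param path output path; columns are chrom, start, end, name, category,
#'   strand (BED6 with the category in the score slot).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features[, c("chrom", "start", "end", "name",
                                "category", "strand")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Methylation-array beta-value table
#'
#' One row per probe with its genomic position and a beta value in `[0, 1]`
#' per sample (samples are columns after `probe_id`, `chrom`, `pos`). Missing
#' betas are allowed and are excluded from downstream averages.
#'
#' @param df data frame with `probe_id`, `chrom`, `pos` and >= 1 sample column.
#' @return a `beta_table` tibble.
#' @export
beta_table <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(df)))
  df$chrom <- normalise_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  samples <- setdiff(names(df), c("probe_id", "chrom", "pos"))
  if (length(samples) == 0) stop_mi("beta table has no sample columns")
  for (s in samples) {
    v <- df[[s]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop_mi("beta value outside [0, 1] in sample '%s'", s)
  }
  if (anyDuplicated(df[, c("chrom", "pos")]))
    stop_mi("duplicate probe positions per chromosome")
  df <- arrange(df, .data$chrom, .data$pos)
  attr(df, "samples") <- samples
  class(df) <- c("beta_table", class(tibble()))
  df
}

#' Read a tab-separated beta-value table
#'
#' Expects a header row `probe_id chrom pos <sample...>`.
#'
#' @param path input path.
#' @return a [beta_table()].
#' @export
read_beta_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  beta_table(df)
}

#' Write a beta-value table
#'
#' @param betas a [beta_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beta_table <- function(betas, path) {
  readr::write_tsv(as_tibble(betas), path, progress = FALSE)
  invisible(path)
}

#' Genome reference
#'
#' A light wrapper around a [Biostrings::DNAStringSet] giving chromosome
#' lengths and an uppercase sequence accessor in the package's 0-based
#' half-open convention.
#'
#' @param seqs a named `DNAStringSet` (or named character vector of sequences).
#' @return a `genome_ref` object.
#' @export
genome_ref <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_mi("genome sequences must be named by chromosome")
  names(seqs) <- normalise_chrom(names(seqs))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  if (any(lens <= 0)) stop_mi("chromosome lengths must be positive")
  structure(list(seqs = seqs, lengths = lens), class = "genome_ref")
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [genome_ref()].
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  genome_ref(seqs)
}

#' Write a genome FASTA
#'
#' @param genome a [genome_ref()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' Extract an interval of genome sequence
#'
#' @param genome a [genome_ref()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return uppercase character string of length `end - start`.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  chrom <- normalise_chrom(chrom)
  if (!chrom %in% names(genome$lengths))
    stop_mi("chromosome '%s' not in genome", chrom)
  if (start < 0 || end > genome$lengths[[chrom]] || start >= end)
    stop_mi("interval [%d, %d) out of bounds for %s (length %d)",
            start, end, chrom, genome$lengths[[chrom]])
  toupper(as.character(Biostrings::subseq(genome$seqs[[chrom]],
                                          start + 1L, end)))
}

#' Genome-wide CpG positions
#'
#' Scans a genome for CpG dinucleotides and returns the 1-based position of
#' the C on the plus strand for each dyad.
#'
#' @param genome a [genome_ref()].
#' @return tibble with `chrom` and `pos`.
#' @export
cpg_positions <- function(genome) {
  out <- lapply(names(genome$seqs), function(ch) {
    hits <- Biostrings::matchPattern("CG", genome$seqs[[ch]])
    tibble(chrom = ch, pos = BiocGenerics::start(hits))
  })
  bind_rows(out)
}

#' Collapse minus-strand CpG calls onto the plus-strand C
#'
#' CpG methylation is symmetric across the dyad and single-cell libraries are
#' too sparse for strand resolution, so calls reported at the G of a CpG
#' (minus-strand C) are mapped to the plus-strand C at `pos - 1` and the
#' counts summed with any plus-strand record.
#'
#' @param calls a [cpg_calls()] table, positions on either strand.
#' @param genome a [genome_ref()] used to recognise which positions are the G
#'   of a CpG dyad.
#' @return a [cpg_calls()] table with all positions on the plus-strand C.
#' @export
collapse_strands <- function(calls, genome) {
  cpgs <- cpg_positions(genome)
  key_c <- paste(cpgs$chrom, cpgs$pos)
  key_g <- paste(cpgs$chrom, cpgs$pos + 1L)
  k <- paste(calls$chrom, calls$pos)
  is_g <- k %in% key_g & !(k %in% key_c)
  pos2 <- ifelse(is_g, calls$pos - 1L, calls$pos)
  merged <- tibble(chrom = calls$chrom, pos = as.integer(pos2),
                   meth = calls$meth, unmeth = calls$unmeth)
  merged <- summarise(group_by(merged, .data$chrom, .data$pos),
                      meth = sum(.data$meth), unmeth = sum(.data$unmeth),
                      .groups = "drop")
  cpg_calls(merged, library_id = attr(calls, "library_id"))
}
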