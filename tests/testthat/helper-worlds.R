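# Shared simulated fixtures, built once per test run.

.world_cache <- new.env(parent = emptyenv())

get_world <- function(preset = "tiny", seed = 11, ...) {
  key <- paste(preset, seed, ...)
  if (is.null(.world_cache[[key]])) {
    sim <- sim_config(preset, seed = seed, ...)
    toy <- build_toy_genome(sim)
    true <- simulate_oocyte(sim, toy$genome, toy$features)
    .world_cache[[key]] <- list(sim = sim, genome = toy$genome,
                                features = toy$features, true = true)
  }
  .world_cache[[key]]
}

# random small call tables for round-trip and oracle tests
random_calls <- function(n = 50, chroms = c("chr1", "chr2"), max_pos = 1e4) {
  pos_by_chrom <- lapply(chroms, function(ch) {
    k <- sample(0:n, 1)
    sort(sample(seq_len(max_pos), k))
  })
  df <- dplyr::bind_rows(lapply(seq_along(chroms), function(i) {
    k <- length(pos_by_chrom[[i]])
    tibble::tibble(chrom = chroms[i], pos = pos_by_chrom[[i]],
                   meth = sample(0:5, k, replace = TRUE),
                   unmeth = sample(0:5, k, replace = TRUE))
  }))
  df <- df[df$meth + df$unmeth >= 1, ]
  cpg_calls(df, library_id = "rand")
}

# brute-force per-base-then-average window quantification
oracle_quantify <- function(calls, windows, min_sites) {
  pct <- 100 * calls$meth / (calls$meth + calls$unmeth)
  out <- windows
  out$meth_pct <- NA_real_
  out$n_sites <- 0L
  for (i in seq_len(nrow(windows))) {
    inside <- which(calls$chrom == windows$chrom[i] &
                    calls$pos - 1 >= windows$start[i] &
                    calls$pos - 1 < windows$end[i])
    out$n_sites[i] <- length(inside)
    if (length(inside) >= min_sites) out$meth_pct[i] <- mean(pct[inside])
  }
  out
}

# brute-force interval overlap counter (0-based half-open, >= 1 bp shared)
oracle_overlap_counts <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sum(b$chrom == a$chrom[i] &
        pmax(b$start, a$start[i]) < pmin(b$end, a$end[i]))
  }, integer(1))
}

# brute-force run merger over a single chromosome of adjacent fixed tiles
oracle_domains <- function(values, width, hi = 70, lo = 30, min_len = 50000) {
  state <- ifelse(is.na(values), NA,
                  ifelse(values > hi, "methylated",
                         ifelse(values < lo, "unmethylated", NA)))
  runs <- list(); cur <- NULL
  for (i in seq_along(state)) {
    if (is.na(state[i])) {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- NULL
      next
    }
    if (!is.null(cur) && cur$state == state[i]) {
      cur$end <- i
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- list(state = state[i], start = i, end = i)
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  out <- dplyr::bind_rows(lapply(runs, function(r) {
    tibble::tibble(start = (r$start - 1) * width, end = r$end * width,
                   state = r$state)
  }))
  if (nrow(out) == 0) return(out)
  out[out$end - out$start >= min_len, ]
}

# brute-force motif scan: position-by-position comparison on both strands,
# returning the deduplicated plus-strand CpG positions (1-based C)
oracle_motif_cpgs <- function(seq, offset0, motifs) {
  revcomp <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  n <- nchar(seq)
  found <- integer()
  for (motif in motifs) {
    w <- nchar(motif)
    cpg_off <- as.integer(regexpr("CG", motif))
    for (s in seq_len(n - w + 1)) {
      sub <- substr(seq, s, s + w - 1)
      if (sub == motif)
        found <- c(found, offset0 + s - 1 + cpg_off)
      if (sub == revcomp(motif))
        found <- c(found, offset0 + s - 1 + w - cpg_off)
    }
  }
  sort(unique(found))
}
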