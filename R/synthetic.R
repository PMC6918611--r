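#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: an oocyte methylome
#' with hypermethylated domains over transcribed gene bodies and
#' hypomethylated intergenic territory, allele-specific gDMR methylation, a
#' genome-wide multiplicative methylation loss in mutant oocytes, sparse
#' per-cell CpG capture, an embryo that retains maternal-allele methylation
#' with tunable efficiency, and a mole/placenta array profile in which the
#' non-imprinted genome remethylates while gDMRs inherit the oocyte deficit.
#'
#' Defaults: gene-body CpGs are methylated at probability 0.85 and intergenic
#' CpGs at 0.10; maternal gDMR CpGs at 0.85 in the oocyte; the mutant oocyte
#' retains a per-region fraction with mean `loss_factor = 0.55` of the
#' control probability (matching the roughly 0.55-0.6 global retention seen
#' in affected oocytes); each cell captures 13\% of CpGs (within the
#' 11-15\% per-cell coverage of saturating scBS-seq libraries);
#' `maintenance_efficiency = 1` is perfect maternal-allele maintenance.
#'
#' @param preset `"study"` (default, two 1-Mb chromosomes) or `"tiny"` (one
#'   0.5-Mb chromosome for quick runs).
#' @param seed mandatory integer seed; every generator draw derives from it.
#' @param n_chroms,chrom_len_bp chromosome count and length (>= 100 kb).
#' @param cpg_spacing_mean mean background CpG spacing in bp.
#' @param cgi_spacing_mean CpG spacing inside CpG-dense features (CGIs,
#'   gDMRs).
#' @param n_genes,gene_len_bp transcribed gene bodies (hypermethylated
#'   domains); lengths should be multiples of 10 kb so domain tiles align.
#' @param n_cgis,cgi_len_bp CpG islands; about half are placed inside gene
#'   bodies (oocyte-methylated), the rest intergenic (unmethylated).
#' @param n_maternal_gdmrs,n_paternal_gdmrs,n_placenta_gdmrs,gdmr_len_bp
#'   imprinted gDMRs; maternal gDMRs sit inside gene bodies, paternal and
#'   placenta-specific gDMRs in intergenic territory.
#' @param p_hyper,p_hypo per-CpG methylation probabilities inside/outside
#'   transcribed gene bodies.
#' @param gdmr_maternal_oocyte_p oocyte methylation probability at maternal
#'   (and placenta-specific) gDMR CpGs.
#' @param sperm_global_p,sperm_paternal_gdmr_p sperm track: high globally,
#'   low at CGIs and maternal gDMRs, high at paternal gDMRs.
#' @param loss_factor mean multiplicative methylation retention in mutant
#'   oocytes, in `[0, 1]`.
#' @param loss_dispersion standard deviation of the per-region Beta-
#'   distributed retention; 0 makes every region retain exactly
#'   `loss_factor`.
#' @param cell_capture_frac fraction of CpGs observed per single cell.
#' @param maintenance_efficiency maternal-allele retention in the embryo,
#'   `[0, 1]`.
#' @param paternal_retention global demethylation scaling of the sperm track
#'   on the embryo's paternal allele.
#' @param embryo_depth simulated read depth per CpG in the embryo library.
#' @param remeth_level post-implantation remethylation level of the
#'   non-imprinted genome in placenta/mole (beta scale).
#' @param beta_noise_sd Gaussian noise s.d. on simulated betas (truncated to
#'   `[0, 1]`).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(preset = c("study", "tiny"), seed,
                       n_chroms = NULL, chrom_len_bp = NULL,
                       cpg_spacing_mean = 150, cgi_spacing_mean = 15,
                       n_genes = NULL, gene_len_bp = 80000,
                       n_cgis = NULL, cgi_len_bp = 1500,
                       n_maternal_gdmrs = NULL, n_paternal_gdmrs = NULL,
                       n_placenta_gdmrs = NULL, gdmr_len_bp = 3000,
                       p_hyper = 0.85, p_hypo = 0.10,
                       gdmr_maternal_oocyte_p = 0.85,
                       sperm_global_p = 0.85, sperm_paternal_gdmr_p = 0.90,
                       loss_factor = 0.55, loss_dispersion = 0.1,
                       cell_capture_frac = 0.13,
                       maintenance_efficiency = 1.0,
                       paternal_retention = 0.25, embryo_depth = 20,
                       remeth_level = 0.5, beta_noise_sd = 0.03) {
  preset <- match.arg(preset)
  if (missing(seed)) stop_mi("'seed' is mandatory")
  base <- if (preset == "study") {
    list(n_chroms = 2, chrom_len_bp = 1e6, n_genes = 10, n_cgis = 20,
         n_maternal_gdmrs = 6, n_paternal_gdmrs = 2, n_placenta_gdmrs = 2)
  } else {
    list(n_chroms = 1, chrom_len_bp = 5e5, n_genes = 3, n_cgis = 6,
         n_maternal_gdmrs = 3, n_paternal_gdmrs = 1, n_placenta_gdmrs = 1)
  }
  sim <- list(
    n_chroms = n_chroms %||% base$n_chroms,
    chrom_len_bp = chrom_len_bp %||% base$chrom_len_bp,
    cpg_spacing_mean = cpg_spacing_mean, cgi_spacing_mean = cgi_spacing_mean,
    n_genes = n_genes %||% base$n_genes, gene_len_bp = gene_len_bp,
    n_cgis = n_cgis %||% base$n_cgis, cgi_len_bp = cgi_len_bp,
    n_maternal_gdmrs = n_maternal_gdmrs %||% base$n_maternal_gdmrs,
    n_paternal_gdmrs = n_paternal_gdmrs %||% base$n_paternal_gdmrs,
    n_placenta_gdmrs = n_placenta_gdmrs %||% base$n_placenta_gdmrs,
    gdmr_len_bp = gdmr_len_bp,
    p_hyper = p_hyper, p_hypo = p_hypo,
    gdmr_maternal_oocyte_p = gdmr_maternal_oocyte_p,
    sperm_global_p = sperm_global_p,
    sperm_paternal_gdmr_p = sperm_paternal_gdmr_p,
    loss_factor = loss_factor, loss_dispersion = loss_dispersion,
    cell_capture_frac = cell_capture_frac,
    maintenance_efficiency = maintenance_efficiency,
    paternal_retention = paternal_retention, embryo_depth = embryo_depth,
    remeth_level = remeth_level, beta_noise_sd = beta_noise_sd,
    seed = as.integer(seed))
  for (f in c("p_hyper", "p_hypo", "gdmr_maternal_oocyte_p", "sperm_global_p",
              "sperm_paternal_gdmr_p", "loss_factor", "maintenance_efficiency",
              "paternal_retention", "remeth_level"))
    assert_scalar_number(sim[[f]], f, 0, 1)
  assert_scalar_number(sim$cell_capture_frac, "cell_capture_frac", 0, 1,
                       lo_open = TRUE)
  assert_scalar_number(sim$loss_dispersion, "loss_dispersion", 0, 0.5)
  assert_scalar_number(sim$chrom_len_bp, "chrom_len_bp", 1e5, Inf)
  assert_scalar_number(sim$n_maternal_gdmrs, "n_maternal_gdmrs", 1, Inf)
  assert_scalar_number(sim$embryo_depth, "embryo_depth", 2, Inf)
  class(sim) <- "sim_config"
  sim
}

# deterministic layout of genes, CGIs and gDMRs on a 10-kb grid
toy_layout <- function(sim) {
  grid <- 10000L
  per_chrom <- tabulate(((seq_len(sim$n_genes) - 1) %% sim$n_chroms) + 1,
                        nbins = sim$n_chroms)
  genes <- list(); gaps <- list()
  gi <- 0L
  for (c in seq_len(sim$n_chroms)) {
    ng <- per_chrom[c]
    gap <- floor((sim$chrom_len_bp - ng * sim$gene_len_bp) / (ng + 1))
    gap <- (gap %/% grid) * grid
    if (gap < 6 * grid)
      stop_mi(paste("features cannot be placed without overlap;",
                    "use longer chromosomes or fewer/shorter genes"))
    ch <- paste0("chr", c)
    prev_end <- 0L
    for (j in seq_len(ng)) {
      gi <- gi + 1L
      gs <- j * gap + (j - 1) * sim$gene_len_bp
      genes[[gi]] <- tibble(chrom = ch, start = gs,
                            end = gs + sim$gene_len_bp,
                            name = paste0("gene_", gi), category = "gene")
      gaps[[length(gaps) + 1]] <- tibble(chrom = ch, start = prev_end,
                                         end = gs)
      prev_end <- gs + sim$gene_len_bp
    }
    gaps[[length(gaps) + 1]] <- tibble(chrom = ch, start = prev_end,
                                       end = sim$chrom_len_bp)
  }
  genes <- bind_rows(genes)
  gaps <- bind_rows(gaps)
  n_genic_cgi <- min(sim$n_genes, ceiling(sim$n_cgis / 2))
  n_inter_cgi <- sim$n_cgis - n_genic_cgi
  if (n_inter_cgi > nrow(gaps) || sim$n_paternal_gdmrs > nrow(gaps) ||
      sim$n_placenta_gdmrs > nrow(gaps))
    stop_mi("too many intergenic features for %d gaps; use longer chromosomes",
            nrow(gaps))
  if (sim$n_maternal_gdmrs > sim$n_genes)
    stop_mi("n_maternal_gdmrs must not exceed n_genes (one per gene body)")
  feats <- list(genes)
  # genic CGIs near the gene start, maternal gDMRs mid-gene
  if (n_genic_cgi > 0)
    feats[[length(feats) + 1]] <- tibble(
      chrom = genes$chrom[1:n_genic_cgi],
      start = genes$start[1:n_genic_cgi] + 2000L,
      end = genes$start[1:n_genic_cgi] + 2000L + sim$cgi_len_bp,
      name = paste0("CGI_genic_", seq_len(n_genic_cgi)), category = "CGI")
  mid <- (sim$gene_len_bp %/% 2)
  feats[[length(feats) + 1]] <- tibble(
    chrom = genes$chrom[1:sim$n_maternal_gdmrs],
    start = genes$start[1:sim$n_maternal_gdmrs] + mid,
    end = genes$start[1:sim$n_maternal_gdmrs] + mid + sim$gdmr_len_bp,
    name = paste0("matDMR_", seq_len(sim$n_maternal_gdmrs)),
    category = "maternal_gDMR")
  # intergenic elements at 1/4, 1/2 and 3/4 of successive gaps
  place_in_gaps <- function(n, frac, len, prefix, category) {
    if (n == 0) return(NULL)
    g <- gaps[seq_len(n), ]
    start <- g$start + floor((g$end - g$start) * frac)
    tibble(chrom = g$chrom, start = start, end = start + len,
           name = paste0(prefix, seq_len(n)), category = category)
  }
  feats[[length(feats) + 1]] <- place_in_gaps(n_inter_cgi, 0.25,
    sim$cgi_len_bp, "CGI_inter_", "CGI")
  feats[[length(feats) + 1]] <- place_in_gaps(sim$n_paternal_gdmrs, 0.5,
    sim$gdmr_len_bp, "patDMR_", "paternal_gDMR")
  feats[[length(feats) + 1]] <- place_in_gaps(sim$n_placenta_gdmrs, 0.75,
    sim$gdmr_len_bp, "placDMR_", "placenta_gDMR")
  list(features = feature_table(bind_rows(feats)), gaps = gaps)
}

#' Build a toy genome with planted methylation features
#'
#' Generates `n_chroms` chromosomes of random sequence in which every CpG
#' dinucleotide is placed deliberately: background CpGs at roughly
#' `cpg_spacing_mean` bp, dense CpGs (every `cgi_spacing_mean` bp) inside
#' CGIs and gDMRs, and three ZFP57 hexamer occurrences planted inside each
#' maternal gDMR. Genes, CGIs and gDMRs never overlap, and gene boundaries
#' sit on the 10-kb domain-tile grid. Deterministic given the seed.
#'
#' @param sim a [sim_config()].
#' @return list with `genome` (a [genome_ref()]) and `features` (a
#'   [feature_table()] of genes, CGIs and gDMRs).
#' @export
build_toy_genome <- function(sim) {
  layout <- toy_layout(sim)
  feats <- layout$features
  with_derived_seed(sim$seed, 101, {
    seqs <- character(sim$n_chroms)
    for (c in seq_len(sim$n_chroms)) {
      ch <- paste0("chr", c)
      len <- as.integer(sim$chrom_len_bp)
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
      # remove accidental CpGs so the dyad placement below is exhaustive
      acc <- which(s[-len] == "C" & s[-1] == "G")
      if (length(acc)) s[acc + 1] <- "T"
      # background CpG positions (0-based C), min gap 8 bp
      mean_gap <- max(sim$cpg_spacing_mean, 20)
      n_draw <- ceiling(len / mean_gap * 1.5)
      gaps <- 10 + stats::rgeom(n_draw, 1 / (mean_gap - 10))
      pos <- cumsum(gaps) + 200L
      pos <- pos[pos < len - 200]
      # dense CpGs inside CpG-dense features on this chromosome
      dense_feats <- filter(as_tibble(feats), .data$chrom == ch,
                            .data$category %in% c("CGI", "maternal_gDMR",
                                                  "paternal_gDMR",
                                                  "placenta_gDMR"))
      for (i in seq_len(nrow(dense_feats)))
        pos <- c(pos, seq(dense_feats$start[i] + 20,
                          dense_feats$end[i] - 20,
                          by = sim$cgi_spacing_mean))
      pos <- sort(unique(as.integer(pos)))
      keep <- c(TRUE, diff(pos) >= 8)
      pos <- pos[keep]
      s[pos + 1] <- "C"; s[pos + 2] <- "G"
      # plant ZFP57 motifs inside maternal gDMRs (3 per gDMR)
      mats <- filter(as_tibble(feats), .data$chrom == ch,
                     .data$category == "maternal_gDMR")
      for (i in seq_len(nrow(mats))) {
        offs <- floor((sim$gdmr_len_bp) * c(0.2, 0.5, 0.8))
        motifs <- sample(c("TGCCGC", "GGCCGC"), 3, replace = TRUE)
        for (j in 1:3) {
          at <- mats$start[i] + offs[j] # 0-based motif start
          s[(at + 1):(at + 6)] <- strsplit(motifs[j], "")[[1]]
        }
      }
      seqs[c] <- paste(s, collapse = "")
    }
    names(seqs) <- paste0("chr", seq_len(sim$n_chroms))
    list(genome = genome_ref(seqs), features = feats)
  })
}

#' Simulate the germline methylomes
#'
#' Assigns per-CpG methylation probabilities for the control oocyte (gene
#' bodies at `p_hyper`, elsewhere `p_hypo`, maternal and placenta-specific
#' gDMRs at `gdmr_maternal_oocyte_p`), for sperm (high globally, low at CGIs
#' and maternal/placenta gDMRs, high at paternal gDMRs) and for the mutant
#' oocyte (control probability times a per-region retention drawn once per
#' region from a Beta law with mean `loss_factor` and s.d.
#' `loss_dispersion`, then fixed). Regions are the gene bodies, the gDMRs
#' and the intergenic blocks.
#'
#' @param sim a [sim_config()].
#' @param genome a [genome_ref()] from [build_toy_genome()].
#' @param features the matching [feature_table()].
#' @return a `true_methylome` list: `cpg` (tibble with `chrom`, `pos`,
#'   `p_oocyte`, `p_mutant`, `p_sperm`), `regions` (planted per-region
#'   retention truth), `features`, `sim`.
#' @export
simulate_oocyte <- function(sim, genome, features) {
  cpgs <- cpg_positions(genome)
  lv <- sort(unique(c(cpgs$chrom, features$chrom)))
  gr_c <- gr_positions(cpgs, lv)
  in_cat <- function(cats) {
    f <- filter(as_tibble(features), .data$category %in% cats)
    if (nrow(f) == 0) return(rep(FALSE, nrow(cpgs)))
    GenomicRanges::countOverlaps(gr_c, gr_intervals(f, lv)) > 0
  }
  in_gene <- in_cat("gene")
  in_cgi <- in_cat("CGI")
  in_mat <- in_cat(c("maternal_gDMR", "placenta_gDMR"))
  in_pat <- in_cat("paternal_gDMR")
  p_oocyte <- ifelse(in_gene, sim$p_hyper, sim$p_hypo)
  p_oocyte[in_mat] <- sim$gdmr_maternal_oocyte_p
  p_sperm <- rep(sim$sperm_global_p, nrow(cpgs))
  p_sperm[in_cgi | in_mat] <- sim$p_hypo
  p_sperm[in_pat] <- sim$sperm_paternal_gdmr_p
  # mutant oocyte: one retention draw per region, fixed thereafter
  regions <- region_partition(sim, features)
  retention <- with_derived_seed(sim$seed, 202,
    draw_retention(nrow(regions), sim$loss_factor, sim$loss_dispersion))
  regions$retention <- retention
  hits <- GenomicRanges::findOverlaps(gr_c, gr_intervals(regions, lv))
  r_per_cpg <- rep(NA_real_, nrow(cpgs))
  # later rows of the partition (gDMRs) override the gene/intergenic draw
  r_per_cpg[S4Vectors::queryHits(hits)] <-
    regions$retention[S4Vectors::subjectHits(hits)]
  r_per_cpg[is.na(r_per_cpg)] <- sim$loss_factor
  p_mutant <- p_oocyte * r_per_cpg
  structure(list(cpg = tibble(chrom = cpgs$chrom, pos = cpgs$pos,
                              p_oocyte = p_oocyte, p_mutant = p_mutant,
                              p_sperm = p_sperm),
                 regions = regions, features = features, sim = sim),
            class = "true_methylome")
}

# genes, intergenic blocks and gDMRs as a region partition; gDMR rows come
# last so their retention draw wins at overlapping CpGs
region_partition <- function(sim, features) {
  f <- as_tibble(features)
  genes <- filter(f, .data$category == "gene")
  gdmrs <- filter(f, .data$category %in% c("maternal_gDMR", "placenta_gDMR"))
  inter <- list()
  for (c in seq_len(sim$n_chroms)) {
    ch <- paste0("chr", c)
    g <- arrange(filter(genes, .data$chrom == ch), .data$start)
    bounds <- c(0L, rbind(g$start, g$end), sim$chrom_len_bp)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    if (any(keep))
      inter[[ch]] <- tibble(chrom = ch, start = starts[keep],
                            end = ends[keep],
                            name = paste0("intergenic_", ch, "_",
                                          seq_len(sum(keep))),
                            type = "intergenic")
  }
  bind_rows(
    tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
           name = genes$name, type = "gene"),
    bind_rows(inter),
    tibble(chrom = gdmrs$chrom, start = gdmrs$start, end = gdmrs$end,
           name = gdmrs$name, type = "gdmr"))
}

draw_retention <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  v <- min(sd^2, mean * (1 - mean) * 0.95)
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Sample one single-cell library from a true methylome
#'
#' Each CpG is observed independently with probability
#' `cell_capture_frac`; an observed CpG carries a single binary read drawn
#' from its track probability (depth 1, matching scBS-seq). Deterministic per
#' `(seed, track, cell_index)`: the same index reproduces the same cell.
#'
#' @param true a `true_methylome` from [simulate_oocyte()].
#' @param which track: `"control"`, `"mutant"` or `"sperm"`.
#' @param cell_index positive integer distinguishing cells.
#' @return a [cpg_calls()] table with depth-1 records.
#' @export
sample_cell <- function(true, which = c("control", "mutant", "sperm"),
                        cell_index = 1) {
  which <- match.arg(which)
  sim <- true$sim
  p <- switch(which, control = true$cpg$p_oocyte,
              mutant = true$cpg$p_mutant, sperm = true$cpg$p_sperm)
  with_derived_seed(sim$seed,
                    1e6 * match(which, c("control", "mutant", "sperm")) +
                      7919 * cell_index, {
    obs <- stats::runif(length(p)) < sim$cell_capture_frac
    meth <- stats::rbinom(sum(obs), 1L, p[obs])
    cpg_calls(tibble(chrom = true$cpg$chrom[obs], pos = true$cpg$pos[obs],
                     meth = meth, unmeth = 1L - meth),
              library_id = sprintf("%s_cell%02d", which, cell_index))
  })
}

#' Sample a bulk library from a true methylome
#'
#' Binomial counts at a fixed depth per CpG, e.g. for the deep reference
#' oocyte and sperm methylomes that anchor domain calling.
#'
#' @param true a `true_methylome`.
#' @param which track: `"control"`, `"mutant"` or `"sperm"`.
#' @param depth reads per CpG (default 20).
#' @return a [cpg_calls()] table.
#' @export
sample_bulk <- function(true, which = c("control", "mutant", "sperm"),
                        depth = 20) {
  which <- match.arg(which)
  p <- switch(which, control = true$cpg$p_oocyte,
              mutant = true$cpg$p_mutant, sperm = true$cpg$p_sperm)
  with_derived_seed(true$sim$seed,
                    2e6 + 17 * match(which, c("control", "mutant", "sperm")), {
    meth <- stats::rbinom(length(p), depth, p)
    cpg_calls(tibble(chrom = true$cpg$chrom, pos = true$cpg$pos,
                     meth = meth, unmeth = depth - meth),
              library_id = paste0("bulk_", which))
  })
}

#' Expected embryo methylation track
#'
#' The diploid expectation: maternal allele = mutant-oocyte probability times
#' `maintenance_efficiency`; paternal allele = sperm probability times
#' `paternal_retention` (global post-fertilisation demethylation); the
#' embryo's per-CpG probability is the mean of the two alleles.
#'
#' @param true a `true_methylome`.
#' @param maintenance_efficiency,paternal_retention override the sim config.
#' @param maternal_track `"mutant"` (default) or `"control"` oocyte as the
#'   maternal allele.
#' @return tibble with `chrom`, `pos`, `p_maternal`, `p_paternal`,
#'   `p_embryo`.
#' @export
embryo_profile <- function(true,
                           maintenance_efficiency = true$sim$maintenance_efficiency,
                           paternal_retention = true$sim$paternal_retention,
                           maternal_track = c("mutant", "control")) {
  maternal_track <- match.arg(maternal_track)
  pm <- switch(maternal_track, mutant = true$cpg$p_mutant,
               control = true$cpg$p_oocyte) * maintenance_efficiency
  pp <- true$cpg$p_sperm * paternal_retention
  tibble(chrom = true$cpg$chrom, pos = true$cpg$pos,
         p_maternal = pm, p_paternal = pp, p_embryo = (pm + pp) / 2)
}

#' Simulate a whole-embryo bulk bisulphite library
#'
#' Draws per-CpG counts by sampling both alleles at the configured depth
#' (half the reads from each allele), with the maternal allele at
#' mutant-oocyte methylation scaled by `maintenance_efficiency` and the
#' paternal allele at sperm methylation scaled by `paternal_retention`.
#'
#' @param true a `true_methylome`.
#' @param maintenance_efficiency,paternal_retention,depth override the sim
#'   config.
#' @param maternal_track `"mutant"` (default) or `"control"`.
#' @return a [cpg_calls()] table (`library_id = "embryo"`).
#' @export
simulate_embryo <- function(true,
                            maintenance_efficiency = true$sim$maintenance_efficiency,
                            paternal_retention = true$sim$paternal_retention,
                            depth = true$sim$embryo_depth,
                            maternal_track = c("mutant", "control")) {
  maternal_track <- match.arg(maternal_track)
  prof <- embryo_profile(true, maintenance_efficiency, paternal_retention,
                         maternal_track)
  d_m <- depth %/% 2
  d_p <- depth - d_m
  with_derived_seed(true$sim$seed, 3e6, {
    meth <- stats::rbinom(nrow(prof), d_m, prof$p_maternal) +
      stats::rbinom(nrow(prof), d_p, prof$p_paternal)
    cpg_calls(tibble(chrom = prof$chrom, pos = prof$pos, meth = meth,
                     unmeth = depth - meth), library_id = "embryo")
  })
}

#' Simulate mole and control-placenta array betas
#'
#' Control placentas follow a placenta profile: CGIs low (0.10), maternal and
#' placenta-specific gDMRs at 0.5 (one methylated allele), everything else at
#' the post-implantation `remeth_level`. The mole is identical except that
#' gDMR probes carry the oocyte-inherited retention on the methylated allele:
#' beta = 0.5 x retention. Gaussian noise (s.d. `beta_noise_sd`) is added per
#' probe and sample, truncated to `[0, 1]`.
#'
#' @param true a `true_methylome`.
#' @param probes optional tibble (`chrom`, `pos`) subsetting the CpGs assayed
#'   by the array; the default keeps all CpGs in CGIs/gDMRs plus a 30\%
#'   sample of the background.
#' @param n_controls number of control placenta samples (default 11).
#' @param gdmr_retention scalar overriding the planted per-gDMR retention
#'   (e.g. 0.2 for a strong inherited deficit); default uses each gDMR's
#'   planted mutant-oocyte retention.
#' @return a [beta_table()] with samples `placenta_01..` and `mole`.
#' @export
simulate_mole_betas <- function(true, probes = NULL, n_controls = 11,
                                gdmr_retention = NULL) {
  sim <- true$sim
  cpgs <- true$cpg
  lv <- sort(unique(c(cpgs$chrom, true$features$chrom)))
  gr_c <- gr_positions(cpgs, lv)
  f <- as_tibble(true$features)
  in_cat <- function(cats) {
    ff <- filter(f, .data$category %in% cats)
    if (nrow(ff) == 0) return(rep(FALSE, nrow(cpgs)))
    GenomicRanges::countOverlaps(gr_c, gr_intervals(ff, lv)) > 0
  }
  in_gdmr <- in_cat(c("maternal_gDMR", "placenta_gDMR"))
  in_cgi <- in_cat("CGI")
  if (is.null(probes)) {
    keep <- with_derived_seed(sim$seed, 404,
      in_gdmr | in_cgi | stats::runif(nrow(cpgs)) < 0.3)
  } else {
    keep <- paste(cpgs$chrom, cpgs$pos) %in% paste(probes$chrom, probes$pos)
  }
  idx <- which(keep)
  base <- rep(sim$remeth_level, length(idx))
  base[in_cgi[idx] & !in_gdmr[idx]] <- 0.10
  base[in_gdmr[idx]] <- 0.5
  # oocyte-inherited deficit at gDMR probes, halved for the single allele
  retention <- rep(1, length(idx))
  if (is.null(gdmr_retention)) {
    gd <- filter(true$regions, .data$type == "gdmr")
    hits <- GenomicRanges::findOverlaps(gr_positions(cpgs[idx, ], lv),
                                        gr_intervals(gd, lv))
    retention[S4Vectors::queryHits(hits)] <-
      gd$retention[S4Vectors::subjectHits(hits)]
  } else {
    retention[in_gdmr[idx]] <- gdmr_retention
  }
  mole_base <- ifelse(in_gdmr[idx], 0.5 * retention, base)
  with_derived_seed(sim$seed, 505, {
    df <- tibble(probe_id = sprintf("cg%07d", seq_along(idx)),
                 chrom = cpgs$chrom[idx], pos = cpgs$pos[idx])
    for (s in seq_len(n_controls)) {
      v <- base + stats::rnorm(length(idx), 0, sim$beta_noise_sd)
      df[[sprintf("placenta_%02d", s)]] <- pmin(pmax(v, 0), 1)
    }
    v <- mole_base + stats::rnorm(length(idx), 0, sim$beta_noise_sd)
    df$mole <- pmin(pmax(v, 0), 1)
    beta_table(df)
  })
}

#' Feature methylation expected under a true methylome
#'
#' The noiseless expectation of [feature_methylation()]: the unweighted mean
#' of per-CpG probabilities (x 100) over the CpGs inside each feature, for
#' any probability track.
#'
#' @param true a `true_methylome`.
#' @param features a [feature_table()].
#' @param track name of a probability column of `true$cpg` (e.g.
#'   `"p_oocyte"`) or a numeric vector aligned with `true$cpg`.
#' @return feature methylation tibble (`sample_id = "expected"`).
#' @export
true_feature_methylation <- function(true, features, track = "p_oocyte") {
  p <- if (is.character(track)) true$cpg[[track]] else track
  stopifnot(length(p) == nrow(true$cpg))
  lv <- sort(unique(c(features$chrom, true$cpg$chrom)))
  hits <- GenomicRanges::findOverlaps(gr_intervals(features, lv),
                                      gr_positions(true$cpg, lv))
  q <- S4Vectors::queryHits(hits)
  v <- p[S4Vectors::subjectHits(hits)]
  mean_p <- rep(NA_real_, nrow(features))
  n <- integer(nrow(features))
  if (length(q)) {
    tb <- tapply(v, q, function(x) c(length(x), mean(x)))
    ii <- as.integer(names(tb))
    n[ii] <- vapply(tb, `[`, numeric(1), 1)
    mean_p[ii] <- vapply(tb, `[`, numeric(1), 2)
  }
  tibble(name = features$name, category = features$category,
         chrom = features$chrom, start = features$start, end = features$end,
         meth_pct = 100 * mean_p, n_sites = n, sample_id = "expected")
}
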