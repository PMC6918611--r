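test_that("the generator is deterministic and mandatorily seeded", {
  expect_error(sim_config("tiny"), "seed")
  sim <- sim_config("tiny", seed = 3)
  t1 <- build_toy_genome(sim)
  t2 <- build_toy_genome(sim)
  expect_identical(as.character(t1$genome$seqs), as.character(t2$genome$seqs))
  expect_identical(as.data.frame(t1$features), as.data.frame(t2$features))
  # written artefacts are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome(t1$genome, file.path(d1, "g.fa"))
  write_genome(t2$genome, file.path(d2, "g.fa"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  t3 <- build_toy_genome(sim_config("tiny", seed = 4))
  expect_false(identical(as.character(t3$genome$seqs),
                         as.character(t1$genome$seqs)))
})

test_that("planted features appear in the requested numbers without overlap", {
  sim <- sim_config("tiny", seed = 5, n_maternal_gdmrs = 2)
  toy <- build_toy_genome(sim)
  f <- toy$features
  expect_equal(sum(f$category == "maternal_gDMR"), 2L)
  expect_equal(sum(f$category == "gene"), sim$n_genes)
  expect_equal(sum(f$category == "CGI"), sim$n_cgis)
  # genes are mutually disjoint, and the CpG-dense islands (CGIs, gDMRs)
  # never overlap one another; CGIs/gDMRs may nest inside gene bodies
  genes <- f[f$category == "gene", ]
  for (i in seq_len(nrow(genes)))
    expect_equal(sum(oracle_overlap_counts(genes[i, ], genes[-i, ]) > 0), 0L)
  islands <- f[f$category != "gene", ]
  for (i in seq_len(nrow(islands)))
    expect_equal(sum(oracle_overlap_counts(islands[i, ], islands[-i, ]) > 0),
                 0L, info = islands$name[i])
  expect_error(build_toy_genome(sim_config("tiny", seed = 5, n_genes = 40)),
               "longer chromosomes")
})

test_that("infeasible layouts error with advice", {
  sim <- sim_config("tiny", seed = 5, n_genes = 8)
  expect_error(build_toy_genome(sim), "longer chromosomes")
})

test_that("germline tracks follow the planted region rules", {
  w <- get_world()
  true <- w$true
  f <- w$features
  gr <- function(cat) f[f$category == cat, ]
  inside <- function(cpg, feats) {
    oracle_overlap_counts(tibble::tibble(chrom = cpg$chrom,
                                         start = cpg$pos - 1L,
                                         end = cpg$pos), feats) > 0
  }
  cpg <- true$cpg
  in_gene <- inside(cpg, gr("gene"))
  in_mat <- inside(cpg, dplyr::bind_rows(gr("maternal_gDMR"),
                                         gr("placenta_gDMR")))
  in_cgi <- inside(cpg, gr("CGI"))
  in_pat <- inside(cpg, gr("paternal_gDMR"))
  expect_true(all(cpg$p_oocyte[in_mat] == w$sim$gdmr_maternal_oocyte_p))
  expect_true(all(cpg$p_oocyte[in_gene & !in_mat] == w$sim$p_hyper))
  expect_true(all(cpg$p_oocyte[!in_gene & !in_mat] == w$sim$p_hypo))
  expect_true(all(cpg$p_sperm[in_cgi | in_mat] == w$sim$p_hypo))
  expect_true(all(cpg$p_sperm[in_pat] == w$sim$sperm_paternal_gdmr_p))
  expect_true(all(cpg$p_sperm[!in_cgi & !in_mat & !in_pat] ==
                    w$sim$sperm_global_p))
})

test_that("the mutant track scales the control by the loss factor", {
  # no dispersion, full retention: mutant identical to control
  w1 <- get_world("tiny", seed = 13, loss_factor = 1, loss_dispersion = 0)
  expect_equal(w1$true$cpg$p_mutant, w1$true$cpg$p_oocyte)
  # complete loss
  w0 <- get_world("tiny", seed = 13, loss_factor = 0, loss_dispersion = 0)
  expect_true(all(w0$true$cpg$p_mutant == 0))
  # mutant never exceeds control when retention <= 1
  w <- get_world()
  expect_true(all(w$true$cpg$p_mutant <= w$true$cpg$p_oocyte + 1e-12))
  # the mean mutant/control ratio over hypermethylated domains tracks the
  # loss factor within Monte-Carlo error of the per-region Beta draws
  genes <- w$features[w$features$category == "gene", ]
  ctrl <- true_feature_methylation(w$true, genes, "p_oocyte")
  mut <- true_feature_methylation(w$true, genes, "p_mutant")
  ratios <- mut$meth_pct / ctrl$meth_pct
  se <- w$sim$loss_dispersion / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - w$sim$loss_factor), 3 * se + 0.02)
})

test_that("lowering the loss factor never raises regional mutant methylation", {
  lows <- get_world("tiny", seed = 17, loss_factor = 0.3, loss_dispersion = 0)
  mids <- get_world("tiny", seed = 17, loss_factor = 0.55, loss_dispersion = 0)
  f <- lows$features
  m_low <- true_feature_methylation(lows$true, f, "p_mutant")$meth_pct
  m_mid <- true_feature_methylation(mids$true, f, "p_mutant")$meth_pct
  expect_true(all(m_low <= m_mid + 1e-12))
})

test_that("single cells capture the configured CpG fraction at depth 1", {
  w <- get_world()
  cell <- sample_cell(w$true, "control", cell_index = 1)
  expect_true(all(cell$meth + cell$unmeth == 1L))
  n <- nrow(w$true$cpg)
  frac <- nrow(cell) / n
  se <- sqrt(w$sim$cell_capture_frac * (1 - w$sim$cell_capture_frac) / n)
  expect_lt(abs(frac - w$sim$cell_capture_frac), 3 * se)
  # determinism per (seed, track, index)
  expect_identical(as.data.frame(sample_cell(w$true, "control", 1)),
                   as.data.frame(cell))
  expect_false(identical(as.data.frame(sample_cell(w$true, "control", 2)),
                         as.data.frame(cell)))
  # full capture of an all-methylated track observes every CpG as methylated
  sat <- w$true
  sat$cpg$p_oocyte <- 1
  sat$sim$cell_capture_frac <- 1
  full <- sample_cell(sat, "control", 1)
  expect_equal(nrow(full), n)
  expect_true(all(full$meth == 1L))
})

test_that("the embryo mixes the two alleles at the expected level", {
  w <- get_world()
  prof <- embryo_profile(w$true, maintenance_efficiency = 1,
                         paternal_retention = 0)
  expect_equal(prof$p_embryo, w$true$cpg$p_mutant / 2)
  prof0 <- embryo_profile(w$true, maintenance_efficiency = 0,
                          paternal_retention = 0)
  expect_true(all(prof0$p_embryo == 0))
  emb <- simulate_embryo(w$true, maintenance_efficiency = 0)
  gdmrs <- w$features[w$features$category == "maternal_gDMR", ]
  fm <- feature_methylation(emb, gdmrs, min_sites = 10)
  # only the demethylated paternal allele remains: sperm 0.10 * 0.25 / 2
  expect_true(all(fm$meth_pct < 8))
  expect_equal(as.data.frame(simulate_embryo(w$true)),
               as.data.frame(simulate_embryo(w$true)))
})

test_that("mole betas inherit the oocyte deficit at gDMRs only", {
  w <- get_world()
  full <- simulate_mole_betas(w$true, gdmr_retention = 1, n_controls = 3)
  gone <- simulate_mole_betas(w$true, gdmr_retention = 0, n_controls = 3)
  gdmrs <- w$features[w$features$category %in% c("maternal_gDMR",
                                                 "placenta_gDMR"), ]
  in_gdmr <- oracle_overlap_counts(
    tibble::tibble(chrom = full$chrom, start = full$pos - 1L, end = full$pos),
    gdmrs) > 0
  ctrl_mean <- rowMeans(cbind(full$placenta_01, full$placenta_02,
                              full$placenta_03))
  # full retention: mole matches control placenta at gDMR probes
  expect_lt(mean(abs(full$mole[in_gdmr] - ctrl_mean[in_gdmr])), 0.05)
  # zero retention: the methylated allele contributes nothing
  expect_lt(mean(gone$mole[in_gdmr]), 0.05)
  # away from gDMRs the two runs agree (same derived seeds)
  expect_equal(gone$mole[!in_gdmr], full$mole[!in_gdmr])
})

test_that("grouped quantification recovers planted domain means from 5 cells", {
  w <- get_world("study", seed = 29)
  cells <- lapply(1:5, function(i) sample_cell(w$true, "control", i))
  pooled <- pool_cells(cells)
  # planted >= 50-kb domains: gene bodies and the intergenic blocks
  genes <- w$features[w$features$category == "gene", ]
  inter <- dplyr::bind_rows(lapply(names(w$genome$lengths), function(ch) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    bounds <- c(0L, rbind(g$start, g$end), w$genome$lengths[[ch]])
    s <- bounds[seq(1, length(bounds), 2)]
    e <- bounds[seq(2, length(bounds), 2)]
    tibble::tibble(chrom = ch, start = s[e > s], end = e[e > s])
  }))
  doms <- feature_table(dplyr::bind_rows(
    genes[, c("chrom", "start", "end")], inter))
  doms <- doms[doms$end - doms$start >= 50000, ]
  est <- feature_methylation(pooled, doms, min_sites = 10)
  truth <- true_feature_methylation(w$true, doms, "p_oocyte")
  expect_true(all(!is.na(est$meth_pct)))
  expect_lt(max(abs(est$meth_pct - truth$meth_pct)), 5)
})
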