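test_that("feature scoring averages per-CpG percentages with a site minimum", {
  meth <- c(1L, 0L, 1L, 1L)
  calls <- cpg_calls(tibble::tibble(chrom = "chr1",
                                    pos = c(110L, 120L, 130L, 140L),
                                    meth = meth, unmeth = 1L - meth))
  gdmr <- feature_table(tibble::tibble(chrom = "chr1", start = 100L,
                                       end = 200L, name = "d1",
                                       category = "maternal_gDMR"))
  fm <- feature_methylation(calls, gdmr, min_sites = 1)
  expect_equal(fm$meth_pct, 75)
  # below the >= 10 CpGs/gDMR coverage threshold the value is missing
  fm10 <- feature_methylation(calls, gdmr, min_sites = 10)
  expect_true(is.na(fm10$meth_pct))
  expect_equal(fm10$n_sites, 4L)
  # equivalence with quantify on windows equal to the feature intervals
  q <- quantify(calls, gdmr[, c("chrom", "start", "end")], min_sites = 1)
  expect_equal(fm$meth_pct, q$meth_pct)
})

test_that("feature scoring is invariant to feature order and bounded", {
  w <- get_world()
  calls <- sample_bulk(w$true, "control")
  fm1 <- feature_methylation(calls, w$features, min_sites = 5)
  shuf <- w$features[rev(seq_len(nrow(w$features))), ]
  fm2 <- feature_methylation(calls, shuf, min_sites = 5)
  expect_equal(fm1[match(fm2$name, fm1$name), ]$meth_pct, fm2$meth_pct)
  expect_true(all(fm1$meth_pct >= 0 & fm1$meth_pct <= 100, na.rm = TRUE))
})

test_that("CGI classification uses strict thresholds", {
  ref <- tibble::tibble(name = paste0("c", 1:5),
                        meth_pct = c(71, 19, 50, 70, NA))
  cls <- classify_cgis(ref)
  expect_equal(cls$cgi_class, c("methylated", "unmethylated", "intermediate",
                                "intermediate", "unclassified"))
})

test_that("delta tables report control minus case with missing-value handling", {
  mk <- function(vals) tibble::tibble(name = paste0("f", seq_along(vals)),
                                      category = rep(c("gene", "CGI"),
                                                     length.out = length(vals)),
                                      meth_pct = vals)
  d <- delta_table(case = mk(c(60, 40, NA, 10)),
                   control = mk(c(80, 50, 70, 30)))
  expect_equal(d$features$delta, c(20, 10, NA, 20))
  used <- d$features[!is.na(d$features$delta), ]
  for (cat in unique(used$category)) {
    expect_equal(d$by_category$mean_delta[d$by_category$category == cat],
                 mean(used$delta[used$category == cat]))
  }
  expect_equal(d$by_category$n_dropped[d$by_category$category == "gene"], 1L)
  expect_error(delta_table(mk(1), dplyr::mutate(mk(1), name = "zzz")),
               "no features")
})

test_that("matched control regions honour both tolerance bands", {
  w <- get_world()
  calls <- sample_bulk(w$true, "control")
  gdmrs <- w$features[w$features$category == "maternal_gDMR", ]
  g_fm <- feature_methylation(calls, gdmrs, min_sites = 5)
  cands <- make_tiles(w$genome, 3)
  res <- match_control_regions(g_fm, cands, calls, tol_meth = 10,
                               tol_density = 0.5, n_per_gdmr = 5, seed = 3)
  expect_gt(nrow(res$matched), 0)
  m_fm <- feature_methylation(calls, res$matched, min_sites = 1)
  dens <- function(t) t$n_sites / ((t$end - t$start) / 1000)
  for (i in seq_len(nrow(res$matched))) {
    g <- sub("_match.*", "", res$matched$name[i])
    gi <- match(g, g_fm$name)
    expect_lte(abs(m_fm$meth_pct[i] - g_fm$meth_pct[gi]), 10)
    expect_lte(abs(dens(m_fm)[i] - dens(g_fm)[gi]), 0.5 * dens(g_fm)[gi])
  }
  # matched regions never overlap a gDMR
  expect_equal(sum(oracle_overlap_counts(res$matched, gdmrs)), 0L)
  # construction property: matched mean methylation tracks the gDMR mean
  expect_lte(abs(mean(m_fm$meth_pct) - mean(g_fm$meth_pct, na.rm = TRUE)), 10)
  # impossible tolerance: every gDMR unmatched, each with a warning
  ws <- testthat::capture_warnings(
    res0 <- match_control_regions(g_fm, cands, calls, tol_meth = 0,
                                  tol_density = 0, n_per_gdmr = 2, seed = 3))
  expect_true(all(grepl("no matched control region", ws)))
  expect_length(ws, nrow(gdmrs))
  expect_equal(sort(res0$unmatched), sort(gdmrs$name))
  expect_equal(nrow(res0$matched), 0L)
})

test_that("a candidate identical to the gDMR is matched at zero tolerance", {
  calls <- cpg_calls(tibble::tibble(chrom = "chr1",
                                    pos = c(10L, 20L, 510L, 520L),
                                    meth = c(1L, 0L, 1L, 0L),
                                    unmeth = c(0L, 1L, 0L, 1L)))
  gdmr <- feature_table(tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                                       name = "d", category = "maternal_gDMR"))
  g_fm <- feature_methylation(calls, gdmr, min_sites = 1)
  cand <- tibble::tibble(chrom = "chr1", start = 500L, end = 600L)
  res <- match_control_regions(g_fm, cand, calls, tol_meth = 0,
                               tol_density = 0, n_per_gdmr = 1,
                               min_sites = 1, seed = 1)
  expect_equal(res$matched$start, 500L)
})

test_that("gene-level LoM varies less than random CpG windows under gene-coherent loss", {
  w <- get_world("tiny", seed = 19, loss_dispersion = 0.15)
  ctrl <- sample_bulk(w$true, "control")
  mut <- sample_bulk(w$true, "mutant")
  genes <- w$features[w$features$category == "gene", ]
  vp <- variability_profile(mut, ctrl, genes, n_windows = 150, seed = 5)
  expect_equal(nrow(vp$gene_lom), nrow(genes))
  expect_lte(vp$gene_sd, vp$window_sd)
  # identical samples: LoM identically zero, both s.d. zero
  vp0 <- variability_profile(ctrl, ctrl, genes, n_windows = 50, seed = 5)
  expect_equal(vp0$gene_sd, 0)
  expect_equal(vp0$window_sd, 0)
})

test_that("expression correlation is rank-based and guards degenerate input", {
  d <- tibble::tibble(name = paste0("g", 1:20), delta = 1:20)
  e <- tibble::tibble(name = paste0("g", 1:20), expression = exp(1:20 / 3))
  r <- expression_correlation(d, e)
  expect_equal(r$estimate, 1)
  withr::with_seed(9, {
    e2 <- e
    e2$expression <- sample(e$expression)
    r2 <- expression_correlation(d, e2)
    expect_lt(abs(r2$estimate), 0.45)
  })
  e3 <- dplyr::mutate(e, expression = 5)
  expect_error(expression_correlation(d, e3), "constant")
  expect_error(expression_correlation(d[1:2, ], e[1:2, ]), "fewer than 3")
})
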