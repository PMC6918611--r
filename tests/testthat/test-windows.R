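test_that("fixed tiles are consecutive, truncated at chromosome ends", {
  tiles <- make_tiles(c(chr1 = 50000L), 20)
  expect_equal(tiles$start, c(0L, 20000L, 40000L))
  expect_equal(tiles$end, c(20000L, 40000L, 50000L))
  # width beyond chromosome length: a single clipped window
  tiles <- make_tiles(c(chr1 = 5000L), 20)
  expect_equal(nrow(tiles), 1L)
  expect_equal(tiles$end, 5000L)
})

test_that("sliding windows sit on the step grid and degenerate to tiles", {
  w <- make_sliding(c(chr1 = 120000L), 100, 10)
  expect_equal(w$start, seq(0L, 110000L, by = 10000L))
  expect_true(all(w$end <= 120000L))
  expect_equal(make_sliding(c(chr1 = 95000L), 20, 20),
               make_tiles(c(chr1 = 95000L), 20))
})

test_that("sliding-window membership matches a brute-force oracle", {
  withr::local_seed(7)
  wins <- make_sliding(c(chr1 = 50000L), 10, 2)
  for (i in 1:20) {
    pos <- sort(sample(50000L, 30))
    calls <- cpg_calls(tibble::tibble(chrom = "chr1", pos = pos,
                                      meth = 1L, unmeth = 0L))
    q <- quantify(calls, wins, min_sites = 1)
    o <- oracle_quantify(calls, wins, min_sites = 1)
    expect_equal(q$n_sites, o$n_sites)
  }
})

test_that("window value averages per-CpG percentages, not pooled counts", {
  # one CpG 2/2 methylated (100%), one 0/3 (0%): mean 50, pooled would be 40
  calls <- cpg_calls(tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                                    meth = c(2L, 0L), unmeth = c(0L, 3L)))
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(quantify(calls, w, min_sites = 1)$meth_pct, 50)
  # empty window is missing, not zero
  w2 <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                       end = c(1000L, 2000L))
  q <- quantify(calls, w2, min_sites = 1)
  expect_true(is.na(q$meth_pct[2]))
  expect_equal(q$n_sites[2], 0L)
  # below min_sites the value is withheld but the count reported
  q <- quantify(calls, w, min_sites = 3)
  expect_true(is.na(q$meth_pct))
  expect_equal(q$n_sites, 2L)
})

test_that("for depth-1 calls the window value is the methylated fraction", {
  withr::local_seed(13)
  meth <- sample(0:1, 40, replace = TRUE)
  calls <- cpg_calls(tibble::tibble(chrom = "chr1",
                                    pos = sort(sample(5000L, 40)),
                                    meth = meth, unmeth = 1L - meth))
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 5000L)
  expect_equal(quantify(calls, w, 1)$meth_pct, 100 * mean(calls$meth))
})

test_that("quantification is invariant to record order and tiles partition CpGs", {
  withr::local_seed(5)
  calls <- random_calls(80, max_pos = 40000)
  tiles <- make_tiles(c(chr1 = 40000L, chr2 = 40000L), 10)
  q1 <- quantify(calls, tiles, 2)
  shuffled <- cpg_calls(dplyr::slice_sample(tibble::as_tibble(calls),
                                            n = nrow(calls)), "rand")
  expect_equal(quantify(shuffled, tiles, 2), q1)
  expect_equal(sum(q1$n_sites), nrow(calls))  # every CpG in exactly one tile
})

test_that("all-samples intersection keeps jointly covered windows only", {
  w <- tibble::tibble(chrom = "chr1", start = c(0L, 10L), end = c(10L, 20L))
  t1 <- dplyr::mutate(w, meth_pct = c(50, NA), n_sites = c(5L, 1L),
                      sample_id = "a")
  t2 <- dplyr::mutate(w, meth_pct = c(20, 80), n_sites = c(4L, 6L),
                      sample_id = "b")
  ic <- intersect_covered(list(t1, t2))
  expect_equal(ic$n_kept, 1L)
  expect_equal(ic$retention_pct, 50)
  expect_equal(ic$tables[[2]]$meth_pct, 20)
  ic2 <- intersect_covered(list(t2, t2))
  expect_equal(ic2$retention_pct, 100)
  t3 <- dplyr::mutate(t2, start = start + 1L)
  expect_error(intersect_covered(list(t1, t3)), "window lists differ")
})

test_that("pooling cells sums counts per site and never loses coverage", {
  a <- cpg_calls(tibble::tibble(chrom = "chr1", pos = c(10L, 30L),
                                meth = c(1L, 1L), unmeth = c(0L, 0L)), "a")
  b <- cpg_calls(tibble::tibble(chrom = "chr1", pos = c(10L, 50L),
                                meth = c(0L, 0L), unmeth = c(1L, 1L)), "b")
  pooled <- pool_cells(list(a, b))
  expect_equal(pooled$pos, c(10L, 30L, 50L))
  expect_equal(pooled$meth[1], 1L)
  expect_equal(pooled$unmeth[1], 1L)   # 1/1 -> 50% at the shared site
  expect_gte(nrow(pooled), max(nrow(a), nrow(b)))
})

test_that("global methylation equals one genome-spanning window", {
  meth <- c(1L, 1L, 0L, 1L)
  calls <- cpg_calls(tibble::tibble(chrom = "chr1",
                                    pos = c(10L, 20L, 30L, 40L),
                                    meth = meth, unmeth = 1L - meth))
  expect_equal(global_methylation(calls), 75)
  allu <- cpg_calls(tibble::tibble(chrom = "chr1", pos = 1:3 * 10L,
                                   meth = 0L, unmeth = 1L))
  expect_equal(global_methylation(allu), 0)
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(global_methylation(calls), quantify(calls, w, 1)$meth_pct)
  empty <- suppressWarnings(
    cpg_calls(tibble::tibble(chrom = character(), pos = integer(),
                             meth = integer(), unmeth = integer())))
  expect_error(global_methylation(empty), "no CpG")
})

test_that("array windows need a minimum of informative probes", {
  b <- beta_table(tibble::tibble(probe_id = paste0("p", 1:5), chrom = "chr1",
                                 pos = c(10L, 20L, 30L, 110L, 120L),
                                 s1 = c(0.2, 0.4, 0.6, 0.5, 0.5)))
  w <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                      end = c(100L, 200L))
  q <- array_quantify(b, w, min_probes = 3)$s1
  expect_equal(q$meth_pct[1], 40)       # 100 * mean(0.2, 0.4, 0.6)
  expect_true(is.na(q$meth_pct[2]))     # only 2 probes
  expect_equal(q$n_sites, c(3L, 2L))
})
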