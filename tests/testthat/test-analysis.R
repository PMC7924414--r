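test_that("self-comparison yields fold change 1 and no significance", {
  sig <- sample_uniform(fx$assembly, 500, seed = 71)$sites
  res <- analyze(sig, sig, list(fx$track))
  expect_equal(res$fold_change, 1)
  expect_equal(res$p_adj, 1)
  expect_false(res$significant)
})

test_that("analyze recovers constructed enrichment arithmetic", {
  tr <- interval_track(data.frame(contig = "chrA", start = 0, end = 10000),
                       label = "T")
  sig <- position_set(rep("chrA", 100), sample.int(10000, 100) - 1)
  bg <- position_set(rep("chrA", 200),
                     c(sample.int(10000, 100) - 1,
                       10000 + sample.int(100000, 100)))
  res <- analyze(sig, bg, list(tr))
  expect_equal(res$fold_change, 2)
  expect_error(analyze(sig, bg, list()), "length")
  expect_error(analyze(position_set(character(), numeric()), bg, list(tr)),
               "empty signal")
})

test_that("scored tracks get a KS row comparing score distributions", {
  set.seed(72)
  ivs <- data.frame(contig = "chrA",
                    start = seq(0, 90000, by = 10000),
                    end = seq(0, 90000, by = 10000) + 5000,
                    score = 1:10)
  sc <- scored_track(ivs, label = "scores")
  sig <- random_sites(fx$assembly, 400)
  bg <- sample_uniform(fx$assembly, 400, seed = 73)
  res <- analyze(sig, bg, list(fx$track, sc))
  expect_true(is.na(res$ks_D[res$track == "feat"]))
  expect_false(is.na(res$ks_D[res$track == "scores"]))
  expect_true(res$ks_D[res$track == "scores"] >= 0)
})

test_that("batch rows equal single analyses and share the background", {
  set.seed(74)
  sig1 <- random_sites(fx$assembly, 300)
  sig1$label <- "s1"
  sig2 <- random_sites(fx$assembly, 300)
  sig2$label <- "s2"
  bg <- sample_uniform(fx$assembly, 1000, seed = 75)
  tracks <- list(fx$track, fx$eco)
  m <- batch(list(sig1, sig2), bg, tracks)
  single <- analyze(sig1, bg, tracks)
  for (tr in tracks) {
    expect_equal(m$log2_fc["s1", tr$label],
                 single$log2_fc[single$track == tr$label])
  }
  # duplicated signal -> identical rows
  sig1b <- sig1
  sig1b$label <- "s1copy"
  m2 <- batch(list(sig1, sig1b), bg, tracks)
  expect_equal(unname(m2$log2_fc["s1", ]), unname(m2$log2_fc["s1copy", ]))
})

test_that("background comparison attenuates a matched covariate's cell", {
  g <- gen_genome(c(chrC = 500000), gc = 0.5, seed = 76)
  tr <- gen_track(g$assembly, coverage = 0.1, mean_len = 800, seed = 77,
                  label = "T")
  sig <- gen_sites(g$assembly, 3000, prefs = list(list(track = tr, r = 3)),
                   seed = 78)$sites
  bgu <- sample_uniform(g$assembly, 5000, seed = 79)
  bgm <- sample_matched(sig, covariate("membership", track = tr),
                        g$assembly, n = 5000, seed = 79)
  m <- compare_backgrounds(sig, list(bgu, bgm), list(tr))
  expect_equal(nrow(m$log2_fc), 2L)
  expect_lt(abs(m$log2_fc[2, "T"]), abs(m$log2_fc[1, "T"]))
  # identical backgrounds give identical rows
  m2 <- compare_backgrounds(sig, list(bgu, bgu), list(tr))
  expect_equal(unname(m2$log2_fc[1, ]), unname(m2$log2_fc[2, ]))
  expect_error(compare_backgrounds(sig, list(bgu), list(tr)), ">= 2")
})

test_that("hotspot windows tile contigs and conserve the site count", {
  asm <- genome_assembly(c(chrA = 100000))
  sig <- position_set(rep("chrA", 50), sample.int(10000, 50))
  hs <- hotspots(sig, asm, window = 10000)
  expect_equal(nrow(hs), 10L)
  expect_equal(sum(hs$count), 50L)
  expect_equal(hs$ratio[1], 1.0)       # all sites in the first window
  expect_equal(hs$count[1], 50L)

  set.seed(80)
  sigu <- position_set(rep("chrA", 10000), floor(runif(10000) * 100000))
  hs <- hotspots(sigu, asm, window = 10000)
  expect_equal(sum(hs$count), 10000L)
  expect_true(all(abs(hs$ratio - 0.1) < 0.01))
  # truncated last window
  asm2 <- genome_assembly(c(chrA = 25000))
  hs2 <- hotspots(sig, asm2, window = 10000)
  expect_equal(hs2$end[order(hs2$start)], c(10000, 20000, 25000))
})

test_that("positional enrichment applies the pseudocounted rate ratio", {
  asm <- genome_assembly(c(chrA = 20000))
  sig <- position_set(rep("chrA", 10), c(rep(1000, 8), rep(15000, 2)))
  bg <- position_set(rep("chrA", 10), c(rep(1000, 5), rep(15000, 5)))
  pe <- positional_enrichment(sig, bg, asm, bin = 10000)
  # hand-computed two-bin case: s=(8,2), b=(5,5), k=2
  expect_equal(pe$log2_enrichment,
               c(log2((8.5 / 11) / (5.5 / 11)), log2((2.5 / 11) / (5.5 / 11))))
  expect_gt(pe$log2_enrichment[1], 0)
  expect_lt(pe$log2_enrichment[2], 0)
  # identical sets give all-zero cells
  pe0 <- positional_enrichment(sig, sig, asm, bin = 10000)
  expect_equal(pe0$log2_enrichment, c(0, 0))
  # per-contig conservation
  expect_equal(sum(pe$s_count), 10L)
})

test_that("CSV export writes the documented columns and round-trips", {
  sig <- sample_uniform(fx$assembly, 300, seed = 81)$sites
  bg <- sample_uniform(fx$assembly, 300, seed = 82)
  res <- analyze(sig, bg, list(fx$track, fx$eco))
  p <- tempfile(fileext = ".csv")
  export_csv(res, p)
  lines <- readLines(p)
  expect_equal(lines[1],
               "track,s_in,s_out,b_in,b_out,fold_change,log2_fc,chi2,p_raw,p_adj,significant")
  expect_equal(length(lines), 3L)
  back <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(back$track, res$track)
  expect_equal(back$s_in, res$s_in)
  expect_equal(back$fold_change, res$fold_change, tolerance = 1e-5)

  # infinite fold change prints as "inf"
  tr0 <- interval_track(data.frame(contig = "chrA", start = 0, end = 50),
                        label = "rare")
  sig2 <- position_set("chrA", 10)
  bg2 <- position_set(rep("chrA", 10), 1000 + (1:10))
  res2 <- analyze(sig2, bg2, list(tr0))
  export_csv(res2, p)
  expect_match(readLines(p)[2], ",inf,")

  # batch matrix export with significance stars
  m <- batch(list(sig), bg, list(fx$track))
  export_csv(m, p)
  lines <- readLines(p)
  expect_equal(lines[1], paste0("signal,", fx$track$label))
  expect_equal(length(lines), 2L)
})
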