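test_that("largest-remainder allocation is exact and deterministic", {
  expect_equal(unname(largest_remainder(c(a = 30, b = 20, c = 40, d = 10), 100)),
               c(30L, 20L, 40L, 10L))
  a <- largest_remainder(c(x = 1, y = 1, z = 1), 100)
  expect_equal(sum(a), 100L)
  # remainder ties break lexicographically
  expect_equal(a, c(x = 34L, y = 33L, z = 33L))
  set.seed(41)
  for (i in 1:50) {
    w <- runif(sample(2:12, 1))
    names(w) <- sprintf("s%02d", seq_along(w))
    n <- sample.int(500, 1)
    al <- largest_remainder(w, n)
    expect_equal(sum(al), n)
    expect_true(all(abs(al - w / sum(w) * n) < 1))
  }
})

test_that("uniform sampling respects the universe and its restriction", {
  asm <- genome_assembly(c(chrA = 100))
  bg <- sample_uniform(asm, n = 5, seed = 3)
  expect_equal(length(bg), 5L)
  expect_true(all(bg$sites$coord >= 0 & bg$sites$coord < 100))

  restrict <- interval_track(data.frame(contig = "chrA", start = 0, end = 10))
  bg <- sample_uniform(asm, n = 1000, seed = 3, restrict = restrict)
  expect_true(all(bg$sites$coord < 10))
  expect_error(sample_uniform(asm, n = 1, restrict = interval_track(
    data.frame(contig = character(), start = numeric(), end = numeric()))),
    "empty sampling universe")
})

test_that("uniform sampling is proportional to contig length and unbiased", {
  asm <- genome_assembly(c(chrA = 900000, chrB = 100000))
  bg <- sample_uniform(asm, n = 100000, seed = 12)
  frac_b <- mean(bg$sites$contig == "chrB")
  expect_lt(abs(frac_b - 0.1), 0.01)

  # goodness of fit over 10 equal slices of one contig
  asm1 <- genome_assembly(c(chrA = 1000000))
  bg <- sample_uniform(asm1, n = 100000, seed = 13)
  counts <- tabulate(floor(bg$sites$coord / 100000) + 1, nbins = 10)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("samplers are bit-for-bit deterministic under a fixed seed", {
  b1 <- sample_uniform(fx$assembly, n = 500, seed = 99)
  b2 <- sample_uniform(fx$assembly, n = 500, seed = 99)
  expect_identical(b1$sites, b2$sites)
  expect_false(identical(
    b1$sites, sample_uniform(fx$assembly, n = 500, seed = 100)$sites))

  m1 <- sample_matched(b1$sites, covariate("membership", track = fx$track),
                       fx$assembly, n = 400, seed = 5)
  m2 <- sample_matched(b1$sites, covariate("membership", track = fx$track),
                       fx$assembly, n = 400, seed = 5)
  expect_identical(m1$sites, m2$sites)

  d1 <- sample_distance_matched(b1$sites, fx$eco, fx$assembly, n = 300,
                                seed = 7)
  d2 <- sample_distance_matched(b1$sites, fx$eco, fx$assembly, n = 300,
                                seed = 7)
  expect_identical(d1$sites, d2$sites)
})

test_that("stratification partitions sites with signal-derived bins", {
  tr <- interval_track(data.frame(contig = "chrA", start = 0, end = 1000),
                       label = "T")
  sig <- position_set(rep("chrA", 100), c(seq_len(60) * 10, 1000 + seq_len(40)))
  st <- stratify(sig, covariate("membership", track = tr))
  expect_equal(st$counts, c("in" = 60L, "out" = 40L))

  tr2 <- interval_track(data.frame(contig = "chrA", start = 500, end = 1500),
                        label = "U")
  st2 <- stratify(sig, list(covariate("membership", track = tr),
                            covariate("membership", track = tr2)))
  expect_lte(length(st2$counts), 4L)
  expect_equal(sum(st2$counts), 100L)

  # equal-frequency distance bins: 10 bins on 1000 distinct distances
  set.seed(44)
  feat <- interval_track(data.frame(contig = "chrA", start = 0, end = 1),
                         label = "pt")
  sig3 <- position_set(rep("chrA", 1000), sample(seq_len(100000), 1000))
  st3 <- stratify(sig3, covariate("distance", track = feat, bins = 10))
  expect_equal(unname(st3$counts), rep(100L, 10))
  # oracle: sorted distances split into consecutive runs of 100
  d <- sort(nearest_distance(sig3, st3$covariates[[1]]$track))
  cuts <- d[seq(100, 900, by = 100)]
  expect_equal(sort(unique(st3$covariates[[1]]$cb)), unique(cuts))

  expect_error(stratify(sig, list()), "stratifying covariate")
})

test_that("matched sampling reproduces stratum proportions exactly", {
  set.seed(45)
  # signal exactly 50% inside T
  tr <- interval_track(data.frame(contig = "chrA", start = 0, end = 50000),
                       label = "T")
  sig <- position_set(rep("chrA", 200),
                      c(sample.int(50000, 100) - 1, 50000 + sample.int(90000, 100)))
  bg <- sample_matched(sig, covariate("membership", track = tr),
                       fx$assembly, n = 10000, seed = 5)
  cm <- count_membership(bg$sites, tr)
  expect_equal(cm$n_in, 5000L)
  expect_equal(cm$n_out, 5000L)
  expect_equal(sum(bg$provenance$allocation), 10000L)

  # matching neutralizes the covariate's own track: fc = 1 up to rounding
  res <- analyze(sig, bg, list(tr))
  eps <- length(bg$provenance$allocation) / 10000
  expect_lt(abs(res$fold_change - 1), 2 * eps + 1e-9)
})

test_that("joint membership strata are allocated with exact integer shares", {
  set.seed(46)
  # two tracks splitting chrA into quadrant-like strata
  trA <- interval_track(data.frame(contig = "chrA", start = 0, end = 75000),
                        label = "A")
  trB <- interval_track(data.frame(contig = "chrA", start = 50000, end = 150000),
                        label = "B")
  # 30 in A only, 20 in A&B, 40 in B only, 10 outside
  sig <- position_set(rep("chrA", 100),
                      c(sample.int(50000, 30) - 1,
                        50000 + sample.int(25000, 20) - 1,
                        75000 + sample.int(75000, 40) - 1,
                        rep(0, 10)))
  sig$contig[91:100] <- "chrB"
  covs <- list(covariate("membership", track = trA),
               covariate("membership", track = trB))
  st <- stratify(sig, covs)
  bg <- sample_matched(sig, covs, fx$assembly, n = 100, seed = 8)
  stb <- table(joint_labels_for_test(st$covariates, bg$sites))
  expect_equal(as.integer(stb[names(st$counts)]), unname(st$counts))
})

test_that("unsatisfiable strata raise an error naming the stratum", {
  tr <- interval_track(data.frame(contig = "chrA", start = 0, end = 1000),
                       label = "T")
  sig <- position_set(rep("chrA", 10), seq_len(10) * 50)   # all inside T
  away <- interval_track(data.frame(contig = "chrB", start = 0, end = 1000))
  expect_error(
    sample_matched(sig, covariate("membership", track = tr), fx$assembly,
                   n = 100, seed = 1, restrict = away),
    "unsatisfiable stratum 'in'")
})

test_that("distance matching reproduces the signal distance multiset", {
  # single feature mid-contig, one signal distance of 10:
  # the two admissible placements are start-10 and end-1+10
  asm <- genome_assembly(c(chrA = 1000))
  feat <- interval_track(data.frame(contig = "chrA", start = 500, end = 510))
  sig <- position_set("chrA", 490)
  hits <- vapply(1:20, function(s) {
    sample_distance_matched(sig, feat, asm, seed = s, resample = FALSE)$sites$coord
  }, 0.0)
  expect_true(all(hits %in% c(490, 519)))
  expect_equal(length(unique(hits)), 2L)

  # distances {0,0,5} copied exactly in no-resample mode
  sig3 <- position_set(rep("chrA", 3), c(502, 505, 495))
  ctl <- sample_distance_matched(sig3, feat, asm, seed = 4, resample = FALSE)
  expect_equal(sort(nearest_distance(ctl$sites, feat)), c(0, 0, 5))
  expect_error(
    sample_distance_matched(sig3, feat, asm, n = 5, resample = FALSE),
    "requires n = length")

  # larger no-resample case on the shared fixture
  sig <- sample_uniform(fx$assembly, 500, seed = 31)$sites
  ctl <- sample_distance_matched(sig, fx$eco, fx$assembly, seed = 32,
                                 resample = FALSE)
  expect_equal(sort(nearest_distance(ctl$sites, fx$eco)),
               sort(nearest_distance(sig, fx$eco)))
})

test_that("resampled distance matching reproduces the distribution", {
  sig <- sample_uniform(fx$assembly, 200, seed = 33)$sites
  ctl <- sample_distance_matched(sig, fx$eco, fx$assembly, n = 5000,
                                 seed = 34, resample = TRUE)
  ks <- suppressMessages(ks_test(nearest_distance(ctl$sites, fx$eco),
                                 nearest_distance(sig, fx$eco)))
  expect_lt(ks$D, 0.08)
})

test_that("infinite signal distances map to feature-less contigs", {
  asm <- genome_assembly(c(chrA = 10000, chrEmpty = 5000))
  feat <- interval_track(data.frame(contig = "chrA", start = 100, end = 200))
  sig <- position_set(c("chrA", "chrEmpty"), c(150, 100))
  ctl <- sample_distance_matched(sig, feat, asm, seed = 9, resample = FALSE)
  expect_equal(sort(is.infinite(nearest_distance(ctl$sites, feat))),
               c(FALSE, TRUE))
})

test_that("user-supplied backgrounds load and round-trip", {
  sig <- sample_uniform(fx$assembly, 100, seed = 51)$sites
  p <- tempfile(fileext = ".bed")
  write_bed(sig, p)
  bg <- load_background(p, fx$assembly)
  expect_equal(length(bg), 100L)
  expect_equal(bg$provenance$model, "user_supplied")
  p2 <- tempfile(fileext = ".bed")
  write_background(bg, p2)
  expect_identical(readLines(p2), readLines(p))
  expect_true(file.exists(paste0(p2, ".json")))
  expect_error(load_background(tmp_bed("chrUn\t1\t2"), fx$assembly),
               "absent from assembly")
})
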