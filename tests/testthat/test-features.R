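test_that("signal window is 2000 bp, centered, zero-padded, max-normalized", {
  trk <- plateau_track(10000, background = 0,
                       plateaus = list(c(4000, 4200, 10), c(4050, 4150, 20)))
  w <- encode_signal_window(trk, "chr1", 4000, 4200)
  expect_length(w, 2000)
  expect_equal(max(w), 1)
  mid <- (4000 + 4200) %/% 2
  expect_equal(w, trk$values$chr1[(mid - 1000 + 1):(mid + 1000)] / 20)

  # all-zero stays all-zero
  expect_equal(encode_signal_window(trk, "chr1", 8000, 8100), rep(0, 2000))

  # region near the chromosome start: left half is padding
  w <- encode_signal_window(trk, "chr1", 450, 550)
  expect_equal(w[1:500], rep(0, 500))

  # invariant to track rescaling
  big <- coverage_track(list(chr1 = trk$values$chr1 * 1000))
  expect_equal(encode_signal_window(big, "chr1", 4000, 4200), w * 0 +
               encode_signal_window(trk, "chr1", 4000, 4200))
})

test_that("the 11 enrichment features behave as max-vs-background ratios", {
  const <- plateau_track(200000, background = 3.5)
  expect_equal(enrichment_features(const, "chr1", 5000, 5400), rep(1, 11))
  zero <- plateau_track(200000, background = 0)
  expect_equal(enrichment_features(zero, "chr1", 5000, 5400), rep(1, 11))

  # brute-force oracle on a single plateau over unit background
  trk <- plateau_track(10000, background = 1,
                       plateaus = list(c(4900, 5100, 10)))
  f <- enrichment_features(trk, "chr1", 4900, 5100)
  v <- trk$values$chr1
  mid <- 5000
  expected <- vapply(seq(10000, 100000, by = 10000), function(b) {
    lo <- max(mid - b / 2, 0); hi <- min(mid + b / 2, 10000)
    (10 + 0.1) / (sum(v[(lo + 1):hi]) / (hi - lo) + 0.1)
  }, numeric(1))
  expected <- c(expected, (10 + 0.1) / (sum(v) / 10000 + 0.1))
  expect_equal(f, expected)
  expect_length(f, 11)
  expect_true(all(f > 1))  # region holds the chromosome maximum

  # rescaling changes the ratios only through the fixed pseudocount; at
  # coverage >= 1 that bounds the relative drift near eps/bg = 10%
  for (c in c(10, 1000)) {
    scaled <- coverage_track(list(chr1 = v * c))
    fs <- enrichment_features(scaled, "chr1", 4900, 5100)
    expect_equal(fs, f, tolerance = 0.1)
    # and the scaled features approach the exact eps -> 0 ratio
    limit <- vapply(seq(10000, 100000, by = 10000), function(b) {
      lo <- max(mid - b / 2, 0); hi <- min(mid + b / 2, 10000)
      10 / (sum(v[(lo + 1):hi]) / (hi - lo))
    }, numeric(1))
    if (c == 1000)
      expect_equal(fs, c(limit, 10 / mean(v)), tolerance = 0.01)
  }
})

test_that("input-control p-values are Poisson upper tails", {
  trt <- plateau_track(10000, background = 0,
                       plateaus = list(c(2000, 2100, 2)))
  inp <- plateau_track(10000, background = 1)

  # zero observed signal -> p = 1
  expect_equal(pvalue_vs_input(trt, inp, "chr1", 5000, 5100), 1)

  # oracle: P(X >= 20 | lambda = 5) by direct mass summation;
  # equal chromosome totals make the depth ratio 1
  trt2 <- coverage_track(list(chr1 = c(rep(1, 20), rep(0, 60), rep(1, 20))))
  inp2 <- coverage_track(list(chr1 = c(rep(0.25, 20), rep(0.4375, 80))))
  expect_equal(sum(trt2$values$chr1), sum(inp2$values$chr1))
  p <- pvalue_vs_input(trt2, inp2, "chr1", 0, 20)   # observed 20, lambda 5
  oracle <- 1 - sum(exp(-5) * 5^(0:19) / factorial(0:19))
  expect_equal(p, oracle, tolerance = 1e-8)

  # monotone: at fixed lambda, a larger observed count never raises p
  ps <- vapply(c(1, 5, 10, 20, 40), function(n) {
    t3 <- coverage_track(list(chr1 = c(rep(n / 20, 20),
                                       rep((40 - n) / 80, 80))))
    pvalue_vs_input(t3, inp2, "chr1", 0, 20)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))

  # all-zero input: lambda floored with a warning
  zin <- plateau_track(10000, background = 0)
  expect_warning(p0 <- pvalue_vs_input(trt, zin, "chr1", 2000, 2100),
                 "floored")
  expect_equal(p0, stats::ppois(200 - 1, 0.1, lower.tail = FALSE))
})

test_that("extract_features bundles match the per-region functions", {
  sim <- simulate_track(simulation_config(chrom_length = 1e5, n_peaks = 10,
                                          n_noise = 15, seed = 21))
  regions <- make_training_set(sim$track, sim$truth)
  fb <- extract_features(sim$track, regions, input_track = sim$track)
  expect_s3_class(fb, "feature_bundles")
  expect_equal(dim(fb$signal), c(20L, 2000L))
  expect_equal(dim(fb$enrich), c(20L, 11L))
  expect_true(all(fb$enrich > 0))
  i <- 7L
  expect_equal(fb$signal[i, ],
               encode_signal_window(sim$track, regions$chrom[i],
                                    regions$start[i], regions$end[i]))
  # treatment as its own input: observed ~= lambda, so p-values are large
  expect_true(all(fb$pvalue >= 0.3))
})
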