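test_that("rolling_mean matches the brute-force windowed mean", {
  expect_equal(rolling_mean(rep(7, 100), 16), rep(7, 100))
  x <- c(3, 1, 4, 1, 5)
  expect_equal(rolling_mean(x, 1), x)
  # worked example: window 2 averages [i-1, i+1) -> (x[i-1] + x[i]) / 2
  expect_equal(rolling_mean(c(0, 4, 0, 0), 2), c(0, 2, 2, 0))
  set.seed(5)
  y <- rpois(500, 2)
  for (w in c(2, 3, 7, 64, 501))
    expect_equal(rolling_mean(y, w), brute_rolling_mean(y, w), info = w)
  expect_error(rolling_mean(y, 0), "window")
})

test_that("flat chromosomes produce an all-zero enrichment map", {
  z <- coverage_track(list(chr1 = rep(0, 3000)))
  expect_true(all(build_enrichment_map(z)$counts$chr1 == 0L))
  k <- coverage_track(list(chr1 = rep(4.2, 3000)))
  expect_true(all(build_enrichment_map(k)$counts$chr1 == 0L))
})

test_that("enrichment map equals the per-definition brute force", {
  trk <- plateau_track(10000, background = 0,
                       plateaus = list(c(4000, 4300, 10)))
  map <- build_enrichment_map(trk)
  expect_equal(map$counts$chr1, oracle_enrichment_map(trk$values$chr1))
  expect_true(all(map$counts$chr1 >= 0 & map$counts$chr1 <= 25))

  for (seed in 1:5) {
    rt <- random_poisson_track(20000, rate = 2, seed = seed)
    expect_identical(build_enrichment_map(rt)$counts$chr1,
                     oracle_enrichment_map(rt$values$chr1),
                     info = seed)
  }
})

test_that("map and candidates are scale invariant", {
  trk <- random_poisson_track(20000, rate = 2, seed = 9)
  base_map <- build_enrichment_map(trk)
  base_cand <- detect_candidates(trk)
  for (c in c(10, 1000)) {
    scaled <- coverage_track(list(chr1 = trk$values$chr1 * c))
    expect_identical(build_enrichment_map(scaled)$counts, base_map$counts)
    sc <- detect_candidates(scaled)
    expect_identical(sc[c("chrom", "start", "end", "n_definitions")],
                     base_cand[c("chrom", "start", "end", "n_definitions")])
  }
})

# build a fake map directly so run segmentation is tested in isolation
fake_map <- function(cnt) {
  structure(list(counts = list(chr1 = as.integer(cnt)),
                 n_definitions = 25L), class = "enrichment_map")
}

test_that("run extraction applies the size rules", {
  params <- enrichment_params()
  trk <- plateau_track(5000, background = 0,
                       plateaus = list(c(1000, 1300, 8)))
  expect_equal(nrow(extract_candidates(fake_map(rep(0, 5000)), trk, params)),
               0L)

  cnt <- rep(0, 5000); cnt[1001:1300] <- 6
  cand <- extract_candidates(fake_map(cnt), trk, params)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 1000)
  expect_equal(cand$end, 1300)
  expect_equal(cand$n_definitions, 5)
  expect_false(cand$saturated)
  expect_equal(cand$height, 8)

  cnt <- rep(0, 5000); cnt[1001:1030] <- 6   # 30 bp < minimum width
  expect_equal(nrow(extract_candidates(fake_map(cnt), trk, params)), 0L)
})

test_that("oversized runs are re-segmented recursively", {
  params <- enrichment_params()
  trk <- plateau_track(6000, background = 0)
  # one 3 kb run at concurrence 5 containing two 800 bp cores at 6
  cnt <- rep(0, 6000)
  cnt[1001:4000] <- 5
  cnt[1201:2000] <- 6
  cnt[2601:3400] <- 6
  cand <- extract_candidates(fake_map(cnt), trk, params)
  expect_equal(cand$start, c(1200, 2600))
  expect_equal(cand$end, c(2000, 3400))
  expect_equal(cand$n_definitions, c(6, 6))

  # a run stuck above 2 kb at every level is emitted saturated at 25
  cnt <- rep(0, 6000); cnt[1001:4000] <- 25
  cand <- extract_candidates(fake_map(cnt), trk, params)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$saturated)
  expect_equal(cand$end - cand$start, 3000)
  expect_equal(cand$n_definitions, 25)
})

test_that("candidates on simulated data are disjoint and within bounds", {
  sim <- simulate_track(simulation_config(chrom_length = 2e5, n_peaks = 30,
                                          n_noise = 40, seed = 3))
  cand <- detect_candidates(sim$track)
  expect_gt(nrow(cand), 0L)
  w <- cand$end - cand$start
  expect_true(all(w >= 50))
  expect_true(all(w <= 2000 | cand$saturated))
  expect_true(all(cand$n_definitions >= 5 & cand$n_definitions <= 25))
  by_chr <- split(cand, cand$chrom)
  for (b in by_chr) expect_true(all(diff(b$start) >= 0) &&
                                all(b$start[-1] >= b$end[-nrow(b)]))
})
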