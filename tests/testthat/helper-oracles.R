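# Independent oracles and fixture builders, deliberately implemented with
# different primitives than the production code (shift-and-add windows
# instead of cumulative sums; explicit per-definition loops).

# Centered rolling mean by summing shifted copies of the signal; edge
# windows shrink to the chromosome.
oracle_rolling_mean <- function(x, w) {
  n <- length(x)
  s <- numeric(n); cnt <- numeric(n)
  for (off in (-(w %/% 2)):((w + 1) %/% 2 - 1)) {
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    s[ok] <- s[ok] + x[src[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  s / cnt
}

# Tiny brute-force windowed mean: literal per-base mean() calls.
brute_rolling_mean <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(i - w %/% 2, 1L)
    hi <- min(i - 1L + (w + 1L) %/% 2, n)
    mean(x[lo:hi])
  }, numeric(1))
}

# Enrichment map by an explicit loop over all 25 (window, fold) pairs.
oracle_enrichment_map <- function(values, params = enrichment_params()) {
  m <- mean(values)
  cnt <- integer(length(values))
  for (w in params$window_sizes) {
    sm <- oracle_rolling_mean(values, w)
    for (f in params$folds) cnt <- cnt + as.integer(sm > f * m)
  }
  cnt
}

# A track with constant background plus rectangular plateaus; `plateaus`
# is a list of c(start, end, height) triples (0-based half-open).
plateau_track <- function(length, background = 1, plateaus = list(),
                          chrom = "chr1") {
  v <- rep(background, length)
  for (p in plateaus) v[(p[1] + 1):p[2]] <- p[3]
  coverage_track(stats::setNames(list(v), chrom))
}

# Integer-valued random track (Poisson background), exactly representable
# so scale invariance can be asserted bit-for-bit.
random_poisson_track <- function(length, rate = 2, seed = 1) {
  set.seed(seed)
  v <- as.numeric(stats::rpois(length, rate))
  coverage_track(list(chr1 = v))
}

# Truth labels of a simulation as an evaluate_calls() label frame.
truth_labels <- function(truth) {
  rbind(
    data.frame(chrom = truth$peak_regions$chrom,
               start = truth$peak_regions$start,
               end = truth$peak_regions$end, label = "peak",
               stringsAsFactors = FALSE),
    data.frame(chrom = truth$noise_regions$chrom,
               start = truth$noise_regions$start,
               end = truth$noise_regions$end, label = "noise",
               stringsAsFactors = FALSE))
}
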