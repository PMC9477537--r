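# Pseudocount used symmetrically in enrichment ratios and as the floor of
# the Poisson lambda in the input-control test.
PSEUDOCOUNT <- 0.1

# Backgrounds for the local enrichment measurements: 10..100 kb windows
# centered on the region midpoint, plus the whole chromosome (11 features).
BACKGROUND_SIZES <- seq(10000L, 100000L, by = 10000L)
SIGNAL_WINDOW_BP <- 2000L

#' Encode the 2 kb signal window of a region
#'
#' Extracts per-base coverage over the 2000 bp interval centered on the
#' region midpoint (`floor((start + end) / 2)`), padding with zeros beyond
#' chromosome ends, and divides by the maximum so the shape model sees a
#' depth-invariant profile. An all-zero window stays all-zero.
#'
#' @param track A [coverage_track()].
#' @param chrom,start,end A region on a track chromosome (0-based
#'   half-open).
#' @return Numeric vector of length 2000 with maximum 1 (or all zeros).
#' @export
encode_signal_window <- function(track, chrom, start, end) {
  mid <- (start + end) %/% 2
  w <- region_signal(track, chrom, mid - SIGNAL_WINDOW_BP %/% 2L,
                     mid + SIGNAL_WINDOW_BP %/% 2L)
  mx <- max(w)
  if (mx > 0) w <- w / mx
  w
}

#' Local enrichment measurements of a region
#'
#' Eleven ratios comparing the maximum coverage inside the region with its
#' surroundings: the mean coverage over windows of 10, 20, ..., 100 kb
#' centered on the region midpoint (clipped to the chromosome), then the
#' whole-chromosome mean. Each ratio carries a symmetric pseudocount of
#' 0.1, so a constant track gives exactly 1 everywhere.
#'
#' @inheritParams encode_signal_window
#' @return Numeric vector of 11 positive values, ordered 10 kb to 100 kb
#'   then chromosome-wide.
#' @export
enrichment_features <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  n <- length(v)
  if (start < 0 || end > n) stop("region out of chromosome bounds")
  peak_max <- max(v[(start + 1L):end])
  mid <- (start + end) %/% 2
  bg <- vapply(BACKGROUND_SIZES, function(b) {
    lo <- max(mid - b %/% 2L, 0L)
    hi <- min(mid + b %/% 2L, n)
    mean(v[(lo + 1L):hi])
  }, numeric(1))
  bg <- c(bg, mean(v))
  (peak_max + PSEUDOCOUNT) / (bg + PSEUDOCOUNT)
}

#' Poisson upper-tail test against an input control
#'
#' The observed statistic is the total treatment coverage in the region
#' (rounded to the nearest integer). The expectation is the total input
#' coverage in the region scaled by the chromosome-wide depth ratio
#' (treatment total / input total), floored at 0.1 to avoid a degenerate
#' zero-rate test. Returns `P(X >= observed)` for `X ~ Poisson(lambda)`.
#'
#' @param track Treatment [coverage_track()].
#' @param input_track Input-control [coverage_track()].
#' @inheritParams encode_signal_window
#' @return A p-value in (0, 1].
#' @export
pvalue_vs_input <- function(track, input_track, chrom, start, end) {
  tv <- track$values[[chrom]]
  iv <- input_track$values[[chrom]]
  if (is.null(tv) || is.null(iv))
    stop("region chromosome missing from treatment or input track")
  observed <- round(sum(tv[(start + 1L):end]))
  input_total <- sum(iv)
  if (input_total == 0) {
    warning("input chromosome total is zero; lambda floored at ",
            PSEUDOCOUNT, call. = FALSE)
    lambda <- PSEUDOCOUNT
  } else {
    depth_ratio <- sum(tv) / input_total
    lambda <- max(sum(iv[(start + 1L):end]) * depth_ratio, PSEUDOCOUNT)
  }
  stats::ppois(observed - 1, lambda, lower.tail = FALSE)
}

#' Extract model inputs for a set of regions
#'
#' Computes, for every region, the 2000-point encoded signal window and
#' the 11 local enrichment measurements; optionally the input-control
#' p-value.
#'
#' @param track A [coverage_track()].
#' @param regions A [genomic_regions()] data frame on track chromosomes.
#' @param input_track Optional input-control track; when supplied a
#'   `pvalue` vector is included.
#' @return A list of class `feature_bundles` with elements `signal`
#'   (n x 2000 matrix), `enrich` (n x 11 matrix), `regions`, and
#'   optionally `pvalue`.
#' @export
extract_features <- function(track, regions, input_track = NULL) {
  n <- nrow(regions)
  sig <- matrix(0, n, SIGNAL_WINDOW_BP)
  enr <- matrix(0, n, length(BACKGROUND_SIZES) + 1L)
  for (i in seq_len(n)) {
    sig[i, ] <- encode_signal_window(track, regions$chrom[i],
                                     regions$start[i], regions$end[i])
    enr[i, ] <- enrichment_features(track, regions$chrom[i],
                                    regions$start[i], regions$end[i])
  }
  out <- list(signal = sig, enrich = enr, regions = regions)
  if (!is.null(input_track)) {
    out$pvalue <- vapply(seq_len(n), function(i) {
      pvalue_vs_input(track, input_track, regions$chrom[i],
                      regions$start[i], regions$end[i])
    }, numeric(1))
  }
  structure(out, class = "feature_bundles")
}
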