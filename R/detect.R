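#' Parameters of the multi-scale enrichment detector
#'
#' The detector smooths the coverage with a rolling mean at five window
#' sizes and thresholds each smoothed signal at five fold enrichments over
#' the chromosome mean; every (window, fold) pair is one *definition of
#' enrichment*, 25 in total. Regions where at least `min_concurrence`
#' definitions agree become candidate peaks, subject to the size rules.
#'
#' @param window_sizes Rolling-mean window sizes in bp.
#' @param folds Fold-enrichment thresholds over the chromosome mean signal.
#' @param min_concurrence Minimum number of concurring definitions.
#' @param min_width,max_width Candidate width bounds in bp; regions wider
#'   than `max_width` are re-segmented recursively at a higher concurrence
#'   requirement, and only regions enriched under all definitions escape
#'   the upper bound.
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(window_sizes = c(100L, 200L, 400L, 800L, 1600L),
                              folds = c(2, 4, 8, 16, 32),
                              min_concurrence = 5L,
                              min_width = 50L,
                              max_width = 2000L) {
  if (any(window_sizes < 1)) stop("window sizes must be >= 1")
  if (any(folds <= 0)) stop("folds must be positive")
  if (min_width < 1 || max_width < min_width)
    stop("need 1 <= min_width <= max_width")
  n_def <- length(window_sizes) * length(folds)
  if (min_concurrence < 1 || min_concurrence > n_def)
    stop("min_concurrence must be in [1, number of definitions]")
  structure(list(window_sizes = as.integer(window_sizes),
                 folds = as.numeric(folds),
                 min_concurrence = as.integer(min_concurrence),
                 min_width = as.integer(min_width),
                 max_width = as.integer(max_width)),
            class = "enrichment_params")
}

#' Centered rolling mean with shrinking edge windows
#'
#' The value at 0-based position `i` is the mean of the signal over
#' `[i - floor(w/2), i + ceil(w/2))` intersected with the chromosome, so
#' windows shrink near the ends rather than padding with phantom zeros.
#'
#' @param signal Numeric vector of per-base values.
#' @param window Window size in bp (>= 1); `window = 1` is the identity.
#' @return Numeric vector of the same length.
#' @export
rolling_mean <- function(signal, window) {
  if (length(window) != 1L || is.na(window) || window < 1)
    stop("`window` must be a single value >= 1")
  window <- as.integer(window)
  n <- length(signal)
  if (n == 0L) stop("`signal` must be non-empty")
  cs <- c(0, cumsum(signal))
  i <- seq_len(n) - 1L                      # 0-based positions
  lo <- pmax(i - window %/% 2L, 0L)         # inclusive, 0-based
  hi <- pmin(i + (window + 1L) %/% 2L, n)   # exclusive
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Genome-wide map of concurring enrichment definitions
#'
#' For every base the map records how many of the 25 (window, fold)
#' definitions are satisfied: a base satisfies a definition when the
#' rolling mean of the coverage at that window size strictly exceeds
#' `fold * mean(chromosome signal)`. Fold thresholds are relative, so the
#' map is invariant to rescaling the track.
#'
#' @param track A [coverage_track()].
#' @param params An [enrichment_params()].
#' @return A list of class `enrichment_map`: one integer vector per
#'   chromosome, values in `[0, n_definitions]`.
#' @export
build_enrichment_map <- function(track, params = enrichment_params()) {
  stopifnot(inherits(track, "CoverageTrack"),
            inherits(params, "enrichment_params"))
  maps <- lapply(track$values, function(v) {
    m <- mean(v)
    cnt <- integer(length(v))
    for (w in params$window_sizes) {
      sm <- rolling_mean(v, w)
      for (f in params$folds) cnt <- cnt + (sm > f * m)
    }
    cnt
  })
  structure(list(counts = maps,
                 n_definitions = length(params$window_sizes) *
                                 length(params$folds)),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat("enrichment_map:", length(x$counts), "chromosome(s),",
      x$n_definitions, "definitions\n")
  invisible(x)
}

# Maximal runs of cnt >= level, as a 2-column matrix of 0-based
# half-open [start, end) pairs.
runs_at_level <- function(cnt, level) {
  r <- rle(cnt >= level)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Extract candidate peaks from an enrichment map
#'
#' Maximal runs of bases with at least `min_concurrence` concurring
#' definitions form the initial regions. Runs narrower than `min_width`
#' are discarded; runs within `[min_width, max_width]` are emitted; wider
#' runs are re-segmented within their own extent with the concurrence
#' requirement raised by one, recursing until the size rule is met or the
#' requirement reaches the total number of definitions, at which point the
#' run is emitted regardless of size and flagged `saturated`.
#'
#' @param map An [build_enrichment_map()] result.
#' @param track The matching [coverage_track()] (used for peak heights).
#' @param params The [enrichment_params()] used to build the map.
#' @return A [genomic_regions()] data frame with columns `n_definitions`
#'   (the requirement at emission), `saturated`, and `height` (maximum
#'   coverage within the region); disjoint and sorted.
#' @export
extract_candidates <- function(map, track, params = enrichment_params()) {
  stopifnot(inherits(map, "enrichment_map"),
            inherits(track, "CoverageTrack"))
  if (!identical(names(map$counts), chrom_names(track)))
    stop("map and track cover different chromosomes")
  n_def <- map$n_definitions
  out <- list()
  for (chrom in names(map$counts)) {
    cnt <- map$counts[[chrom]]
    v <- track$values[[chrom]]
    acc <- new.env(parent = emptyenv()); acc$rows <- list()
    segment <- function(start, end, level) {
      segs <- runs_at_level(cnt[(start + 1L):end], level)
      for (k in seq_len(nrow(segs))) {
        a <- start + segs[k, 1L]; b <- start + segs[k, 2L]
        wd <- b - a
        if (wd < params$min_width) next
        if (wd <= params$max_width || level >= n_def) {
          acc$rows[[length(acc$rows) + 1L]] <-
            list(start = a, end = b, level = level,
                 saturated = level >= n_def,
                 height = max(v[(a + 1L):b]))
        } else {
          segment(a, b, level + 1L)
        }
      }
    }
    segment(0L, length(cnt), params$min_concurrence)
    if (length(acc$rows)) {
      rows <- acc$rows
      df <- genomic_regions(
        chrom = rep(chrom, length(rows)),
        start = vapply(rows, `[[`, numeric(1), "start"),
        end   = vapply(rows, `[[`, numeric(1), "end"),
        n_definitions = vapply(rows, `[[`, numeric(1), "level"),
        saturated = vapply(rows, `[[`, logical(1), "saturated"),
        height = vapply(rows, `[[`, numeric(1), "height"))
      out[[chrom]] <- df[order(df$start), , drop = FALSE]
    }
  }
  if (!length(out))
    return(genomic_regions(character(0), numeric(0), numeric(0) + 1,
                           n_definitions = numeric(0),
                           saturated = logical(0),
                           height = numeric(0))[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("genomic_regions", "data.frame")
  res
}

#' Run candidate detection on a track
#'
#' Convenience wrapper: builds the enrichment map and extracts candidates.
#'
#' @inheritParams build_enrichment_map
#' @return See [extract_candidates()].
#' @export
detect_candidates <- function(track, params = enrichment_params()) {
  extract_candidates(build_enrichment_map(track, params), track, params)
}
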