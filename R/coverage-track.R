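#' Per-base coverage track
#'
#' A `CoverageTrack` holds strandless per-base read-overlap depth for a set of
#' chromosomes: one non-negative numeric vector per chromosome, with the
#' vector length equal to the declared chromosome length. It is the common
#' currency of the package: the simulator produces one, the candidate
#' detector and the feature extractor consume one.
#'
#' @param values Named list of numeric vectors, one per chromosome, each
#'   value the coverage at that base (0-based position `i` is element
#'   `i + 1`).
#' @return An object of class `CoverageTrack`.
#' @examples
#' trk <- coverage_track(list(chr1 = c(0, 0, 3, 3, 1)))
#' chrom_lengths(trk)
#' @export
coverage_track <- function(values) {
  if (!is.list(values) || is.null(names(values)) || any(names(values) == ""))
    stop("`values` must be a named list of per-chromosome numeric vectors")
  if (anyDuplicated(names(values)))
    stop("chromosome names must be unique")
  values <- lapply(values, function(v) {
    v <- as.numeric(v)
    if (length(v) == 0L) stop("chromosome length must be positive")
    if (anyNA(v)) stop("coverage values must not be NA")
    if (any(v < 0)) stop("coverage values must be non-negative")
    v
  })
  structure(list(values = values), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  len <- chrom_lengths(x)
  cat("CoverageTrack with", length(len), "chromosome(s)\n")
  for (nm in names(len)) {
    v <- x$values[[nm]]
    cat(sprintf("  %s: %d bp, mean %.4g, max %.4g\n",
                nm, len[[nm]], mean(v), max(v)))
  }
  invisible(x)
}

#' Chromosome names and lengths of a track
#' @param track A [coverage_track()].
#' @return `chrom_names()`: character vector; `chrom_lengths()`: named
#'   integer vector of base-pair lengths.
#' @export
chrom_names <- function(track) names(track$values)

#' @rdname chrom_names
#' @export
chrom_lengths <- function(track) {
  vapply(track$values, length, integer(1))
}

#' Genomic regions as plain data frames
#'
#' Regions are 0-based half-open intervals (`start` inclusive, `end`
#' exclusive), the native convention of BED and bigWig. A region set is a
#' data frame with at least columns `chrom`, `start`, `end`; extra columns
#' are carried along untouched.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like coordinates, `0 <= start < end`.
#' @param ... Further equal-length columns (e.g. labels, scores).
#' @return A `data.frame` with class `c("genomic_regions", "data.frame")`.
#' @export
genomic_regions <- function(chrom, start, end, ...) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal length")
  if (length(start) && (anyNA(start) || anyNA(end)))
    stop("region coordinates must not be NA")
  if (any(start < 0)) stop("region start must be >= 0")
  if (any(start >= end)) stop("region start must be < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   ..., stringsAsFactors = FALSE)
  class(df) <- c("genomic_regions", "data.frame")
  df
}

# Check that every region lies on a track chromosome within bounds.
# Returns the subset that does; warns about (and counts) the rest.
validate_regions <- function(regions, track, action = c("error", "skip")) {
  action <- match.arg(action)
  len <- chrom_lengths(track)
  on_track <- regions$chrom %in% names(len)
  in_bounds <- on_track
  in_bounds[on_track] <-
    regions$end[on_track] <= len[regions$chrom[on_track]]
  bad <- !(on_track & in_bounds)
  if (any(bad)) {
    msg <- sprintf("%d region(s) off the track's chromosomes or out of bounds",
                   sum(bad))
    if (action == "error") stop(msg)
    warning(msg, call. = FALSE)
  }
  regions[!bad, , drop = FALSE]
}

# Extract per-base coverage over [start, end) (0-based half-open);
# positions beyond the chromosome contribute 0.
region_signal <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  n <- length(v)
  out <- numeric(end - start)
  lo <- max(start, 0L); hi <- min(end, n)
  if (hi > lo) out[(lo - start + 1L):(hi - start)] <- v[(lo + 1L):hi]
  out
}
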