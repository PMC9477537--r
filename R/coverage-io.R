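# Track and interval IO. bigWig and bedGraph parsing is delegated to
# rtracklayer; the per-base materialization on top is ours. BED-like peak
# tables are written with a fixed column contract (below) so they
# round-trip byte-identically.

granges_to_track <- function(gr, lengths) {
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) {
    if (length(gr)) stop("track file has no score column")
    score <- numeric(0)
    S4Vectors::mcols(gr)$score <- score
  }
  if (any(score < 0)) stop("negative coverage value in track file")
  values <- list()
  for (chrom in names(lengths)) {
    L <- as.integer(lengths[[chrom]])
    sel <- gr[GenomeInfoDb::seqnames(gr) == chrom]
    v <- numeric(L)
    if (length(sel)) {
      s <- pmax(BiocGenerics::start(sel) - 1L, 0L)  # back to 0-based
      e <- pmin(BiocGenerics::end(sel), L)
      sc <- S4Vectors::mcols(sel)$score
      for (i in seq_along(sel))
        if (e[i] > s[i]) v[(s[i] + 1L):e[i]] <- sc[i]
    }
    values[[chrom]] <- v
  }
  coverage_track(values)
}

guess_format <- function(path) {
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "bigwig"
  else if (grepl("\\.(bg|bedgraph)$", path, ignore.case = TRUE)) "bedgraph"
  else stop("cannot guess track format from extension: ", path)
}

#' Read a coverage track
#'
#' bigWig files carry chromosome lengths in their header; bedGraph files
#' do not, so either supply `chrom_lengths` or the length of each
#' chromosome is inferred as the largest end coordinate seen. Bases absent
#' from the file have coverage 0.
#'
#' @param path Track file.
#' @param format `"bigwig"`, `"bedgraph"`, or `"auto"` (by extension).
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   chromosomes named here but absent from a bedGraph come back all-zero.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, format = c("auto", "bigwig", "bedgraph"),
                          chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "bigwig") {
    gr <- rtracklayer::import(path, format = "BigWig")
    lengths <- GenomeInfoDb::seqlengths(gr)
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!is.null(chrom_lengths)) {
      lengths <- chrom_lengths
    } else {
      lengths <- tapply(BiocGenerics::end(gr),
                        as.character(GenomeInfoDb::seqnames(gr)), max)
      lengths <- lengths[unique(as.character(GenomeInfoDb::seqnames(gr)))]
      if (!length(lengths))
        stop("empty bedGraph and no `chrom_lengths` supplied")
    }
  }
  granges_to_track(gr, as.list(lengths))
}

#' Write a coverage track
#'
#' bedGraph output collapses runs of equal coverage and omits zero runs
#' (absent means 0); values are printed with enough digits to round-trip.
#' bigWig output goes through rtracklayer and stores 32-bit floats.
#'
#' @param track A [coverage_track()].
#' @param path Output file.
#' @param format `"bedgraph"` or `"bigwig"`.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path, format = c("bedgraph", "bigwig")) {
  format <- match.arg(format)
  lengths <- chrom_lengths(track)
  if (format == "bedgraph") {
    con <- file(path, "w"); on.exit(close(con))
    for (chrom in names(lengths)) {
      r <- rle(track$values[[chrom]])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep))
        writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, starts[keep],
                           ends[keep], r$values[keep]), con)
    }
  } else {
    grl <- lapply(names(lengths), function(chrom) {
      r <- rle(track$values[[chrom]])
      ends <- cumsum(r$lengths)
      GenomicRanges::GRanges(chrom,
                             IRanges::IRanges(ends - r$lengths + 1L, ends),
                             score = r$values)
    })
    gr <- do.call(c, grl)
    GenomeInfoDb::seqlengths(gr) <- lengths[GenomeInfoDb::seqlevels(gr)]
    rtracklayer::export(gr, path, format = "BigWig")
  }
  invisible(path)
}

#' Read a BED3+ region file
#'
#' Reads 0-based half-open intervals; columns beyond the first three are
#' kept but not interpreted (column 4, when present, is named `name`).
#'
#' @param path BED file.
#' @return A [genomic_regions()] data frame in file order.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(genomic_regions(character(0), numeric(0), numeric(0)))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "", fill = TRUE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop("BED coordinates must be numeric")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("invalid BED interval: need 0 <= start < end")
  class(df) <- c("genomic_regions", "data.frame")
  df
}

# Fixed column contract for scored peak files (tab-separated, no header):
#   chrom start end peak_score shape_score enrichment_score height
#   [pvalue] [pass]
# Scores and height use fixed 4-decimal notation; p-values use scientific
# notation (always containing an 'e', which is how readers tell the
# optional columns apart); pass is 0/1.
PEAK_COLS <- c("chrom", "start", "end", "peak_score", "shape_score",
               "enrichment_score", "height")

#' Write and read scored peak calls
#'
#' @param peaks Data frame with the columns above, plus optional `pvalue`
#'   and `pass`; must be sorted by chromosome block and start.
#' @param path Output / input file.
#' @return `read_peaks()` returns the data frame; `write_peaks()` the
#'   path, invisibly. An empty peak set writes an empty file.
#' @export
write_peaks <- function(peaks, path) {
  if (!all(PEAK_COLS %in% names(peaks)))
    stop("peaks must have columns: ", paste(PEAK_COLS, collapse = ", "))
  n <- nrow(peaks)
  if (n > 1L) {
    blocks <- rle(peaks$chrom)$values
    if (anyDuplicated(blocks))
      stop("peaks must be grouped by chromosome")
    if (any(unlist(tapply(peaks$start, factor(peaks$chrom, levels = blocks),
                          function(s) diff(s) < 0))))
      stop("peaks must be sorted by start within each chromosome")
  }
  lines <- character(n)
  if (n) {
    lines <- sprintf("%s\t%d\t%d\t%.4f\t%.4f\t%.4f\t%.4f",
                     peaks$chrom, as.integer(peaks$start),
                     as.integer(peaks$end), peaks$peak_score,
                     peaks$shape_score, peaks$enrichment_score, peaks$height)
    if (!is.null(peaks$pvalue) && !all(is.na(peaks$pvalue)))
      lines <- paste(lines, sprintf("%.4e", peaks$pvalue), sep = "\t")
    if (!is.null(peaks$pass))
      lines <- paste(lines, as.integer(peaks$pass), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_score = numeric(0),
                      shape_score = numeric(0),
                      enrichment_score = numeric(0), height = numeric(0))
  if (file.size(path) == 0L) return(empty)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  df[[1]] <- as.character(df[[1]])
  nc <- ncol(df)
  nm <- PEAK_COLS
  if (nc == 8L) {
    raw <- readLines(path, 1L)
    f8 <- strsplit(raw, "\t")[[1]][8]
    nm <- c(nm, if (grepl("e", f8, fixed = TRUE)) "pvalue" else "pass")
  } else if (nc == 9L) {
    nm <- c(nm, "pvalue", "pass")
  } else if (nc != 7L) {
    stop("unrecognized peak file layout (", nc, " columns)")
  }
  names(df) <- nm
  if (!is.null(df$pass)) df$pass <- df$pass == 1
  df
}
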