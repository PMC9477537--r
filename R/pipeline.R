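# The three operating modes. Each accepts in-memory objects or file
# paths (tracks by path go through read_coverage, models through
# load_model), so the CLI wrappers stay thin.

as_track <- function(x, chrom_lengths = NULL) {
  if (inherits(x, "CoverageTrack")) return(x)
  read_coverage(x, chrom_lengths = chrom_lengths)
}

as_model <- function(x) {
  if (inherits(x, "peak_model")) return(x)
  if (!dir.exists(x))
    stop("model bundle not found at '", x,
         "'; train one with train_peak_model()/`peakshaper train` ",
         "or point --model at an existing bundle directory")
  load_model(x)
}

#' Find and score peaks
#'
#' The full pipeline: enrichment map, candidate extraction, feature
#' encoding, wide-and-deep scoring. Every candidate is returned with its
#' scores; `threshold` only sets the `pass` flag, so downstream filtering
#' stays in the user's hands.
#'
#' @param track A [coverage_track()] or a track file path.
#' @param model A `peak_model` or a model bundle directory.
#' @param threshold Peak-Score cutoff used for the `pass` column.
#' @param params Detector [enrichment_params()].
#' @param input_track Optional input-control track (or path); adds a
#'   `pvalue` column from the Poisson upper-tail test.
#' @param out Optional output file; when given the calls are also written
#'   with [write_peaks()].
#' @param chrom_lengths Passed to [read_coverage()] for bedGraph paths.
#' @return Data frame of scored candidates (sorted, disjoint), with
#'   columns `chrom`, `start`, `end`, `peak_score`, `shape_score`,
#'   `enrichment_score`, `height`, `n_definitions`, `saturated`,
#'   optionally `pvalue`, and `pass`.
#' @export
call_peaks <- function(track, model, threshold = 0.5,
                       params = enrichment_params(), input_track = NULL,
                       out = NULL, chrom_lengths = NULL) {
  track <- as_track(track, chrom_lengths)
  model <- as_model(model)
  if (!is.null(input_track)) {
    input_track <- as_track(input_track, chrom_lengths)
    mism <- union(setdiff(chrom_names(track), chrom_names(input_track)),
                  setdiff(chrom_names(input_track), chrom_names(track)))
    if (length(mism))
      stop("treatment and input tracks disagree on chromosomes: ",
           paste(mism, collapse = ", "))
    if (!identical(chrom_lengths(track)[chrom_names(track)],
                   chrom_lengths(input_track)[chrom_names(track)]))
      stop("treatment and input tracks disagree on chromosome lengths")
  }
  cand <- detect_candidates(track, params)
  feats <- extract_features(track, cand, input_track = input_track)
  scores <- score_features(model, feats)
  res <- cbind(cand[, c("chrom", "start", "end"), drop = FALSE],
               scores[, c("peak_score", "shape_score", "enrichment_score"),
                      drop = FALSE],
               height = cand$height,
               n_definitions = cand$n_definitions,
               saturated = cand$saturated)
  if (!is.null(input_track)) res$pvalue <- feats$pvalue
  res$pass <- !is.na(res$peak_score) & res$peak_score >= threshold
  rownames(res) <- NULL
  if (!is.null(out)) write_peaks(res, out)
  res
}

#' Score user-supplied regions
#'
#' No candidate detection: each region of the BED (or region data frame)
#' is featurized and scored as-is, in input order, with the original
#' columns retained. Regions off the track's chromosomes are skipped with
#' a warning.
#'
#' @param track A [coverage_track()] or track file path.
#' @param regions A [genomic_regions()] data frame or a BED file path.
#' @inheritParams call_peaks
#' @return The input regions (off-track rows dropped) with score columns
#'   appended, plus `height` and optionally `pvalue`.
#' @export
score_bed <- function(track, regions, model, input_track = NULL,
                      out = NULL, chrom_lengths = NULL) {
  track <- as_track(track, chrom_lengths)
  model <- as_model(model)
  if (is.character(regions)) regions <- read_regions(regions)
  regions <- validate_regions(regions, track, action = "skip")
  if (!is.null(input_track)) input_track <- as_track(input_track, chrom_lengths)
  feats <- extract_features(track, regions, input_track = input_track)
  scores <- score_features(model, feats)
  res <- cbind(as.data.frame(regions), scores)
  res$height <- vapply(seq_len(nrow(regions)), function(i) {
    max(region_signal(track, regions$chrom[i], regions$start[i],
                      regions$end[i]))
  }, numeric(1))
  if (!is.null(input_track)) res$pvalue <- feats$pvalue
  rownames(res) <- NULL
  if (!is.null(out)) {
    ord <- res
    utils::write.table(ord, out, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  res
}
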