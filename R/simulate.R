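#' Configuration for the synthetic coverage simulator
#'
#' The simulator builds coverage by summing fragment pileups: background
#' fragment midpoints fall uniformly at a rate of
#' `background_rate / fragment_length` per bp (so the expected background
#' coverage is `background_rate`), and each planted peak receives extra
#' fragments bringing its mean coverage to `fold` times background.
#' Punctate peaks draw fragment midpoints from a Normal centered on the
#' summit (sd = width / 4), giving the summit-and-shoulders profile of
#' transcription-factor binding; broad peaks draw midpoints uniformly over
#' the interval, giving histone-mark-like plateaus.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param background_rate Mean background coverage in reads per bp.
#' @param n_peaks Total number of planted peaks.
#' @param peak_width_range `(min, max)` peak width in bp.
#' @param fold_range `(min, max)` fold enrichment over background; min > 1.
#' @param fragment_length Sequenced-fragment length in bp.
#' @param shape_mix Fraction of punctate (vs broad) peaks in `[0, 1]`.
#' @param n_noise Number of truth noise regions to sample away from peaks.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chroms = 1L,
                              chrom_length = 1e6,
                              background_rate = 1.0,
                              n_peaks = 200L,
                              peak_width_range = c(150L, 800L),
                              fold_range = c(5, 20),
                              fragment_length = 150L,
                              shape_mix = 0.5,
                              n_noise = 2L * n_peaks,
                              seed = 1L) {
  stopifnot(n_chroms >= 1, chrom_length > 0, background_rate > 0,
            n_peaks >= 0, fragment_length >= 1,
            shape_mix >= 0, shape_mix <= 1, n_noise >= 0)
  if (any(peak_width_range <= 0) || peak_width_range[1] > peak_width_range[2])
    stop("peak_width_range must be positive and ordered")
  if (fold_range[1] <= 1 || fold_range[1] > fold_range[2])
    stop("fold_range min must be > 1 and <= max")
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              background_rate = background_rate,
              n_peaks = as.integer(n_peaks),
              peak_width_range = as.integer(peak_width_range),
              fold_range = as.numeric(fold_range),
              fragment_length = as.integer(fragment_length),
              shape_mix = shape_mix,
              n_noise = as.integer(n_noise),
              seed = as.integer(seed))
  # feasibility: each peak needs its width plus a 2 kb gap on either side
  need <- cfg$n_peaks * (cfg$peak_width_range[2] + 2000) + 2000
  if (cfg$n_peaks > 0 && need > cfg$n_chroms * cfg$chrom_length)
    stop("infeasible placement: too many peaks for the genome size")
  structure(cfg, class = "simulation_config")
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# Add +1 coverage over [start, end) (0-based, clipped to [0, L)) for each
# fragment, via a difference array.
pileup <- function(starts, ends, L) {
  starts <- pmax(pmin(starts, L), 0L)
  ends <- pmax(pmin(ends, L), 0L)
  keep <- ends > starts
  d <- numeric(L + 1L)
  add <- tabulate(starts[keep] + 1L, nbins = L + 1L)
  sub <- tabulate(ends[keep] + 1L, nbins = L + 1L)
  cumsum(add - sub)[seq_len(L)]
}

# Place k disjoint intervals of the given widths on [0, L) with >= `gap`
# bp between them and to the chromosome ends; the spare space is spread
# over the gaps at random.
place_intervals <- function(widths, L, gap = 2000L) {
  k <- length(widths)
  if (k == 0L) return(cbind(start = integer(0), end = integer(0)))
  slack <- L - sum(widths) - (k + 1L) * gap
  if (slack < 0) stop("infeasible placement: too many peaks for the genome size")
  u <- stats::runif(k + 1L)
  extra <- floor(slack * u / sum(u))
  starts <- integer(k); pos <- 0L
  for (i in seq_len(k)) {
    pos <- pos + gap + extra[i]
    starts[i] <- pos
    pos <- pos + widths[i]
  }
  cbind(start = starts, end = starts + widths)
}

#' Simulate a coverage track with planted peaks and truth labels
#'
#' @param config A [simulation_config()].
#' @return A list with elements `track` (a [coverage_track()]) and `truth`
#'   (class `synthetic_truth`: `peak_regions` with per-peak `fold` and
#'   `shape` columns, and `noise_regions`, disjoint from the peaks).
#' @export
simulate_track <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    L <- config$chrom_length
    fl <- config$fragment_length
    chroms <- paste0("chr", seq_len(config$n_chroms))
    # spread peaks over chromosomes as evenly as possible
    per_chrom <- diff(floor(seq(0, config$n_peaks,
                                length.out = config$n_chroms + 1L)))
    values <- list(); peak_rows <- list(); noise_rows <- list()
    for (ci in seq_along(chroms)) {
      k <- per_chrom[ci]
      widths <- if (k) as.integer(round(stats::runif(
        k, config$peak_width_range[1], config$peak_width_range[2]))) else integer(0)
      folds <- if (k) stats::runif(k, config$fold_range[1],
                                   config$fold_range[2]) else numeric(0)
      shapes <- if (k) ifelse(stats::runif(k) < config$shape_mix,
                              "punctate", "broad") else character(0)
      loc <- place_intervals(widths, L)
      # background fragments
      n_bg <- stats::rpois(1L, config$background_rate * L / fl)
      mids <- stats::runif(n_bg, 0, L)
      # extra peak fragments bring mean in-peak coverage to fold x background
      for (i in seq_len(k)) {
        n_extra <- stats::rpois(
          1L, (folds[i] - 1) * config$background_rate * widths[i] / fl)
        pm <- if (shapes[i] == "punctate") {
          summit <- (loc[i, "start"] + loc[i, "end"]) / 2
          stats::rnorm(n_extra, summit, widths[i] / 4)
        } else {
          stats::runif(n_extra, loc[i, "start"], loc[i, "end"])
        }
        mids <- c(mids, pm)
      }
      frag_start <- as.integer(floor(mids - fl / 2))
      values[[chroms[ci]]] <- pileup(frag_start, frag_start + fl, L)
      if (k) {
        peak_rows[[ci]] <- data.frame(chrom = chroms[ci],
                                      start = loc[, "start"],
                                      end = loc[, "end"],
                                      fold = folds, shape = shapes,
                                      stringsAsFactors = FALSE)
      }
      # noise regions: same width law, rejection-sampled >= 1 kb from any
      # peak and disjoint from each other
      n_noise_here <- diff(floor(seq(0, config$n_noise,
                                     length.out = config$n_chroms + 1L)))[ci]
      if (n_noise_here > 0) {
        taken <- if (k) cbind(pmax(loc[, "start"] - 1000L, 0L),
                              pmin(loc[, "end"] + 1000L, L))
                 else cbind(integer(0), integer(0))
        got <- 0L; tries <- 0L; ns <- integer(0); ne <- integer(0)
        while (got < n_noise_here && tries < 50L * n_noise_here) {
          tries <- tries + 1L
          w <- as.integer(round(stats::runif(1, config$peak_width_range[1],
                                             config$peak_width_range[2])))
          s <- as.integer(floor(stats::runif(1, 0, L - w)))
          if (!any(s < taken[, 2] & s + w > taken[, 1])) {
            taken <- rbind(taken, c(s, s + w))
            ns <- c(ns, s); ne <- c(ne, s + w); got <- got + 1L
          }
        }
        if (got < n_noise_here)
          stop("could not place the requested noise regions; genome too full")
        noise_rows[[ci]] <- data.frame(chrom = chroms[ci], start = ns,
                                       end = ne, stringsAsFactors = FALSE)
      }
    }
    peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 fold = numeric(0), shape = character(0))
    noise <- if (length(noise_rows)) do.call(rbind, noise_rows) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    class(peaks) <- c("genomic_regions", "data.frame")
    class(noise) <- c("genomic_regions", "data.frame")
    list(track = coverage_track(values),
         truth = structure(list(peak_regions = peaks, noise_regions = noise),
                           class = "synthetic_truth"))
  })
}

#' Build a balanced labeled training set from synthetic truth
#'
#' All truth peaks become positives and an equal number of noise regions
#' (taken in order) become negatives.
#'
#' @param track The simulated [coverage_track()].
#' @param truth The matching `synthetic_truth`.
#' @return A [genomic_regions()] data frame with a `label` column in
#'   `{"peak", "noise"}`; empty when there are no truth peaks.
#' @export
make_training_set <- function(track, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  peaks <- validate_regions(truth$peak_regions, track, "error")
  noise <- validate_regions(truth$noise_regions, track, "error")
  npos <- nrow(peaks)
  if (npos == 0L)
    return(genomic_regions(character(0), numeric(0), numeric(0),
                           label = character(0)))
  if (nrow(noise) < npos)
    stop("fewer noise regions than peaks; cannot balance the training set")
  noise <- noise[seq_len(npos), , drop = FALSE]
  out <- rbind(
    data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
               label = "peak", stringsAsFactors = FALSE),
    data.frame(chrom = noise$chrom, start = noise$start, end = noise$end,
               label = "noise", stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("genomic_regions", "data.frame")
  out
}
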