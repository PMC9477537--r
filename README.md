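# peakshaper

Peak calling for coverage tracks from ChIP-seq, ATAC-seq and DNase-seq
experiments, for analysts who want every enriched region back with a
probability attached rather than a hard-thresholded call set.

peakshaper separates peak calling into two stages:

1. **Candidate detection** — a deterministic multi-scale scan. Coverage is
   smoothed with rolling means at window sizes *w* ∈ {100, 200, 400, 800,
   1600} bp; a base is enriched under definition (*w*, *f*) when its
   smoothed coverage exceeds *f* · mean(chromosome coverage) for fold
   thresholds *f* ∈ {2, 4, 8, 16, 32}. The per-base count of the 25
   concurring definitions forms a genome-wide enrichment map; maximal runs
   with ≥ 5 definitions become candidates, subject to 50 bp ≤ width ≤ 2 kb
   with recursive re-segmentation of wider runs (regions enriched under
   all 25 definitions escape the ceiling as *saturated*).
2. **Wide-and-deep scoring** — for each candidate, a 1-D CNN reads the
   max-normalized 2000-point coverage window and returns a *shape score*;
   a logistic regression over 11 local enrichment measurements
   (max-in-region vs mean of 10–100 kb backgrounds and the whole
   chromosome) returns an *enrichment score*; a small MLP combines both
   with the 11 measurements into the **Peak Score**
   P(signal arises from a biological event) ∈ [0, 1].

With a matched input-control track, each region also receives a Poisson
upper-tail p-value on depth-normalized counts. A synthetic-data module
simulates fragment-pileup coverage with planted punctate/broad peaks and
truth labels, so training, benchmarking and the tests run with no
external data. See `vignettes/peakshaper-methods.Rmd` for the model,
its assumptions, and known limitations.

## Worked example

```r
library(peakshaper)

# a 200 kb synthetic genome: 30 planted peaks (folds 5-20) over
# Poisson-fragment background at 1 read/bp
sim <- simulate_track(simulation_config(chrom_length = 2e5, n_peaks = 30,
                                        n_noise = 60, seed = 7))
sim$track
#> CoverageTrack with 1 chromosome(s)
#>   chr1: 200000 bp, mean 1.913, max 35

train <- make_training_set(sim$track, sim$truth)     # 30 peaks + 30 noise
feats <- extract_features(sim$track, train)
model <- train_peak_model(feats, train$label, seed = 1, epochs = 60)

calls <- call_peaks(sim$track, model, threshold = 0.5)
head(calls[, c("chrom", "start", "end", "peak_score", "shape_score",
               "enrichment_score", "height", "pass")], 4)
#>   chrom start   end peak_score shape_score enrichment_score height pass
#> 1  chr1  4801  5672  0.9965495   0.9993123                1     24 TRUE
#> 2  chr1  7618  8013  0.9934626   0.9979868                1     16 TRUE
#> 3  chr1 21087 21231  0.9880169   0.9374783                1     13 TRUE
#> 4  chr1 29112 29378  0.9941826   0.9937280                1     19 TRUE
```

Every candidate is returned with its scores; `threshold` only sets the
`pass` flag. `peak_score` near 1 means the region both *looks* like a
peak (shape score) and *towers over* its 10–100 kb surroundings
(enrichment score, here saturated at 1.00 for strongly separable planted
peaks); `height` is the maximum coverage inside the call. Evaluating
against the simulation's truth labels:

```r
labels <- rbind(
  cbind(sim$truth$peak_regions[c("chrom", "start", "end")], label = "peak"),
  cbind(sim$truth$noise_regions[c("chrom", "start", "end")], label = "noise"))
evaluate_calls(calls, labels)
#> evaluation at Peak Score >= 0.50
#>   TP 27  FP 0  TN 60  FN 3
#>   precision 1.0000  recall 0.9000  selectivity 1.0000  F1 0.9474
```

The three misses are low-fold broad peaks below the detector's
concurrence floor in this peak-dense toy genome (discussed in the
vignette); no noise region is called.

## Command line

The same pipeline is exposed as subcommands (installed at
`exec/peakshaper`, or call `peakshaper_cli()` from R):

```sh
peakshaper simulate --out world --seed 33            # synthetic track + truth
peakshaper train --track world/track.bedgraph \
                 --labels world/labels.bed --out world/model
peakshaper call world/track.bedgraph --model world/model --out calls.bed
peakshaper call-with-input treat.bw --input input.bw --model world/model
peakshaper score world/track.bedgraph --bed regions.bed --model world/model
peakshaper eval --calls calls.bed --labels world/truth_peaks.bed
```

bigWig and bedGraph tracks are accepted; output is a tab-separated
BED3+ table (`chrom start end peak_score shape_score enrichment_score
height [pvalue] pass`). All randomness is funneled through `--seed`.

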