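# Numerical gradient check of the hand-written backprop: central
# differences on the binary cross-entropy loss, parameter by parameter.
numeric_grad <- function(fwd, params, X, y, keys = names(params),
                         eps = 1e-5) {
  out <- list()
  for (k in keys) {
    g <- params[[k]] * 0
    for (i in seq_along(params[[k]])) {
      up <- params; up[[k]][i] <- up[[k]][i] + eps
      dn <- params; dn[[k]][i] <- dn[[k]][i] - eps
      g[i] <- (peakshaper:::bce_loss(fwd(up, X), y) -
               peakshaper:::bce_loss(fwd(dn, X), y)) / (2 * eps)
    }
    out[[k]] <- g
  }
  out
}

test_that("CNN and MLP backprop match numerical gradients", {
  set.seed(42)
  X <- matrix(runif(6 * 2000), 6, 2000)
  y <- c(1, 0, 1, 1, 0, 0)
  params <- peakshaper:::with_seed(1, peakshaper:::shape_init_params())
  cache <- peakshaper:::shape_forward(params, X, cache = TRUE)
  ana <- peakshaper:::shape_backward(params, cache, y)
  num <- numeric_grad(function(p, X) peakshaper:::shape_forward(p, X),
                      params, X, y, keys = c("W4", "b4", "b2", "b1"))
  # spot-check the dense head exhaustively and the conv biases
  for (k in c("W4", "b4", "b2", "b1"))
    expect_equal(as.numeric(ana[[k]]), as.numeric(num[[k]]),
                 tolerance = 1e-5, info = k)
  # a handful of conv weights by direct perturbation
  for (idx in c(1, 5, 9)) {
    up <- params; up$W1[1, idx] <- up$W1[1, idx] + 1e-5
    dn <- params; dn$W1[1, idx] <- dn$W1[1, idx] - 1e-5
    g <- (peakshaper:::bce_loss(peakshaper:::shape_forward(up, X), y) -
          peakshaper:::bce_loss(peakshaper:::shape_forward(dn, X), y)) / 2e-5
    expect_equal(ana$W1[1, idx], g, tolerance = 1e-4)
  }

  Xm <- matrix(rnorm(8 * 13), 8, 13)
  ym <- rep(c(0, 1), 4)
  pm <- peakshaper:::with_seed(2, peakshaper:::mlp_init_params(13L))
  cm <- peakshaper:::mlp_forward(pm, Xm, cache = TRUE)
  am <- peakshaper:::mlp_backward(pm, cm, ym)
  nm <- numeric_grad(function(p, X) peakshaper:::mlp_forward(p, X), pm, Xm, ym)
  for (k in names(pm))
    expect_equal(as.numeric(am[[k]]), as.numeric(nm[[k]]),
                 tolerance = 1e-5, info = k)
})

test_that("a single separating feature is learned by the logistic stage", {
  set.seed(7)
  n <- 200
  enrich <- matrix(exp(rnorm(n * 11, 0, 0.3)), n, 11)
  y <- as.integer(seq_len(n) <= n / 2)
  enrich[y == 1, 4] <- enrich[y == 1, 4] * 10   # feature 4 separates classes
  fit <- peakshaper:::fit_enrichment_model(enrich, y)
  pred <- peakshaper:::predict_enrichment(fit, enrich) >= 0.5
  expect_gte(mean(pred == y), 0.95)
})

small_sim <- function(seed) {
  simulate_track(simulation_config(chrom_length = 2e5, n_peaks = 25,
                                   n_noise = 50, seed = seed))
}

trained_small <- function() {
  if (is.null(.fixture_env$small)) {
    sim <- small_sim(31)
    ts <- make_training_set(sim$track, sim$truth)
    feats <- extract_features(sim$track, ts)
    .fixture_env$small <- list(
      sim = sim, ts = ts, feats = feats,
      model = train_peak_model(feats, ts$label, seed = 5, epochs = 60))
  }
  .fixture_env$small
}

test_that("training is reproducible and scores stay in [0, 1]", {
  fx <- trained_small()
  m2 <- train_peak_model(fx$feats, fx$ts$label, seed = 5, epochs = 60)
  s1 <- score_features(fx$model, fx$feats)
  s2 <- score_features(m2, fx$feats)
  expect_identical(s1, s2)

  # arbitrary finite inputs stay bounded
  set.seed(99)
  junk <- structure(list(signal = matrix(runif(5 * 2000, 0, 1), 5),
                         enrich = matrix(exp(rnorm(5 * 11, 0, 3)), 5),
                         regions = NULL), class = "feature_bundles")
  sj <- score_features(fx$model, junk)
  expect_true(all(sj >= 0 & sj <= 1))

  # misshapen features are rejected
  bad <- junk; bad$enrich <- bad$enrich[, 1:7]
  expect_error(score_features(fx$model, bad), "dimensionality")
})

test_that("single-class labels are a training error", {
  fx <- trained_small()
  expect_error(train_peak_model(fx$feats, rep("peak", nrow(fx$ts)),
                                seed = 1), "each class")
})

test_that("trained model separates planted peaks from noise", {
  fx <- trained_small()
  sim2 <- small_sim(32)
  ts2 <- make_training_set(sim2$track, sim2$truth)
  sc <- score_features(fx$model, extract_features(sim2$track, ts2))
  pos <- ts2$label == "peak"
  expect_gte(auc_score(sc$peak_score, pos), 0.9)
  # matched peak/noise pairs: the peak outscores the noise region
  wins <- sc$peak_score[pos] > sc$peak_score[!pos]
  expect_gte(mean(wins), 0.9)
})

test_that("model bundles round-trip through disk bit-identically", {
  fx <- trained_small()
  sc0 <- score_features(fx$model, fx$feats)
  dir <- withr::local_tempdir()
  save_model(fx$model, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  expect_true(file.exists(file.path(dir, "weights.txt")))
  m <- load_model(dir)
  expect_identical(score_features(m, fx$feats), sc0)

  # corruption and descriptor mismatches are load errors
  w <- readLines(file.path(dir, "weights.txt"))
  writeLines(w[1:(length(w) - 5)], file.path(dir, "weights.txt"))
  expect_error(load_model(dir), "weights")
  writeLines(w, file.path(dir, "weights.txt"))
  desc <- readLines(file.path(dir, "model.json"))
  writeLines(gsub("bg_40kb", "bg_41kb", desc), file.path(dir, "model.json"))
  expect_error(load_model(dir), "feature ordering")
  expect_error(load_model(withr::local_tempdir()), "model bundle")
})
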