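# The synthetic acceptance fixture: the stated world (1 Mb, 200 planted
# peaks, folds 5-20, background 1.0), one training track and one test
# track under different seeds, with the model trained once and memoized so
# several test files can share it.

.fixture_env <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  sim_train <- simulate_track(simulation_config(seed = 101L))
  sim_test <- simulate_track(simulation_config(seed = 202L))
  train_set <- make_training_set(sim_train$track, sim_train$truth)
  feats <- extract_features(sim_train$track, train_set)
  model <- train_peak_model(feats, train_set$label, seed = 11L)
  .fixture_env$fx <- list(sim_train = sim_train, sim_test = sim_test,
                          model = model)
  .fixture_env$fx
}
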