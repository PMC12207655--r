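# Shared fixtures, computed lazily and cached for the whole test session
# (the classifier fixture is expensive: full tuning workflow on 200
# segments per class).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 200 labelled 15-s segments per class over 4 synthetic birds
training_segments <- function() {
  fixture("segments", function()
    gen_labelled_segments(n_per_bird = 450, n_birds = 4, seed = 2024))
}

# classifier trained with the full study workflow (50/50 split, 5x10 CV,
# 18-combo random grid, RFE)
trained_classifier <- function() {
  fixture("classifier", function()
    train_classifier(training_segments(), classifier_config(seed = 2024)))
}

# small fast config for workflow-mechanics tests
small_config <- function(seed = 1) {
  classifier_config(cv_folds = 3, cv_repeats = 1, grid_size = 4,
                    rfe_sizes = c(8, 36), tune_trees = 50, num_trees = 100,
                    seed = seed)
}
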