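# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; no files ship with the package.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A default scene with one spike, six leaves and crossings.
fixture_scene <- function(seed = 42) {
  memo(paste0("scene", seed), function() generate_scene(scene_spec(rng_seed = seed)))
}

# The same scene's Laws feature stack and half-scale masks.
fixture_features <- function(seed = 42) {
  memo(paste0("feat", seed), function() {
    sc <- fixture_scene(seed)
    A <- dwt_haar(to_grayscale(sc$image))$A
    list(scene = sc, A = A, stack = laws_features(A))
  })
}

# The standard trained classifier (20 scenes, derived seeds).
fixture_model <- function() {
  memo("model", function() train_synthetic_classifier(n_scenes = 20, seed = 1))
}
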