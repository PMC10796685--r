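# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 96-channel population with mid-range correlation and full laterality.
fix_pop <- function() cached("pop", function() {
  sample_population(96, rho_x = 0.5, rho_y = 0.5, lat_scale = 1, seed = 101)
})

# Small noiseless unimanual movement-window dataset.
fix_unimanual <- function() cached("unimanual", function() {
  generate_unimanual_dataset(fix_pop(), n_per_hand = 64, seed = 102)
})

# Delayed-movement session (both unimanual types + bimanual), noiseless.
fix_delayed <- function() cached("delayed", function() {
  generate_delayed_session(fix_pop(), n_per_type = 32, seed = 103)
})

# Preprocessed noisy labeled stream for augmentation tests.
fix_stream <- function() cached("stream", function() {
  sess <- generate_delayed_session(fix_pop(), n_per_type = 16,
                                   types = c("unimanual_right", "unimanual_left"),
                                   seed = 104)
  sess$rates <- add_noise_and_clip(sess$rates, noise_model(4), seed = 105)
  label_stream(zscore_session(remove_block_means(sess)))
})
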