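# Small fixtures shared across tests; everything is generated in code.

# a tiny encoder configuration cheap enough for forward/backward in tests
micro_cfg <- function(num_classes = 3L, use_attention = TRUE) {
  encoder_config(input_side = 16L, stem_width = 4L, num_stages = 2L,
                 groups = 2L, se_reduction = 2L, num_classes = num_classes,
                 use_attention = use_attention)
}

micro_model <- function(seed = 1L, num_classes = 3L, N = 4L, k = 1L) {
  init_rgn_model(micro_cfg(num_classes), N = N, k = k, seed = seed,
                 dec_seed_channels = 16L)
}

random_images <- function(n, side = 16L, channels = 3L, seed = 1L) {
  set.seed(seed)
  array(runif(n * side * side * channels), c(n, side, side, channels))
}

# tiny labeled set drawn from the synthetic generator
micro_dataset <- function(n_per_class = 8L, seed = 1L, side = 16L) {
  synth_generate(n_per_class, seed = seed, side = side)
}
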