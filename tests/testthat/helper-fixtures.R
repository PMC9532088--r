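# Shared fixtures built in code at test time.

# Small bank for cheap exact checks.
tiny_params <- function() {
  log_gabor_params(n_scales = 2, n_orientations = 3, min_wavelength = 3)
}

# Pure sinusoidal grating: cos(2*pi/lambda * (x cos(theta) + y sin(theta))),
# x along columns, y along rows (the package's frequency-grid convention).
make_grating <- function(size, lambda, theta, phase = 0) {
  X <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  Y <- matrix(seq_len(size) - 1, size, size)
  cos(2 * pi / lambda * (X * cos(theta) + Y * sin(theta)) + phase)
}

# Tiny 2-class grating dataset for training smoke tests: horizontal vs
# vertical texture at 16 px.
toy_two_class <- function(n_per_class = 8, seed = 1) {
  p <- log_gabor_params(n_scales = 2, n_orientations = 2, min_wavelength = 4)
  specs <- default_class_specs(2, p, noise_sd = 0.05)
  gen_dataset(2, n_per_class, 16, seed = seed, specs = specs, params = p)
}

tiny_arch <- function(num_classes = 2, fusion_enabled = FALSE, ...) {
  arch_config(block_sizes = c(1, 1), growth_rate = 4, stem_channels = 6,
              input_size = 16, num_classes = num_classes,
              fusion_enabled = fusion_enabled,
              gabor = log_gabor_params(n_scales = 2, n_orientations = 2,
                                       min_wavelength = 4), ...)
}

# The default study-scale synthetic dataset, generated once per test run.
default_synth <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) cache[[key]] <- gen_dataset(8, 50, 64, seed = seed)
    cache[[key]]
  }
})
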