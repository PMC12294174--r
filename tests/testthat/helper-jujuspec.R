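# small study configuration used across unit tests (fast to generate)
small_config <- function(seed = 1L, ...) {
  synth_config(n_classes = 5, n_per_class = 24, n_bands = 60,
               seed = seed, ...)
}

# noise-free configuration: every sample equals its class template
noiseless_config <- function(seed = 1L, ...) {
  synth_config(n_classes = 4, n_per_class = 6, n_bands = 40,
               scatter_sd = 0, offset_sd = 0, tilt_sd = 0, noise_sd = 0,
               seed = seed, ...)
}

# mean squared distance between rows of two matrices
mean_cross_dist <- function(A, B) {
  mean(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B))
}
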