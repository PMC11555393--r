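# shared helpers: tiny fixtures are generated in code, never stored

# a small, fast configuration that still exercises every layer kind
tiny_config <- function(input_size = 12L, ...) {
  mifnet_config(stage_widths = c(4L, 8L, 8L),
                bottleneck_widths = c(2L, 2L, 4L),
                mini_blocks_per_stage = 1L,
                groups = c(2L, 2L, 2L),
                fusion_channels = 2L,
                dropout_rates = c(0, 0, 0),
                input_size = input_size, ...)
}

# seeded random valid configurations for property-style loops
random_config <- function(seed) {
  set.seed(seed)
  g <- sample(c(1L, 2L, 4L), 3, replace = TRUE)
  mifnet_config(stage_widths = g * sample(2:4, 3, replace = TRUE),
                bottleneck_widths = g * sample(1:2, 3, replace = TRUE),
                mini_blocks_per_stage = sample(1:3, 1),
                groups = g,
                fusion_channels = sample(1:3, 1),
                input_size = 50L)
}

# independent brute-force parameter oracle: enumerate every weight
# tensor actually allocated for the network and sum their lengths
enumerate_weights <- function(graph) {
  net <- init_network(graph, seed = 1)
  sum(vapply(net$weights, function(w)
    if (is.null(w)) 0 else sum(lengths(lapply(w, as.vector))), 0))
}

# independent receptive-field oracle: propagate the index set that can
# influence the first output unit back through a (kernel, stride) chain
# of valid convolutions, and measure its extent
rf_support_oracle <- function(chain) {
  support <- 1L          # positions (1-based) at the top layer
  for (ks in rev(chain)) {
    k <- ks[[1]]; s <- ks[[2]]
    support <- unique(unlist(lapply(support, function(p)
      (p - 1L) * s + seq_len(k))))
  }
  max(support) - min(support) + 1L
}

# random (kernel, stride) chains for receptive-field properties
random_chain <- function(seed) {
  set.seed(seed)
  n <- sample(1:4, 1)
  lapply(seq_len(n), function(i)
    c(sample(c(1L, 2L, 3L, 5L), 1), sample(c(1L, 2L), 1)))
}

# grayscale patch batch with fixed values
const_batch <- function(n, size = 50, value = 0) {
  array(value, c(size, size, n))
}

# a quickly separable patch problem shared by training tests
separable_patches <- function(n_per_class, seed = 7) {
  ds <- make_patch_dataset(n_per_class, separation = 8, noise_sd = 0.05,
                           seed = seed)
  list(images = ds$images, labels = ds$labels)
}
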