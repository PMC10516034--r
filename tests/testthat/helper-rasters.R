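# small builders shared across test files

raster_with_spikes <- function(n_channels, n_bins, spikes, bin_width = 1) {
  m <- matrix(0L, n_channels, n_bins)
  if (length(spikes)) {
    m[do.call(rbind, spikes)] <- 1L # spikes: list of c(channel, bin), 1-based
  }
  spike_raster(m, bin_width = bin_width)
}

expect_tensor_equal <- function(a, b) {
  expect_identical(as.vector(unclass(a)), as.vector(unclass(b)))
}

# canonical worked-example fixture: 16 isolated feedforward motifs, 48 spikes
fig_fixture <- function(seed = 42) generate_feedforward_raster(16, seed = seed)

fig_window <- function() lag_window(5, 4)
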