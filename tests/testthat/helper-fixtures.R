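# Shared fixtures, memoized across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small phantom: a handful of contacts in a thin block, quick to render
small_phantom <- function() memo("small_phantom", {
  generate_phantom(phantom_config(
    volume_size_um = c(25, 25, 0.9),
    n_synapses = 4, n_near_misses = 2,
    n_dendrites = 2, n_axons = 2, seed = 11))
})

small_detect <- function() memo("small_detect", {
  run_detect(small_phantom()$stack, run_config())
})

# the full study-conditions phantom (defaults, seed 42) and its detection
default_phantom <- function() memo("default_phantom", {
  generate_phantom(phantom_config(seed = 42))
})

default_detect <- function() memo("default_detect", {
  run_detect(default_phantom()$stack, run_config())
})

random_histogram <- function(n_bins, bimodal = runif(1) < 0.5) {
  if (bimodal) {
    m1 <- runif(1, 0.1, 0.4) * n_bins
    m2 <- runif(1, 0.6, 0.9) * n_bins
    x <- c(rnorm(400, m1, n_bins / 20), rnorm(200, m2, n_bins / 25))
  } else {
    x <- rnorm(600, n_bins / 2, n_bins / 6)
  }
  counts <- tabulate(pmin(n_bins, pmax(1, round(x))), nbins = n_bins)
  if (sum(counts > 0) < 2L) counts[c(1L, n_bins)] <- counts[c(1L, n_bins)] + 1L
  counts
}
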