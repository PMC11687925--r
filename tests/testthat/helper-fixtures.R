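# Deterministic fixtures shared across test files.

# Closed-form 64x64 12-bit image: a smooth two-band sinusoidal pattern whose
# pixel values are a pure function of the coordinates (no RNG), so reference
# values computed elsewhere apply bit-for-bit.
sinusoid_image <- function() {
  i <- matrix(0:63, 64, 64)
  j <- t(i)
  v <- 1800 + 1200 * sin(2 * pi * i / 32) * cos(2 * pi * j / 32)
  gray_image(pmin(pmax(floor(v + 0.5), 0), 4095), 12)
}

# Bimodal 12-bit mixture emulating a background/foreground scan
bimodal_spec <- function(seed, shape = c(64L, 64L)) {
  mixture_spec(means = c(1000, 3000), sds = c(150, 200),
               weights = c(0.6, 0.4), bit_depth = 12L,
               shape = shape, seed = seed)
}

# Four-mode 12-bit mixture for the high-threshold-count regime
fourmode_spec <- function(seed, shape = c(64L, 64L)) {
  mixture_spec(means = c(500, 1500, 2500, 3500),
               sds = c(120, 150, 150, 120),
               weights = c(0.3, 0.3, 0.2, 0.2), bit_depth = 12L,
               shape = shape, seed = seed)
}

# Small random histogram for property tests
random_histogram <- function(L, seed) {
  set.seed(seed)
  p <- stats::runif(L)
  gray_histogram(probs = p / sum(p))
}

extdata <- function(file) {
  system.file("extdata", file, package = "ciwpso", mustWork = TRUE)
}
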