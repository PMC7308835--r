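# Shared fixtures, built in code. The default study table is expensive
# enough to memoise across test files.

.fixtures <- new.env(parent = emptyenv())

defaultStudyTable <- function() {
  if (is.null(.fixtures$st))
    .fixtures$st <- simulateSpectraTable(studyDesign(seed = 1L))
  .fixtures$st
}

# Planted-signal toy for selection-recovery tests: two informative bands
# carry a linear FP-like signal at the given signal-to-noise ratio, the
# rest are pure noise.
makePlantedToy <- function(n = 100, p = 50, informative = NULL,
                           snr = 20, seed = 7) {
  if (is.null(informative)) informative <- round(c(0.33, 0.66) * p)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  signal <- rowSums(X[, informative, drop = FALSE])
  y <- signal + rnorm(n, 0, sqrt(var(signal) / snr))
  list(X = X, y = y, informative = informative)
}

# Minimal valid PLSModel with an arbitrary coefficient profile, for
# exercising Bw extrema extraction in isolation.
stubPLSModel <- function(coef, wavelength = seq(500, by = 1,
                                                length.out = length(coef))) {
  p <- length(coef)
  new("PLSModel", nLV = 1L, xMean = numeric(p), yMean = 0,
      weights = matrix(1, p, 1), loadings = matrix(1, p, 1),
      yLoadings = 1, coef = as.numeric(coef),
      wavelength = as.numeric(wavelength),
      cv = new("CVResult", candidates = data.frame(n_lv = 1L),
               rmsecv = 0, chosen = 1L))
}

# Tiny deterministic cube: values are a fixed arithmetic pattern so
# brute-force oracles stay readable.
toyCube <- function(bands = 5, rows = 6, cols = 6, seed = 11) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  SpectralCube(array(runif(bands * rows * cols), c(bands, rows, cols)),
               seq(500, 900, length.out = bands))
}
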