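# Shared in-code fixtures for the test suite.

# tiny single-day plasma design used where rendering speed matters
smallDesign <- function(fluid = "plasma", nPerCell = 3, points = 4096,
                        noiseSD = 0.2, ...) {
  cohortDesign(fluid, nPerCell = nPerCell, days = "D8", points = points,
               noiseSD = noiseSD, ...)
}

# noiseless design: no noise, no baseline, no jitter, no dispersion
cleanDesign <- function(fluid = "plasma", nPerCell = 2, points = 8192,
                        ...) {
  cohortDesign(fluid, nPerCell = nPerCell, days = "D8", points = points,
               noiseSD = 0, shiftJitterSD = 0, baselineAmplitude = 0,
               sigmaLog = 0, ...)
}

# one-singlet library for integration oracles
singletLibrary <- function(center = 3.0, width_hz = 1.5,
                           fluid = "plasma") {
  new("PeakLibrary",
      peaks = data.frame(metabolite = "Probe", ppm = center,
                         pattern = "s", area = 1, width_hz = width_hz,
                         stringsAsFactors = FALSE),
      fluid = fluid)
}

# trapezoidal integral of a spectrum over its full axis (oracle)
trapzSpectrum <- function(s) {
  x <- rev(ppm(s)); y <- rev(intensity(s))
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# samples x features Gaussian matrix with a two-class label
randomTwoClass <- function(n = 16, p = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    list(X = X, y = rep(c("C", "H"), each = n / 2))
  })
}

# brute-force upper-tail hypergeometric probability via binomial
# coefficients (independent of stats::phyper)
bruteHyper <- function(overlap, m, bg, k) {
  js <- overlap:min(m, k)
  sum(choose(m, js) * choose(bg - m, k - js)) / choose(bg, k)
}

fixturePath <- function(name)
  system.file("extdata", name, package = "NMRScreen")
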