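test_that("spectrum CSV and JCAMP-DX round-trips preserve the data", {
  s0 <- Spectrum1D(c(1.0, 0.9, 0.8), c(5, 6, 7), "s1", "C", "D8",
                   "plasma")
  expect_length(ppm(s0), 3)

  d <- smallDesign(points = 4096)
  s <- renderSpectrum(c(Probe = 2), singletLibrary(), d, seed = 3,
                      meta = list(sample_id = "a1", group = "H",
                                  day = "D8"))
  csv <- withr::local_tempfile(fileext = ".csv")
  jdx <- withr::local_tempfile(fileext = ".jdx")
  writeSpectrum(s, csv, "csv")
  writeSpectrum(s, jdx, "jcampdx")
  r1 <- readSpectrum(csv)
  r2 <- readSpectrum(jdx)
  expect_equal(ppm(r1), ppm(s), tolerance = 1e-9)
  expect_equal(intensity(r1), intensity(s), tolerance = 1e-9)
  expect_equal(ppm(r2), ppm(s), tolerance = 1e-9)
  expect_equal(intensity(r2), intensity(s), tolerance = 1e-9)
  expect_identical(spectrumMeta(r2)[1:4], spectrumMeta(s)[1:4])
  # the two formats decode to the same object
  expect_equal(intensity(r1), intensity(r2), tolerance = 1e-9)

  writeLines(c("#sample_id=x", "ppm,intensity", "1,2"), csv)
  expect_error(readSpectrum(csv), "missing metadata")
})

test_that("apodization broadens lines by the stated factor", {
  # decaying complex exponential: natural FWHM = 1/(pi * T2)
  t2 <- 0.3
  dwell <- 5e-4
  n <- 8192
  tt <- (0:(n - 1)) * dwell
  fid <- Fid(exp(2i * pi * 100 * tt - tt / t2), dwell)
  fwhm <- function(lb) {
    s <- apodizeTransform(fid, lb)
    hz <- rev((ppm(s) - fid@carrierPpm) * fid@frequency)
    y <- rev(intensity(s))
    half <- max(y) / 2
    above <- which(y > half)
    i1 <- min(above); i2 <- max(above)
    # linear interpolation of the half-height crossings
    left <- hz[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) *
      (hz[i1] - hz[i1 - 1])
    right <- hz[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) *
      (hz[i2 + 1] - hz[i2])
    right - left
  }
  f0 <- fwhm(0)
  expect_equal(f0, 1 / (pi * t2), tolerance = 0.15)
  # lb = 1 Hz adds ~1 Hz to the linewidth
  expect_equal(fwhm(1) - f0, 1, tolerance = 0.3)
  expect_error(apodizeTransform(fid, -1), ">= 0")
})

test_that("calibration finds the reference and is idempotent", {
  d <- cleanDesign(points = 16384, nPerCell = 2)
  lib <- buildDefaultLibrary("plasma")
  sim <- simulateCohort(d, effectSpec(), seed = 2, library = lib)
  s <- sim$spectra[[1]]
  cal <- calibrateSpectrum(s)
  # jitter is off, so the doublet sits at its library position already
  step <- abs(diff(ppm(s)))[1]
  expect_lt(abs(cal@shift), 2 * step)

  # planted mis-calibration of +0.015 ppm is recovered
  shifted <- cal
  shifted@ppm <- shifted@ppm + 0.015
  recal <- calibrateSpectrum(shifted)
  expect_equal(ppm(recal), ppm(cal), tolerance = 2 * step)

  # idempotence: a second pass applies (at most) one grid step
  again <- calibrateSpectrum(cal)
  expect_lt(abs(again@shift - cal@shift), 2 * step)

  # a signal-free window in a noisy spectrum is rejected
  dn <- smallDesign(points = 8192, noiseSD = 0.3)
  noisy <- renderSpectrum(c(Probe = 2), singletLibrary(center = 3.0),
                          dn, seed = 8)
  expect_error(calibrateSpectrum(noisy, nominal = 8.9,
                                 window = c(8.8, 9.0), doublet = FALSE),
               "noise floor")
})

test_that("urine spectra calibrate on the TSP singlet", {
  d <- cleanDesign("urine", points = 16384)
  sim <- simulateCohort(d, effectSpec(), seed = 5)
  cal <- calibrateSpectrum(sim$spectra[[1]])
  step <- abs(diff(ppm(cal)))[1]
  expect_lt(abs(cal@shift), 2 * step)
})

test_that("binning tiles the region, drops exclusions, conserves mass", {
  spec <- plasmaBinSpec()
  d <- smallDesign(points = 16384, noiseSD = 0.1)
  s <- renderSpectrum(c(Probe = 3), singletLibrary(), d, seed = 7)
  b <- binSpectrum(s, spec)
  # integer arithmetic: 4250 - 250 - 345 retained bins
  expect_length(b, 3655)
  centers <- attr(b, "centers")
  expect_false(any(centers > 4.54 & centers < 5.23))
  expect_false(any(centers > 5.5 & centers < 6.0))
  expect_length(binSpectrum(s, urineBinSpec()), 1590)

  # constant intensity c integrates to c * spacing in every bin
  flat <- Spectrum1D(seq(9.6, 0.4, length.out = 4001),
                     rep(2, 4001), "f", "C", "D8", "plasma")
  bf <- binSpectrum(flat, spec)
  expect_equal(unname(as.numeric(bf)), rep(2 * 0.002, 3655),
               tolerance = 1e-9)

  # mass conservation: retained bins sum to the integral over the
  # retained region
  x <- rev(ppm(s)); y <- rev(intensity(s))
  cum <- function(a, b2) {
    keep <- x >= a & x <= b2
    xx <- c(a, x[keep], b2)
    yy <- c(approx(x, y, a)$y, y[keep], approx(x, y, b2)$y)
    sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
  }
  direct <- cum(0.5, 4.54) + cum(5.23, 5.5) + cum(6.0, 9.0)
  expect_equal(sum(b), direct, tolerance = 1e-6 * abs(direct))

  expect_error(binSpectrum(s, binSpec(c(-2, 1), 0.01)), "outside")
})

test_that("assembled matrices are canonically ordered and validated", {
  d <- smallDesign(nPerCell = 2, points = 4096)
  sim <- simulateCohort(d, effectSpec(), seed = 3)
  rows <- lapply(sim$spectra, binSpectrum, spec = plasmaBinSpec())
  fm1 <- assembleMatrix(rows)
  fm2 <- assembleMatrix(rev(rows))
  expect_identical(featureValues(fm1), featureValues(fm2))
  expect_equal(dim(featureValues(fm1)), c(4L, 3655L))

  one <- assembleMatrix(rows[1])
  expect_equal(unname(featureValues(one)[1, ]), unname(as.numeric(rows[[1]])))

  bad <- rows
  names(bad[[2]])[1] <- "9.999999"
  expect_error(assembleMatrix(bad), "mismatch")
})

test_that("normalization contracts hold and pqn undoes dilution", {
  vals <- matrix(c(1, 2, 3, 2, 4, 6, 1.5, 3, 4.5), 3, 3, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c")))
  info <- data.frame(sample_id = c("s1", "s2", "s3"), group = "C",
                     day = "D8", fluid = "urine")
  fm <- FeatureMatrix(vals, info)

  ta <- normalizeMatrix(fm, "total_area")
  expect_equal(unname(rowSums(featureValues(ta))),
               rep(median(rowSums(vals)), 3), tolerance = 1e-9)

  # row 2 is exactly 2x row 1; pqn restores it to the reference profile
  pq <- normalizeMatrix(fm, "pqn")
  v <- featureValues(pq)
  expect_equal(unname(v["s2", ]), unname(v["s1", ]), tolerance = 1e-9)

  # identical rows are left untouched by pqn
  same <- FeatureMatrix(matrix(1:3, 3, 3, byrow = TRUE,
                               dimnames = list(NULL, c("a", "b", "c"))),
                        info)
  expect_equal(featureValues(normalizeMatrix(same, "pqn")),
               featureValues(same))

  vals0 <- vals; vals0[1, ] <- 0
  expect_error(normalizeMatrix(FeatureMatrix(vals0, info), "pqn"), "s1")

  # known dilution factors are recovered from a simulated urine cohort
  d <- cohortDesign("urine", nPerCell = 4, days = "D8", points = 8192,
                    noiseSD = 0.1)
  sim <- simulateCohort(d, effectSpec(), seed = 21)
  rows <- lapply(sim$spectra, binSpectrum, spec = urineBinSpec())
  fmu <- normalizeMatrix(assembleMatrix(rows), "pqn")
  fac <- S4Vectors::metadata(fmu)$scale_factors
  dil <- sim$truth$dilution[names(fac)]
  expect_gt(cor(log(fac), log(dil)), 0.95)
  expect_equal(unname(fac / dil), rep(mean(fac / dil), length(fac)),
               tolerance = 0.1)
})

test_that("window quantification sums the right bins", {
  vals <- matrix(1:6, 1, 6,
                 dimnames = list(NULL,
                                 sprintf("%.6f", seq(3.0, 2.5, by = -0.1))))
  info <- data.frame(sample_id = "s1", group = "C", day = "D8",
                     fluid = "plasma")
  fm <- FeatureMatrix(vals, info,
                      featureData = data.frame(
                        feature_id = colnames(vals),
                        ppm_center = seq(3.0, 2.5, by = -0.1)))
  # window covering bins at 3.0, 2.9, 2.8 -> values 1 + 2 + 3
  q <- quantifyMetabolites(fm, list(M = list(c(2.75, 3.05))))
  expect_equal(unname(featureValues(q)[1, "M"]), 6)
  # two disjoint windows add up
  q2 <- quantifyMetabolites(fm, list(M = list(c(2.95, 3.05),
                                              c(2.45, 2.55))))
  expect_equal(unname(featureValues(q2)[1, "M"]), 1 + 6)
  expect_error(quantifyMetabolites(fm, list(M = list(c(8, 9)))),
               "overlaps no retained bin")
})

test_that("planted fold changes survive the spectral pipeline", {
  # end-to-end at zero noise: simulate, calibrate, bin, quantify, and
  # recover a planted FC of 2.0 within 1%
  lib <- new("PeakLibrary", fluid = "plasma",
             peaks = rbind(peakRow <- data.frame(
               metabolite = c("Lactate", "Lactate", "Target", "Other"),
               ppm = c(1.33, 4.11, 6.51, 3.0),
               pattern = c("d", "q", "s", "s"),
               area = c(3, 1, 2, 2), width_hz = 1.5,
               stringsAsFactors = FALSE)))
  d <- cleanDesign(points = 16384, nPerCell = 3)
  eff <- effectSpec("Target", "D8", 2)
  sim <- simulateCohort(d, eff, seed = 31, library = lib,
                        baseLevels = c(Lactate = 4, Target = 1,
                                       Other = 1))
  spec <- plasmaBinSpec()
  rows <- lapply(sim$spectra, function(s)
    binSpectrum(calibrateSpectrum(s), spec))
  qm <- quantifyMetabolites(assembleMatrix(rows),
                            defaultAssignments(lib, spec))
  v <- featureValues(qm)
  g <- sampleInfo(qm)$group
  expect_equal(foldChange(v[, "Target"], g), 2, tolerance = 0.01)
  expect_equal(foldChange(v[, "Other"], g), 1, tolerance = 0.01)

  # quantification linearity: scaling a spectrum scales every metabolite
  s1 <- sim$spectra[[1]]
  s1k <- s1; s1k@intensity <- 3 * s1k@intensity
  r1 <- binSpectrum(calibrateSpectrum(s1), spec)
  rk <- binSpectrum(calibrateSpectrum(s1k), spec)
  expect_equal(as.numeric(rk), 3 * as.numeric(r1), tolerance = 1e-9)
})
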