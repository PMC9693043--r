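# Synthetic two-group NMR cohorts with planted effects. Chemical shifts are
# implementer-chosen from standard small-molecule references; only relative
# fold changes between groups carry meaning (base levels are arbitrary a.u.).

peakRow <- function(metabolite, ppm, pattern = "s", area = 1,
                    width_hz = 1.5) {
  data.frame(metabolite = metabolite, ppm = ppm, pattern = pattern,
             area = area, width_hz = width_hz, stringsAsFactors = FALSE)
}

plasmaPeakTable <- function() {
  rbind(
    peakRow("3-Hydroxybutyrate", c(1.20, 2.31, 4.13), c("d", "m", "m"),
            c(3, 2, 1)),
    peakRow("Acetoacetate", c(2.27, 3.43), c("s", "s"), c(3, 2)),
    peakRow("Acetate", 1.92, "s", 3),
    peakRow("Acetone", 2.23, "s", 6),
    peakRow("Benzoate", c(7.48, 7.87), c("m", "d"), c(3, 2)),
    peakRow("cis-Aconitate", c(3.11, 5.70), c("d", "s"), c(2, 1)),
    peakRow("Choline", c(3.19, 3.51, 4.05), c("s", "m", "m"), c(9, 2, 2)),
    peakRow("Citrate", c(2.53, 2.65), c("d", "d"), c(2, 2)),
    peakRow("Creatine", c(3.03, 3.92), c("s", "s"), c(3, 2)),
    peakRow("Cytidine", c(6.06, 7.84), c("d", "d"), c(1, 1)),
    peakRow("Deoxyguanosine", c(6.28, 7.95), c("m", "s"), c(1, 1)),
    peakRow("N,N-Dimethylglycine", c(2.92, 3.71), c("s", "s"), c(6, 2)),
    peakRow("Ethanolamine", c(3.14, 3.82), c("t", "t"), c(2, 2)),
    peakRow("Fumarate", 6.51, "s", 2),
    peakRow("Glutamine", c(2.13, 2.44, 3.77), c("m", "m", "t"), c(2, 2, 1)),
    peakRow("Glycerol", c(3.56, 3.65, 3.78), c("m", "m", "m"), c(2, 2, 1)),
    peakRow("Isobutyrate", c(1.06, 2.38), c("d", "m"), c(6, 1)),
    peakRow("Isoleucine", c(0.93, 1.00), c("t", "d"), c(3, 3)),
    peakRow("Lipid", c(0.89, 1.29), c("m", "m"), c(4, 8), 18),
    peakRow("VLDL", c(0.87, 1.28), c("m", "m"), c(3, 4), 15),
    peakRow("LDL", c(0.84, 1.26), c("m", "m"), c(3, 4), 15),
    peakRow("Lactate", c(1.33, 4.11), c("d", "q"), c(3, 1)),
    peakRow("Leucine", c(0.96, 1.70), c("d", "m"), c(6, 3)),
    peakRow("Lysine", c(1.72, 1.90, 3.02), c("m", "m", "t"), c(2, 2, 2)),
    peakRow("Methionine", c(2.14, 2.64), c("s", "t"), c(3, 2)),
    peakRow("Phenylalanine", c(7.32, 7.42), c("m", "m"), c(2, 3)),
    peakRow("Sarcosine", c(2.73, 3.60), c("s", "s"), c(3, 2)),
    peakRow("Serine", c(3.83, 3.96), c("m", "m"), c(1, 2)),
    peakRow("Threonine", c(1.32, 4.25), c("d", "m"), c(3, 1)),
    peakRow("Valine", c(0.98, 1.04), c("d", "d"), c(3, 3)),
    # abundant background resonances present in any plasma spectrum
    peakRow("Alanine", 1.47, "d", 3),
    peakRow("Glycine", 3.55, "s", 2),
    peakRow("Glucose", c(3.40, 3.72, 5.23), c("m", "m", "d"), c(2, 2, 1)),
    peakRow("Pyruvate", 2.36, "s", 3),
    peakRow("Formate", 8.44, "s", 1)
  )
}

urinePeakTable <- function() {
  rbind(
    peakRow("TSP", 0.00, "s", 9),
    peakRow("1-Methylhistidine", c(7.04, 7.76), c("s", "s"), c(1, 1)),
    peakRow("2-Hydroxybutyrate", c(0.90, 4.00), c("t", "m"), c(3, 1)),
    peakRow("3-Hydroxybutyrate", c(1.20, 2.31, 4.13), c("d", "m", "m"),
            c(3, 2, 1)),
    peakRow("Acetoacetate", c(2.27, 3.43), c("s", "s"), c(3, 2)),
    peakRow("Acetone", 2.23, "s", 6),
    peakRow("Allantoin", 5.39, "s", 1),
    peakRow("Aminoadipate", c(1.65, 2.25), c("m", "t"), c(4, 2)),
    peakRow("Benzoate", c(7.48, 7.87), c("m", "d"), c(3, 2)),
    peakRow("Butyrate", c(0.88, 1.56, 2.16), c("t", "m", "t"), c(3, 2, 2)),
    peakRow("cis-Aconitate", c(3.11, 5.70), c("d", "s"), c(2, 1)),
    peakRow("Citrate", c(2.53, 2.65), c("d", "d"), c(2, 2)),
    peakRow("Fumarate", 6.51, "s", 2),
    peakRow("Glycine", 3.56, "s", 2),
    peakRow("Hippurate", c(3.97, 7.55, 7.64, 7.84), c("d", "t", "t", "d"),
            c(2, 2, 1, 2)),
    peakRow("Hydroxypyruvate", 4.37, "s", 2),
    peakRow("Lactate", c(1.33, 4.11), c("d", "q"), c(3, 1)),
    peakRow("Malate", c(2.37, 2.67, 4.30), c("dd", "dd", "dd"), c(1, 1, 1)),
    peakRow("Maleicate", 6.01, "s", 2),
    peakRow("N,N-Dimethylglycine", c(2.92, 3.71), c("s", "s"), c(6, 2)),
    peakRow("N-Acetylaspartate", c(2.01, 2.49), c("s", "dd"), c(3, 1)),
    peakRow("N-Acetylglutamate", c(2.04, 2.23), c("s", "m"), c(3, 2)),
    peakRow("ortho-Hydroxyphenylacetate", c(3.66, 7.15), c("s", "m"),
            c(2, 2)),
    peakRow("Phenylacetylglycine", c(3.68, 7.36, 7.42), c("s", "m", "m"),
            c(2, 2, 3)),
    peakRow("Picolinate", c(7.55, 8.00, 8.55), c("m", "m", "d"), c(1, 1, 1)),
    peakRow("Succinate", 2.41, "s", 4),
    peakRow("Taurine", c(3.25, 3.42), c("t", "t"), c(2, 2)),
    peakRow("Trigonelline", c(4.43, 8.08, 8.83, 9.12), c("s", "m", "m", "s"),
            c(3, 1, 2, 1)),
    peakRow("Urocanate", c(6.40, 7.30, 7.89), c("d", "d", "s"), c(1, 1, 1)),
    peakRow("alpha-Ketoglutarate", c(2.44, 3.01), c("t", "t"), c(2, 2)),
    # abundant background resonances in any urine spectrum
    peakRow("Creatinine", c(3.05, 4.06), c("s", "s"), c(3, 2)),
    peakRow("Urea", 5.78, "s", 4, 12),
    peakRow("Formate", 8.44, "s", 1),
    peakRow("Alanine", 1.47, "d", 3)
  )
}

#' Default metabolite peak library for a fluid
#'
#' Plasma and urine vocabularies covering every metabolite the screening
#' report can name for that fluid, plus abundant background resonances.
#' Lactate is a doublet centred at 1.33 ppm (the plasma calibration
#' reference); the urine library includes the TSP reference singlet at
#' 0.00 ppm. Chemical shifts are taken from standard references; relative
#' areas approximate proton counts.
#'
#' @param fluid \code{"plasma"} or \code{"urine"}.
#' @return a \linkS4class{PeakLibrary}.
#' @examples
#' lib <- buildDefaultLibrary("plasma")
#' "Lactate" %in% libraryMetabolites(lib)
#' @export
buildDefaultLibrary <- function(fluid = c("plasma", "urine")) {
  fluid <- match.arg(fluid)
  peaks <- if (fluid == "plasma") plasmaPeakTable() else urinePeakTable()
  new("PeakLibrary", peaks = peaks, fluid = fluid)
}

#' Planted differential effects
#'
#' @param metabolite,day,foldChange equal-length vectors: metabolite name,
#'   sampling day, and H/C fold change (> 0) applied to that (H, day) cell.
#' @return validated data.frame with class \code{effect_spec}.
#' @examples
#' effectSpec("Citrate", "D20", 0.5)
#' @export
effectSpec <- function(metabolite = character(), day = character(),
                       foldChange = numeric()) {
  df <- data.frame(metabolite = as.character(metabolite),
                   day = as.character(day),
                   fold_change = as.numeric(foldChange),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$fold_change <= 0)) stop("fold changes must be positive")
    if (!all(df$day %in% DAY_LEVELS))
      stop("effect days must be one of ", paste(DAY_LEVELS, collapse = ", "))
    if (anyDuplicated(df[c("metabolite", "day")]))
      stop("(metabolite, day) pairs must be unique")
  }
  class(df) <- c("effect_spec", "data.frame")
  df
}

#' Default base concentration levels
#'
#' The emulated study reports no absolute concentrations, so base levels
#' are arbitrary units; only fold changes between groups are meaningful.
#' A handful of genuinely abundant species (lactate, glucose, the lipid
#' envelopes, creatinine, urea, the TSP standard) sit above the default of
#' 1 so the rendered spectra have the dynamic range of real biofluids and
#' the calibration references dominate their neighbourhoods.
#'
#' @param library a \linkS4class{PeakLibrary}.
#' @return named numeric vector of base levels.
#' @export
defaultBaseLevels <- function(library) {
  m <- libraryMetabolites(library)
  lv <- setNames(rep(1, length(m)), m)
  abundant <- c(Lactate = 4, Glucose = 5, Lipid = 3, VLDL = 2.5,
                LDL = 2.5, Creatinine = 3, Urea = 5, TSP = 3,
                Hippurate = 2, Citrate = 2)
  hit <- intersect(names(abundant), m)
  lv[hit] <- abundant[hit]
  lv
}

cohortSampleTable <- function(design) {
  grid <- expand.grid(rep = seq_len(design@nPerCell),
                      day = design@days, group = design@groups,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$group, GROUP_LEVELS),
                     match(grid$day, DAY_LEVELS), grid$rep), ]
  data.frame(sample_id = sprintf("%s_%s_r%d", grid$group, grid$day,
                                 grid$rep),
             group = grid$group, day = grid$day, fluid = design@fluid,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample per-animal metabolite concentrations
#'
#' Concentrations are lognormal around each metabolite's base level
#' (log-scale SD \code{design@sigmaLog}), multiplied by the planted fold
#' change in the (H, day) cells named by \code{effects}. Deterministic for
#' a fixed seed.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param effects an \code{\link{effectSpec}}.
#' @param baseLevels named positive vector of base levels covering every
#'   effect metabolite.
#' @param seed integer seed.
#' @return list with \code{concentrations} (samples x metabolites matrix),
#'   \code{samples} (metadata data.frame), \code{effects}, and
#'   \code{dilution} (per-sample factors, filled in by
#'   \code{\link{simulateCohort}}); class \code{synthetic_truth}.
#' @export
sampleConcentrations <- function(design, effects, baseLevels, seed) {
  stopifnot(is(design, "CohortDesign"))
  if (any(baseLevels <= 0)) stop("base levels must be positive")
  unknown <- setdiff(effects$metabolite, names(baseLevels))
  if (length(unknown))
    stop("effect references unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  samples <- cohortSampleTable(design)
  nmet <- length(baseLevels)
  conc <- withr::with_seed(seed, {
    noise <- matrix(rnorm(nrow(samples) * nmet, 0, design@sigmaLog),
                    nrow(samples), nmet)
    sweep(exp(noise), 2, baseLevels, `*`)
  })
  dimnames(conc) <- list(samples$sample_id, names(baseLevels))
  for (i in seq_len(nrow(effects))) {
    rows <- samples$group == "H" & samples$day == effects$day[i]
    conc[rows, effects$metabolite[i]] <-
      conc[rows, effects$metabolite[i]] * effects$fold_change[i]
  }
  structure(list(concentrations = conc, samples = samples,
                 effects = effects,
                 dilution = setNames(rep(1, nrow(samples)),
                                     samples$sample_id)),
            class = "synthetic_truth")
}

# expand a multiplet into individual Lorentzian lines (position offsets in
# ppm and area weights); J fixed at 7 Hz, "m" rendered as one broadened line
expandMultiplet <- function(pattern, frequency = SPECTROMETER_MHZ) {
  j <- 7 / frequency
  switch(pattern,
    s = list(offset = 0, weight = 1, widen = 1),
    d = list(offset = c(-0.5, 0.5) * j, weight = c(0.5, 0.5), widen = 1),
    t = list(offset = c(-1, 0, 1) * j, weight = c(0.25, 0.5, 0.25),
             widen = 1),
    q = list(offset = c(-1.5, -0.5, 0.5, 1.5) * j,
             weight = c(1, 3, 3, 1) / 8, widen = 1),
    dd = list(offset = c(-0.5, 0.5) * j * 1.4, weight = c(0.5, 0.5),
              widen = 1),
    m = list(offset = 0, weight = 1, widen = 3),
    stop("unknown multiplicity pattern: ", pattern))
}

#' Render one spectrum from metabolite concentrations
#'
#' Each library line becomes a Lorentzian of area concentration x relative
#' area, FWHM = linewidth(Hz) / spectrometer frequency, centred at the
#' library shift plus a per-metabolite Gaussian jitter; a smooth sinusoidal
#' baseline and white noise are added. Deterministic for a fixed seed.
#'
#' @param concentrations named non-negative vector (a.u.).
#' @param library a \linkS4class{PeakLibrary} covering all names.
#' @param design a \linkS4class{CohortDesign} (axis and noise parameters).
#' @param seed integer seed.
#' @param meta optional list(sample_id, group, day) for the output.
#' @return a \linkS4class{Spectrum1D}.
#' @export
renderSpectrum <- function(concentrations, library, design, seed,
                           meta = list(sample_id = "sample", group = "C",
                                       day = "D8")) {
  peaks <- library@peaks
  missing <- setdiff(names(concentrations), peaks$metabolite)
  if (length(missing))
    stop("no library entry for metabolite(s): ",
         paste(missing, collapse = ", "))
  grid <- seq(design@ppmRange[1], design@ppmRange[2],
              length.out = design@points)
  signal <- numeric(design@points)
  withr::with_seed(seed, {
    jitter <- setNames(rnorm(length(concentrations), 0,
                             design@shiftJitterSD),
                       names(concentrations))
    for (m in names(concentrations)) {
      conc <- concentrations[[m]]
      if (conc <= 0) next
      rows <- which(peaks$metabolite == m)
      for (i in rows) {
        mult <- expandMultiplet(peaks$pattern[i])
        fwhm <- peaks$width_hz[i] * mult$widen / SPECTROMETER_MHZ
        hwhm <- fwhm / 2
        for (k in seq_along(mult$offset)) {
          centre <- peaks$ppm[i] + mult$offset[k] + jitter[[m]]
          area <- conc * peaks$area[i] * mult$weight[k]
          signal <- signal +
            area / pi * hwhm / ((grid - centre)^2 + hwhm^2)
        }
      }
    }
    span <- diff(design@ppmRange)
    baseline <- design@baselineAmplitude *
      (0.6 + 0.4 * sin(2 * pi * (grid - design@ppmRange[1]) / span))
    noise <- rnorm(design@points, 0, design@noiseSD)
    intensity <- signal + baseline + noise
  })
  Spectrum1D(grid, intensity, meta$sample_id, meta$group, meta$day,
             design@fluid)
}

#' Simulate a full two-group cohort
#'
#' Draws per-animal concentrations, renders one spectrum per animal, and
#' (for urine) multiplies each rendered signal by a lognormal per-sample
#' dilution factor with the design's CV, giving the normalization stage
#' something to remove. Bit-identical for a fixed seed.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param effects an \code{\link{effectSpec}} of planted fold changes.
#' @param seed integer seed (kept below 2^31 internally).
#' @param baseLevels optional named base levels (default all 1).
#' @param library optional \linkS4class{PeakLibrary} (default for fluid).
#' @return list(spectra = list of \linkS4class{Spectrum1D}, truth =
#'   \code{synthetic_truth} including realized dilution factors).
#' @examples
#' d <- cohortDesign("plasma", nPerCell = 2, days = "D8", points = 2048)
#' sim <- simulateCohort(d, effectSpec(), seed = 1)
#' length(sim$spectra)
#' @export
simulateCohort <- function(design, effects = effectSpec(), seed,
                           baseLevels = NULL, library = NULL) {
  if (is.null(library)) library <- buildDefaultLibrary(design@fluid)
  if (is.null(baseLevels)) baseLevels <- defaultBaseLevels(library)
  covered <- baseLevels > 0
  rng <- range(library@peaks$ppm[library@peaks$metabolite %in%
                                   names(baseLevels)[covered]])
  if (rng[1] < design@ppmRange[1] || rng[2] > design@ppmRange[2])
    stop("ppmRange does not span all library peaks in use")
  truth <- sampleConcentrations(design, effects, baseLevels, seed)
  n <- nrow(truth$samples)
  dil <- rep(1, n)
  if (design@dilutionCV > 0) {
    sdlog <- sqrt(log(1 + design@dilutionCV^2))
    dil <- withr::with_seed(seed + 777L,
                            rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  truth$dilution <- setNames(dil, truth$samples$sample_id)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    s <- renderSpectrum(truth$concentrations[i, ], library, design,
                        seed = (seed + 7919L * i) %% .Machine$integer.max,
                        meta = list(sample_id = truth$samples$sample_id[i],
                                    group = truth$samples$group[i],
                                    day = truth$samples$day[i]))
    if (dil[i] != 1)
      s@intensity <- s@intensity * dil[i]
    spectra[[i]] <- s
  }
  names(spectra) <- truth$samples$sample_id
  list(spectra = spectra, truth = truth)
}
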