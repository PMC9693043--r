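#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats approx cor fft mad median p.adjust pf phyper qt quantile
#'   rlnorm rnorm runif sd t.test var predict setNames
#' @importFrom utils head read.csv tail write.csv
NULL

GROUP_LEVELS <- c("C", "H")
DAY_LEVELS <- c("D8", "D11", "D14", "D17", "D20")
FLUID_LEVELS <- c("plasma", "urine")
SPECTROMETER_MHZ <- 600.13

#' One-dimensional NMR spectrum
#'
#' Container for a single processed 1D spectrum: a strictly descending
#' chemical-shift axis (ppm, the NMR plotting convention), matching
#' intensities in arbitrary units, and the sample metadata the rest of the
#' pipeline keys on (sample id, group C/H, gestational day, fluid).
#'
#' @slot ppm numeric, strictly descending chemical-shift axis in ppm.
#' @slot intensity numeric, same length as \code{ppm}.
#' @slot sampleID character scalar.
#' @slot group \code{"C"} (normoxic control) or \code{"H"} (hypoxia).
#' @slot day one of \code{"D8"}, \code{"D11"}, \code{"D14"}, \code{"D17"},
#'   \code{"D20"}.
#' @slot fluid \code{"plasma"} or \code{"urine"}.
#' @slot shift cumulative calibration shift (ppm) applied to the axis.
#'
#' @export
setClass("Spectrum1D",
  representation(
    ppm = "numeric",
    intensity = "numeric",
    sampleID = "character",
    group = "character",
    day = "character",
    fluid = "character",
    shift = "numeric"
  ),
  prototype(shift = 0)
)

setValidity("Spectrum1D", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) >= 2 && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly descending")
  if (length(object@sampleID) != 1L)
    msg <- c(msg, "sampleID must be a single string")
  if (!object@group %in% GROUP_LEVELS)
    msg <- c(msg, sprintf("group must be one of %s",
                          paste(GROUP_LEVELS, collapse = ", ")))
  if (!object@day %in% DAY_LEVELS)
    msg <- c(msg, sprintf("day must be one of %s",
                          paste(DAY_LEVELS, collapse = ", ")))
  if (!object@fluid %in% FLUID_LEVELS)
    msg <- c(msg, sprintf("fluid must be one of %s",
                          paste(FLUID_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum1D
#'
#' Accepts the axis in either direction and stores it descending.
#'
#' @param ppm chemical-shift axis (ppm), strictly monotone.
#' @param intensity intensities (a.u.), same length.
#' @param sampleID sample identifier.
#' @param group,day,fluid sample metadata (closed vocabularies).
#' @param shift calibration shift already applied, ppm.
#' @return a \linkS4class{Spectrum1D}.
#' @examples
#' s <- Spectrum1D(c(1.0, 0.9, 0.8), c(5, 6, 7), "s1", "C", "D8", "plasma")
#' @export
Spectrum1D <- function(ppm, intensity, sampleID, group, day, fluid,
                       shift = 0) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) >= 2 && ppm[1] < ppm[length(ppm)]) {
    ord <- rev(seq_along(ppm))
    ppm <- ppm[ord]
    intensity <- intensity[ord]
  }
  new("Spectrum1D", ppm = ppm, intensity = intensity,
      sampleID = as.character(sampleID), group = as.character(group),
      day = as.character(day), fluid = as.character(fluid),
      shift = as.numeric(shift))
}

setMethod("show", "Spectrum1D", function(object) {
  cat(sprintf(
    "Spectrum1D: %s (%s, %s, %s)\n  %d points, %.3f..%.3f ppm, shift %.4g ppm\n",
    object@sampleID, object@group, object@day, object@fluid,
    length(object@ppm), max(object@ppm), min(object@ppm), object@shift))
})

#' @describeIn Spectrum1D chemical-shift axis accessor.
#' @param object,x a \code{Spectrum1D}.
#' @export
ppm <- function(object) object@ppm

#' @describeIn Spectrum1D intensity accessor.
#' @export
intensity <- function(object) object@intensity

#' @describeIn Spectrum1D metadata accessor (named list).
#' @export
spectrumMeta <- function(object) {
  list(sample_id = object@sampleID, group = object@group,
       day = object@day, fluid = object@fluid, shift = object@shift)
}

#' Free induction decay
#'
#' Complex time-domain NMR signal prior to apodization and Fourier
#' transform.
#'
#' @slot points complex vector of time-domain samples.
#' @slot dwellTime sampling interval in seconds (1 / spectral width).
#' @slot frequency spectrometer proton frequency in MHz.
#' @slot carrierPpm chemical shift of the carrier (axis centre), ppm.
#' @export
setClass("Fid",
  representation(points = "complex", dwellTime = "numeric",
                 frequency = "numeric", carrierPpm = "numeric"),
  prototype(frequency = SPECTROMETER_MHZ, carrierPpm = 4.7)
)

setValidity("Fid", function(object) {
  msg <- character()
  if (length(object@points) < 1024L)
    msg <- c(msg, "FID must have at least 1024 points")
  if (length(object@dwellTime) != 1L || object@dwellTime <= 0)
    msg <- c(msg, "dwell time must be a single positive number")
  if (object@frequency <= 0) msg <- c(msg, "frequency must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a Fid
#'
#' @param points complex time-domain samples (>= 1024).
#' @param dwellTime sampling interval, seconds.
#' @param frequency spectrometer frequency, MHz (default 600.13).
#' @param carrierPpm carrier position, ppm (default 4.7, on-water).
#' @return a \linkS4class{Fid}.
#' @export
Fid <- function(points, dwellTime, frequency = SPECTROMETER_MHZ,
                carrierPpm = 4.7) {
  new("Fid", points = as.complex(points), dwellTime = as.numeric(dwellTime),
      frequency = as.numeric(frequency), carrierPpm = as.numeric(carrierPpm))
}

setMethod("show", "Fid", function(object) {
  cat(sprintf("Fid: %d complex points, sw %.0f Hz, %.2f MHz\n",
              length(object@points), 1 / object@dwellTime, object@frequency))
})

#' Metabolite peak library
#'
#' Vocabulary of metabolites and their resonances used by the spectrum
#' simulator: one row per multiplet (centre ppm, multiplicity pattern,
#' relative area, linewidth in Hz).
#'
#' @slot peaks data.frame with columns \code{metabolite}, \code{ppm},
#'   \code{pattern} (s, d, t, q, dd, m), \code{area}, \code{width_hz}.
#' @slot fluid which fluid the library describes.
#' @export
setClass("PeakLibrary",
  representation(peaks = "data.frame", fluid = "character"))

setValidity("PeakLibrary", function(object) {
  p <- object@peaks
  need <- c("metabolite", "ppm", "pattern", "area", "width_hz")
  if (!all(need %in% names(p)))
    return(sprintf("peaks must have columns %s", paste(need, collapse = ", ")))
  msg <- character()
  if (any(p$ppm < -0.5 | p$ppm > 10))
    msg <- c(msg, "peak centres must lie within -0.5..10 ppm")
  if (any(p$area <= 0)) msg <- c(msg, "relative areas must be positive")
  if (any(p$width_hz <= 0)) msg <- c(msg, "linewidths must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PeakLibrary", function(object) {
  cat(sprintf("PeakLibrary (%s): %d metabolites, %d multiplets\n",
              object@fluid, length(unique(object@peaks$metabolite)),
              nrow(object@peaks)))
})

#' @describeIn PeakLibrary metabolite names in the library.
#' @param object a \code{PeakLibrary}.
#' @export
libraryMetabolites <- function(object) unique(object@peaks$metabolite)

#' Cohort design for the synthetic generator
#'
#' Describes the study layout the simulator emulates: two groups (C and H),
#' five gestational sampling days, a fixed number of animals per group and
#' day, and the acquisition/noise parameters of the rendered spectra.
#'
#' @slot groups group labels, fixed \code{c("C", "H")}.
#' @slot days ordered day labels.
#' @slot nPerCell animals per group x day cell (>= 2).
#' @slot fluid \code{"plasma"} or \code{"urine"}.
#' @slot ppmRange rendered axis range, c(low, high) ppm.
#' @slot points spectrum length (>= 1024).
#' @slot noiseSD additive white-noise SD, intensity a.u.
#' @slot shiftJitterSD per-metabolite chemical-shift jitter SD, ppm.
#' @slot baselineAmplitude amplitude of the smooth additive baseline, a.u.
#' @slot dilutionCV coefficient of variation of the per-sample dilution
#'   factor (urine only; 0 disables).
#' @slot sigmaLog log-scale SD of metabolite concentrations.
#' @export
setClass("CohortDesign",
  representation(groups = "character", days = "character",
                 nPerCell = "integer", fluid = "character",
                 ppmRange = "numeric", points = "integer",
                 noiseSD = "numeric", shiftJitterSD = "numeric",
                 baselineAmplitude = "numeric", dilutionCV = "numeric",
                 sigmaLog = "numeric"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (!identical(object@groups, GROUP_LEVELS))
    msg <- c(msg, "groups must be c(\"C\", \"H\")")
  if (!all(object@days %in% DAY_LEVELS) || !length(object@days))
    msg <- c(msg, "days must be drawn from D8, D11, D14, D17, D20")
  if (object@nPerCell < 2L) msg <- c(msg, "nPerCell must be >= 2")
  if (!object@fluid %in% FLUID_LEVELS)
    msg <- c(msg, "fluid must be plasma or urine")
  if (length(object@ppmRange) != 2L || diff(object@ppmRange) <= 0)
    msg <- c(msg, "ppmRange must be an increasing pair")
  if (object@points < 1024L) msg <- c(msg, "points must be >= 1024")
  if (object@noiseSD < 0 || object@shiftJitterSD < 0 ||
      object@baselineAmplitude < 0 || object@dilutionCV < 0 ||
      object@sigmaLog < 0)
    msg <- c(msg, "noise/jitter/baseline/dilution/sigmaLog must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortDesign
#'
#' Defaults reproduce the emulated study layout: 2 groups x 5 days x 8
#' animals, 16384-point spectra, lognormal concentration dispersion 0.15,
#' shift jitter 0.002 ppm, and a dilution CV of 0.3 for urine.
#'
#' @param fluid \code{"plasma"} or \code{"urine"}.
#' @param nPerCell animals per group and day (default 8).
#' @param days sampling days (default all five).
#' @param ppmRange rendered range; defaults cover the fluid's full library
#'   including the reference resonance (0.00 ppm TSP for urine).
#' @param points spectrum length (default 16384).
#' @param noiseSD white-noise SD (default 0.5 a.u.).
#' @param shiftJitterSD shift jitter SD in ppm (default 0.002).
#' @param baselineAmplitude baseline amplitude (default 2 a.u.).
#' @param dilutionCV urine dilution CV (default 0.3 for urine, 0 plasma).
#' @param sigmaLog lognormal concentration dispersion (default 0.15).
#' @return a \linkS4class{CohortDesign}.
#' @examples
#' d <- cohortDesign("plasma")
#' @export
cohortDesign <- function(fluid = c("plasma", "urine"), nPerCell = 8L,
                         days = DAY_LEVELS,
                         ppmRange = NULL, points = 16384L, noiseSD = 0.5,
                         shiftJitterSD = 0.002, baselineAmplitude = 2,
                         dilutionCV = NULL, sigmaLog = 0.15) {
  fluid <- match.arg(fluid)
  if (is.null(ppmRange))
    ppmRange <- if (fluid == "plasma") c(0.0, 9.5) else c(-0.25, 9.75)
  if (is.null(dilutionCV)) dilutionCV <- if (fluid == "urine") 0.3 else 0
  new("CohortDesign", groups = GROUP_LEVELS, days = days,
      nPerCell = as.integer(nPerCell), fluid = fluid,
      ppmRange = as.numeric(ppmRange), points = as.integer(points),
      noiseSD = noiseSD, shiftJitterSD = shiftJitterSD,
      baselineAmplitude = baselineAmplitude, dilutionCV = dilutionCV,
      sigmaLog = sigmaLog)
}

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf(
    "CohortDesign (%s): %d x %d x %d samples, %d pts %.2f..%.2f ppm\n",
    object@fluid, length(object@groups), length(object@days),
    object@nPerCell, object@points, object@ppmRange[1], object@ppmRange[2]))
})

#' Feature matrix of binned or quantified NMR data
#'
#' Samples-by-features container built on
#' \link[SummarizedExperiment]{SummarizedExperiment}: the assay holds
#' features (bins or named metabolites) as rows and samples as columns;
#' \code{colData} carries sample_id/group/day/fluid; \code{rowData} carries
#' bin centres or metabolite names.
#'
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "group", "day", "fluid")
  if (!all(need %in% names(cd)))
    msg <- c(msg, sprintf("colData must contain %s",
                          paste(need, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (length(SummarizedExperiment::assays(object)) &&
      anyNA(SummarizedExperiment::assay(object)))
    msg <- c(msg, "feature matrix must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values samples x features numeric matrix.
#' @param sampleData data.frame with columns sample_id, group, day, fluid
#'   (one row per sample, same order as \code{values} rows).
#' @param featureData optional data.frame of per-feature annotation.
#' @param normalization provenance tag (default "none").
#' @return a \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, sampleData, featureData = NULL,
                          normalization = "none") {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("values must have feature ids as column names")
  assay <- t(values)
  colnames(assay) <- sampleData$sample_id
  rd <- if (is.null(featureData)) {
    S4Vectors::DataFrame(feature_id = rownames(assay))
  } else S4Vectors::DataFrame(featureData)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = assay),
    colData = S4Vectors::DataFrame(sampleData), rowData = rd)
  out <- new("FeatureMatrix", se)
  S4Vectors::metadata(out)$normalization <- normalization
  out
}

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d features (%s normalized)\n",
              ncol(object), nrow(object),
              S4Vectors::metadata(object)$normalization %||% "none"))
  callNextMethod()
})

#' @describeIn FeatureMatrix samples x features value matrix.
#' @param object a \code{FeatureMatrix}.
#' @export
featureValues <- function(object) t(SummarizedExperiment::assay(object))

#' @describeIn FeatureMatrix sample metadata as a base data.frame.
#' @export
sampleInfo <- function(object)
  as.data.frame(SummarizedExperiment::colData(object))

#' @describeIn FeatureMatrix feature identifiers.
#' @export
featureIDs <- function(object) rownames(object)

`%||%` <- function(a, b) if (is.null(a)) b else a
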