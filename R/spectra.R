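# Spectral preprocessing: read/write, apodization + FT, chemical-shift
# calibration, exclusion-masked fixed-width binning, normalization, and
# window-based metabolite quantification.

#' Read a 1D spectrum from CSV or JCAMP-DX
#'
#' CSV layout: comment header lines \code{#key=value} carrying sample_id,
#' group, day and fluid, then a \code{ppm,intensity} table. JCAMP-DX:
#' AFFN \code{XYDATA=(X++(Y..Y))} with the same metadata in
#' \code{##$SAMPLEID} etc.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"csv"} or
#'   \code{"jcampdx"}.
#' @return a \linkS4class{Spectrum1D}.
#' @seealso \code{\link{writeSpectrum}}
#' @export
readSpectrum <- function(path, format = c("auto", "csv", "jcampdx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcampdx"
              else "csv"
  }
  if (format == "csv") readSpectrumCsv(path) else readSpectrumJcamp(path)
}

readSpectrumCsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  need <- c("sample_id", "group", "day", "fluid")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("spectrum CSV ", path, " is missing metadata: ",
         paste(miss, collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  tab <- tryCatch(
    read.csv(text = paste(body, collapse = "\n")),
    error = function(e) stop("malformed spectrum CSV ", path, ": ",
                             conditionMessage(e)))
  if (!all(c("ppm", "intensity") %in% names(tab)))
    stop("spectrum CSV ", path, " must have columns ppm, intensity")
  Spectrum1D(tab$ppm, tab$intensity, meta$sample_id, meta$group, meta$day,
             meta$fluid, shift = as.numeric(meta$shift %||% 0))
}

#' Write a 1D spectrum to CSV or JCAMP-DX
#'
#' Round-trips through \code{\link{readSpectrum}} to better than 1e-9
#' relative in both formats.
#'
#' @param spectrum a \linkS4class{Spectrum1D}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"jcampdx"}.
#' @return invisibly, \code{path}.
#' @export
writeSpectrum <- function(spectrum, path, format = c("csv", "jcampdx")) {
  format <- match.arg(format)
  if (format == "csv") {
    m <- spectrumMeta(spectrum)
    hdr <- sprintf("#%s=%s", names(m), unlist(m))
    body <- sprintf("%.12g,%.12g", spectrum@ppm, spectrum@intensity)
    writeLines(c(hdr, "ppm,intensity", body), path)
  } else {
    writeSpectrumJcamp(spectrum, path)
  }
  invisible(path)
}

writeSpectrumJcamp <- function(spectrum, path) {
  x <- spectrum@ppm
  y <- spectrum@intensity
  n <- length(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##TITLE=1H NMR spectrum",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##$SAMPLEID=%s", spectrum@sampleID),
    sprintf("##$GROUP=%s", spectrum@group),
    sprintf("##$DAY=%s", spectrum@day),
    sprintf("##$FLUID=%s", spectrum@fluid),
    sprintf("##$SHIFT=%.12g", spectrum@shift),
    sprintf("##NPOINTS=%d", n),
    sprintf("##FIRSTX=%.12g", x[1]),
    sprintf("##LASTX=%.12g", x[n]),
    "##XFACTOR=1", "##YFACTOR=1",
    "##XYDATA=(X++(Y..Y))"), con)
  step <- 4L
  for (i in seq(1, n, by = step)) {
    j <- min(i + step - 1L, n)
    writeLines(paste(c(sprintf("%.12g", x[i]),
                       sprintf("%.12g", y[i:j])), collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}

readSpectrumJcamp <- function(path) {
  lines <- readLines(path)
  fields <- list()
  dataStart <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##")) {
      kv <- strsplit(sub("^##", "", ln), "=", fixed = TRUE)[[1]]
      key <- toupper(trimws(kv[1]))
      fields[[key]] <- trimws(paste(kv[-1], collapse = "="))
      if (startsWith(key, "XYDATA")) { dataStart <- i + 1L; break }
    }
  }
  if (is.na(dataStart))
    stop("malformed JCAMP-DX file ", path, ": no XYDATA block")
  for (k in c("NPOINTS", "FIRSTX", "LASTX", "$SAMPLEID", "$GROUP", "$DAY",
              "$FLUID")) {
    if (is.null(fields[[k]]))
      stop("JCAMP-DX file ", path, " is missing ##", k)
  }
  n <- as.integer(fields$NPOINTS)
  ys <- numeric(0)
  for (i in dataStart:length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "##")) break
    if (!nzchar(ln)) next
    vals <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
    if (anyNA(vals))
      stop("malformed JCAMP-DX data at line ", i, " of ", path, ": ", ln)
    ys <- c(ys, vals[-1] * as.numeric(fields$YFACTOR %||% "1"))
  }
  if (length(ys) != n)
    stop("JCAMP-DX file ", path, ": expected ", n, " points, found ",
         length(ys))
  x <- seq(as.numeric(fields$FIRSTX), as.numeric(fields$LASTX),
           length.out = n) * as.numeric(fields$XFACTOR %||% "1")
  Spectrum1D(x, ys, fields[["$SAMPLEID"]], fields[["$GROUP"]],
             fields[["$DAY"]], fields[["$FLUID"]],
             shift = as.numeric(fields[["$SHIFT"]] %||% "0"))
}

#' Apodize a FID and Fourier-transform it
#'
#' The FID is multiplied by the exponential window exp(-pi * lb * t) --
#' adding \code{lb} Hz to every line's width -- then Fourier-transformed;
#' the real part is returned on a ppm axis derived from the spectral width
#' and spectrometer frequency. Default broadening: 1 Hz for plasma, 0.3 Hz
#' for urine.
#'
#' @param fid a \linkS4class{Fid}.
#' @param lineBroadening exponential broadening factor in Hz (>= 0), or
#'   \code{NULL} to use the fluid default via \code{fluid}.
#' @param fluid used only to pick the default broadening.
#' @param meta list(sample_id, group, day, fluid) for the output spectrum.
#' @return a \linkS4class{Spectrum1D}.
#' @export
apodizeTransform <- function(fid, lineBroadening = NULL,
                             fluid = c("plasma", "urine"),
                             meta = list(sample_id = "fid", group = "C",
                                         day = "D8", fluid = NULL)) {
  fluid <- match.arg(fluid)
  if (is.null(lineBroadening))
    lineBroadening <- if (fluid == "plasma") 1 else 0.3
  if (lineBroadening < 0) stop("line broadening must be >= 0")
  if (fid@dwellTime <= 0) stop("dwell time must be positive")
  n <- length(fid@points)
  t <- (seq_len(n) - 1) * fid@dwellTime
  apodized <- fid@points * exp(-pi * lineBroadening * t)
  apodized[1] <- apodized[1] / 2  # first-point scaling for flat baseline
  spec <- fft(apodized)
  half <- n %/% 2
  spec <- c(spec[(half + 1):n], spec[1:half])  # fftshift
  sw <- 1 / fid@dwellTime
  freq <- (seq_len(n) - 1 - half) * sw / n
  axis <- fid@carrierPpm + freq / fid@frequency
  Spectrum1D(axis, Re(spec), meta$sample_id, meta$group, meta$day,
             meta$fluid %||% fluid)
}

#' Calibrate the chemical-shift axis against a reference resonance
#'
#' Detects the reference inside a search window (running-mean smoothed
#' maximum; for a doublet, the midpoint of the two strongest local maxima)
#' and shifts the whole axis so it lands on the nominal position.
#' Fluid defaults: plasma uses the lactate doublet at 1.33 ppm, urine the
#' TSP singlet at 0.00 ppm. Intensities are untouched and the applied
#' shift accumulates in the spectrum's \code{shift} field.
#'
#' @param spectrum a \linkS4class{Spectrum1D}.
#' @param nominal reference position, ppm (default by fluid).
#' @param window search window c(low, high), ppm (default nominal +- 0.1).
#' @param doublet detect a doublet midpoint instead of a single maximum
#'   (default TRUE for plasma).
#' @return the calibrated \linkS4class{Spectrum1D}.
#' @export
calibrateSpectrum <- function(spectrum, nominal = NULL, window = NULL,
                              doublet = NULL) {
  if (is.null(nominal))
    nominal <- if (spectrum@fluid == "plasma") 1.33 else 0.00
  if (is.null(window)) window <- nominal + c(-0.1, 0.1)
  if (is.null(doublet)) doublet <- spectrum@fluid == "plasma"
  inWin <- spectrum@ppm >= window[1] & spectrum@ppm <= window[2]
  if (sum(inWin) < 5)
    stop("search window contains too few points; widen the window")
  x <- rev(spectrum@ppm[inWin])      # ascending for detection
  y <- rev(spectrum@intensity[inWin])
  k <- 5
  ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  # point-to-point differences estimate the noise level robustly even when
  # the window holds several genuine resonances
  noise <- mad(diff(y)) / sqrt(2)
  floorLevel <- median(ys) + 5 * noise
  if (max(ys) <= floorLevel)
    stop("no reference peak above the noise floor in [",
         window[1], ", ", window[2], "] ppm; widen the window")
  if (doublet) {
    # doublet = two local maxima separated by roughly one J (7 Hz);
    # take the strongest such pair, fall back to the global maximum
    imax <- which(diff(sign(diff(ys))) < 0) + 1L
    imax <- imax[ys[imax] > floorLevel]
    j <- 7 / SPECTROMETER_MHZ
    found <- x[which.max(ys)]
    if (length(imax) >= 2) {
      best <- -Inf
      for (a in seq_along(imax)) for (b in seq_along(imax)) {
        if (b <= a) next
        sep <- abs(x[imax[b]] - x[imax[a]])
        if (sep > 0.5 * j && sep < 1.5 * j &&
            ys[imax[a]] + ys[imax[b]] > best) {
          best <- ys[imax[a]] + ys[imax[b]]
          found <- (x[imax[a]] + x[imax[b]]) / 2
        }
      }
    }
  } else {
    found <- x[which.max(ys)]
  }
  shift <- nominal - found
  spectrum@ppm <- spectrum@ppm + shift
  spectrum@shift <- spectrum@shift + shift
  validObject(spectrum)
  spectrum
}

#' Binning specification
#'
#' @param region retained region c(low, high), ppm.
#' @param spacing bin width, ppm.
#' @param exclusions list of c(low, high) windows removed from the region.
#' @return a validated list with class \code{bin_spec}.
#' @export
binSpec <- function(region, spacing, exclusions = list()) {
  if (length(region) != 2 || region[1] >= region[2])
    stop("region must be c(low, high) with low < high")
  if (spacing <= 0) stop("spacing must be positive")
  for (e in exclusions)
    if (e[1] >= e[2] || e[1] < region[1] - 1e-9 || e[2] > region[2] + 1e-9)
      stop("exclusion windows must be ordered and lie within the region")
  structure(list(region = as.numeric(region), spacing = as.numeric(spacing),
                 exclusions = exclusions), class = "bin_spec")
}

#' @describeIn binSpec plasma default: 0.5-9.0 ppm at 0.002 ppm spacing,
#'   excluding the urea (5.5-6.0) and residual-water (4.54-5.23) windows
#'   (3655 retained bins).
#' @export
plasmaBinSpec <- function()
  binSpec(c(0.5, 9.0), 0.002, list(c(4.54, 5.23), c(5.5, 6.0)))

#' @describeIn binSpec urine default: 0.5-9.5 ppm at 0.005 ppm spacing,
#'   excluding 5.55-6.00 (urea) and 4.50-5.10 (water).
#' @export
urineBinSpec <- function()
  binSpec(c(0.5, 9.5), 0.005, list(c(4.50, 5.10), c(5.55, 6.00)))

# exact cumulative trapezoid evaluated at arbitrary positions on an
# ascending grid (piecewise-linear intensity assumption)
trapezoidAt <- function(x, y, at) {
  cum <- c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
  idx <- findInterval(at, x, rightmost.closed = TRUE)
  idx <- pmax(pmin(idx, length(x) - 1L), 1L)
  x0 <- x[idx]
  y0 <- y[idx]
  slope <- (y[idx + 1L] - y0) / (x[idx + 1L] - x0)
  d <- at - x0
  cum[idx] + d * (y0 + (y0 + slope * d)) / 2
}

#' Integrate a spectrum into fixed-width bins
#'
#' Bins of width \code{spec$spacing} tile the retained region; each bin
#' value is the trapezoidal integral of intensity over the bin (units:
#' intensity x ppm). Bins overlapping an exclusion window -- wholly or
#' partially -- are dropped, keeping all bins equal width. Bin ids are
#' centre ppm formatted to 6 decimals.
#'
#' @param spectrum a calibrated \linkS4class{Spectrum1D}.
#' @param spec a \code{\link{binSpec}}.
#' @return named numeric vector of bin integrals with attributes
#'   \code{centers} (numeric) and \code{meta} (sample metadata).
#' @export
binSpectrum <- function(spectrum, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  lo <- spec$region[1]; hi <- spec$region[2]
  if (lo < min(spectrum@ppm) - 1e-9 || hi > max(spectrum@ppm) + 1e-9)
    stop("bin region [", lo, ", ", hi, "] outside the spectrum axis")
  nb <- round((hi - lo) / spec$spacing)
  edges <- lo + (0:nb) * spec$spacing
  binLo <- edges[-(nb + 1)]
  binHi <- edges[-1]
  keep <- rep(TRUE, nb)
  eps <- 1e-9
  for (e in spec$exclusions)
    keep <- keep & (binHi <= e[1] + eps | binLo >= e[2] - eps)
  x <- rev(spectrum@ppm)
  y <- rev(spectrum@intensity)
  vals <- trapezoidAt(x, y, binHi[keep]) - trapezoidAt(x, y, binLo[keep])
  centers <- (binLo[keep] + binHi[keep]) / 2
  # descending ppm order, NMR convention
  ord <- order(centers, decreasing = TRUE)
  vals <- vals[ord]
  centers <- centers[ord]
  names(vals) <- sprintf("%.6f", centers)
  attr(vals, "centers") <- centers
  attr(vals, "meta") <- spectrumMeta(spectrum)
  vals
}

#' Assemble binned rows into a FeatureMatrix
#'
#' All rows must share identical feature ids. Samples are ordered by
#' (group, day, sample id) and features by descending ppm, so the stored
#' matrix is invariant to input order.
#'
#' @param rows list of feature rows from \code{\link{binSpectrum}} (or any
#'   named numeric vectors with a \code{meta} attribute).
#' @return a \linkS4class{FeatureMatrix}.
#' @export
assembleMatrix <- function(rows) {
  stopifnot(length(rows) >= 1)
  ref <- names(rows[[1]])
  for (i in seq_along(rows)) {
    ni <- names(rows[[i]])
    if (!identical(ni, ref)) {
      bad <- c(setdiff(ni, ref), setdiff(ref, ni),
               ni[ni != ref])[1]
      stop("row ", i, " has mismatching feature ids (first mismatch: ",
           bad, ")")
    }
  }
  meta <- do.call(rbind, lapply(rows, function(r) {
    m <- attr(r, "meta")
    data.frame(sample_id = m$sample_id, group = m$group, day = m$day,
               fluid = m$fluid, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(meta$sample_id)) stop("sample ids must be unique")
  values <- do.call(rbind, lapply(rows, as.numeric))
  colnames(values) <- ref
  ord <- order(match(meta$group, GROUP_LEVELS),
               match(meta$day, DAY_LEVELS), meta$sample_id)
  values <- values[ord, , drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  centers <- attr(rows[[1]], "centers")
  fd <- if (!is.null(centers)) {
    data.frame(feature_id = ref, ppm_center = centers)
  } else data.frame(feature_id = ref)
  FeatureMatrix(values, meta, featureData = fd)
}

#' Normalize a FeatureMatrix across samples
#'
#' \code{total_area} rescales every sample to the cohort-median total
#' integral; \code{pqn} (probabilistic quotient normalization) divides each
#' sample by the median quotient against the median spectrum, removing
#' per-sample dilution factors such as urine concentration differences.
#'
#' @param object a \linkS4class{FeatureMatrix}.
#' @param method \code{"none"}, \code{"total_area"} or \code{"pqn"}.
#' @return the normalized \linkS4class{FeatureMatrix}; the method and the
#'   per-sample scale factors are recorded in \code{metadata()}.
#' @export
normalizeMatrix <- function(object, method = c("none", "total_area",
                                               "pqn")) {
  method <- match.arg(method)
  if (method == "none") {
    S4Vectors::metadata(object)$normalization <- "none"
    return(object)
  }
  a <- SummarizedExperiment::assay(object)  # features x samples
  sums <- colSums(a)
  if (any(sums <= 0))
    stop("non-positive total intensity for sample(s): ",
         paste(colnames(a)[sums <= 0], collapse = ", "))
  if (method == "total_area") {
    target <- median(sums)
    fac <- sums / target
  } else {
    if (ncol(a) < 3) stop("pqn needs at least 3 samples")
    refSpec <- apply(a, 1, median)
    ok <- refSpec > 0
    if (!any(ok)) stop("pqn reference spectrum is all zero")
    fac <- vapply(seq_len(ncol(a)), function(j)
      median(a[ok, j] / refSpec[ok]), numeric(1))
  }
  a <- sweep(a, 2, fac, `/`)
  SummarizedExperiment::assay(object) <- a
  S4Vectors::metadata(object)$normalization <- method
  S4Vectors::metadata(object)$scale_factors <-
    setNames(fac, colnames(a))
  object
}

#' Assignment map from a peak library
#'
#' One window per multiplet, centre +- \code{halfWidth} ppm, merged when
#' overlapping and clipped against the bin specification's exclusions.
#' Windows falling entirely inside an exclusion are dropped.
#'
#' @param library a \linkS4class{PeakLibrary}.
#' @param spec a \code{\link{binSpec}} defining region and exclusions.
#' @param halfWidth window half-width, ppm (default 0.02).
#' @return named list: metabolite -> list of c(low, high) windows.
#' @export
defaultAssignments <- function(library, spec, halfWidth = 0.02) {
  insideExclusion <- function(w)
    any(vapply(spec$exclusions, function(e)
      w[1] >= e[1] && w[2] <= e[2], logical(1)))
  out <- list()
  for (m in libraryMetabolites(library)) {
    pp <- sort(library@peaks$ppm[library@peaks$metabolite == m])
    wins <- list()
    cur <- c(pp[1] - halfWidth, pp[1] + halfWidth)
    for (p in pp[-1]) {
      if (p - halfWidth <= cur[2]) cur[2] <- p + halfWidth
      else { wins <- c(wins, list(cur)); cur <- c(p - halfWidth,
                                                  p + halfWidth) }
    }
    wins <- c(wins, list(cur))
    wins <- Filter(function(w) !insideExclusion(w) &&
                     w[2] > spec$region[1] && w[1] < spec$region[2], wins)
    if (length(wins)) out[[m]] <- wins
  }
  out
}

#' Aggregate bins into named metabolite quantities
#'
#' Each metabolite's value is the sum of retained bin integrals whose
#' centres fall inside any of its assignment windows.
#'
#' @param object a binned \linkS4class{FeatureMatrix} with
#'   \code{ppm_center} feature annotation.
#' @param assignments named list metabolite -> list of c(low, high)
#'   windows (see \code{\link{defaultAssignments}}).
#' @return a metabolite-named \linkS4class{FeatureMatrix}.
#' @export
quantifyMetabolites <- function(object, assignments) {
  centers <- SummarizedExperiment::rowData(object)$ppm_center
  if (is.null(centers))
    stop("feature matrix has no ppm_center annotation; quantify from bins")
  a <- SummarizedExperiment::assay(object)  # bins x samples
  vals <- matrix(0, length(assignments), ncol(a),
                 dimnames = list(names(assignments), colnames(a)))
  for (m in names(assignments)) {
    sel <- rep(FALSE, length(centers))
    for (w in assignments[[m]]) {
      hit <- centers >= w[1] & centers <= w[2]
      if (!any(hit))
        stop("assignment window [", w[1], ", ", w[2], "] for ", m,
             " overlaps no retained bin")
      sel <- sel | hit
    }
    vals[m, ] <- colSums(a[sel, , drop = FALSE])
  }
  out <- FeatureMatrix(t(vals), sampleInfo(object),
                       featureData = data.frame(
                         feature_id = names(assignments),
                         metabolite = names(assignments)),
                       normalization =
                         S4Vectors::metadata(object)$normalization %||%
                           "none")
  out
}

#' Write a FeatureMatrix to CSV
#'
#' Samples as rows; leading metadata columns sample_id/group/day/fluid,
#' then one column per feature id.
#'
#' @param object a \linkS4class{FeatureMatrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFeatureMatrix <- function(object, path) {
  df <- cbind(sampleInfo(object)[c("sample_id", "group", "day", "fluid")],
              as.data.frame(featureValues(object), check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a FeatureMatrix written by \code{\link{writeFeatureMatrix}}
#' @param path CSV path.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  metaCols <- c("sample_id", "group", "day", "fluid")
  vals <- as.matrix(df[setdiff(names(df), metaCols)])
  rownames(vals) <- df$sample_id
  ids <- colnames(vals)
  centers <- suppressWarnings(as.numeric(ids))
  fd <- if (!anyNA(centers))
    data.frame(feature_id = ids, ppm_center = centers)
  else data.frame(feature_id = ids)
  FeatureMatrix(vals, df[metaCols], featureData = fd)
}
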