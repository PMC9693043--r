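# End-to-end orchestration: simulate (or load) -> preprocess -> model ->
# screen -> enrich, with one config, one seed, structured logging and a
# manifest of outputs.

comparisonLabel <- function(day) {
  n <- sub("^D", "", day)
  paste0("C", n, "-H", n)
}

defaultConfig <- function(fluid) {
  list(
    fluid = fluid,
    mode = "synthetic",
    seed = NULL,
    n_per_cell = 8L,
    days = DAY_LEVELS,
    effects = NULL,
    spectra_dir = NULL,
    tables = NULL,
    bin = list(spacing = if (fluid == "plasma") 0.002 else 0.005),
    normalize = if (fluid == "urine") "pqn" else "none",
    assignment_half_width = 0.02,
    scaling = "pareto",
    model = list(n_orth = 1L, folds = 7L, n_perm = 200L,
                 validate = FALSE),
    screen = list(alpha = 0.05, vip_top = 0.10, r_df = NULL,
                  report_r_df = 7),
    out_dir = NULL
  )
}

checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown config key ", where, "/", unknown[1])
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a plain list, injects the per-fluid
#' defaults (bin spacing 0.002 plasma / 0.005 urine, pqn for urine,
#' 200 permutations, 7 folds, alpha 0.05, VIP top 10%), and rejects
#' unknown keys naming their path.
#'
#' @param config file path or list.
#' @return a fully defaulted config list of class \code{run_config}.
#' @examples
#' cfg <- validateConfig(list(fluid = "plasma", mode = "synthetic",
#'                            seed = 1))
#' cfg$bin$spacing
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (is.null(config$fluid) || !config$fluid %in% FLUID_LEVELS)
    stop("config /fluid must be \"plasma\" or \"urine\"")
  def <- defaultConfig(config$fluid)
  checkKeys(config, names(def), "")
  for (sub in c("bin", "model", "screen"))
    if (!is.null(config[[sub]])) {
      if (!is.list(config[[sub]]))
        stop("config /", sub, " must be a mapping")
      checkKeys(config[[sub]],
                union(names(def[[sub]]),
                      c("region", "exclusions")[sub == "bin"]), sub)
      def[[sub]][names(config[[sub]])] <- config[[sub]]
    }
  flat <- setdiff(names(def), c("bin", "model", "screen"))
  def[intersect(names(config), flat)] <-
    config[intersect(names(config), flat)]
  cfg <- def
  if (!cfg$mode %in% c("synthetic", "spectra", "tables"))
    stop("config /mode must be synthetic, spectra or tables")
  if (cfg$mode == "synthetic" && is.null(cfg$seed))
    stop("config /seed is required in synthetic mode")
  if (cfg$mode == "spectra" &&
      (is.null(cfg$spectra_dir) || !dir.exists(cfg$spectra_dir)))
    stop("config /spectra_dir must name an existing directory")
  cfg$days <- as.character(unlist(cfg$days))
  cfg$n_per_cell <- as.integer(cfg$n_per_cell)
  if (is.null(cfg$screen$r_df))
    cfg$screen$r_df <- 2 * cfg$n_per_cell - 2
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Per-day OPLS-DA modelling and screening of a quantified cohort
#'
#' For every day present in the matrix, fits C-vs-H OPLS-DA on
#' Pareto-scaled values, computes correlation loadings, VIP, Welch t-test
#' p and fold change per metabolite on the unscaled values, and applies
#' the three-criterion screen. Optionally runs cross-validation,
#' permutation testing and CV-ANOVA per comparison.
#'
#' @param fm a metabolite-level \linkS4class{FeatureMatrix}.
#' @param nOrth orthogonal components (default 1; reduced automatically
#'   when the within-day matrix has too little rank).
#' @param folds CV folds (default 7).
#' @param nPerm permutations for validation (default 200; only used when
#'   \code{validate = TRUE}).
#' @param alpha,vipTop,rDf screening rule (defaults 0.05, 0.10, pooled
#'   df).
#' @param scaling scaling mode for the models (default "pareto").
#' @param validate run Q2/permutation/CV-ANOVA per comparison.
#' @param seed integer seed for fold assignment and permutations.
#' @return list(cells = long data.frame of screening cells, models =
#'   per-comparison summaries, volcano = per-comparison volcano
#'   data.frames).
#' @export
screenCohort <- function(fm, nOrth = 1, folds = 7, nPerm = 200,
                         alpha = 0.05, vipTop = 0.10, rDf = NULL,
                         scaling = "pareto", validate = FALSE, seed = 1) {
  info <- sampleInfo(fm)
  vals <- featureValues(fm)
  days <- intersect(DAY_LEVELS, unique(info$day))
  if (is.null(rDf)) rDf <- 2 * min(table(info$group, info$day)) - 2
  cells <- list()
  models <- list()
  volcano <- list()
  for (d in days) {
    sel <- info$day == d
    y <- info$group[sel]
    V <- vals[sel, , drop = FALSE]
    sc <- scaleFeatures(V, scaling)
    rk <- qr(sc$X)$rank
    no <- min(nOrth, max(0L, rk - 1L))
    model <- fitOPLSDA(sc$X, y, nOrth = no)
    stats <- data.frame(
      feature = colnames(vals),
      r = as.numeric(corrLoadings(model)),
      vip = as.numeric(vipScores(model)),
      p = apply(V, 2, groupTTest, groups = y),
      fold_change = apply(V, 2, foldChange, groups = y),
      stringsAsFactors = FALSE)
    scr <- screenComparison(stats, alpha = alpha, rDf = rDf,
                            vipTop = vipTop)
    cmp <- comparisonLabel(d)
    scr$comparison <- cmp
    cells[[cmp]] <- scr
    summary <- list(comparison = cmp, day = d, n = nrow(V),
                    n_orth = no, R2X = model@R2X, R2Y = model@R2Y,
                    n_significant = sum(scr$significant))
    if (validate) {
      cv <- crossValidate(sc$X, y, "oplsda", nOrth = no, folds = folds,
                          seed = seed)
      pt <- permutationTest(sc$X, y, "oplsda", nOrth = no, folds = folds,
                            nPerm = nPerm, seed = seed)
      an <- cvAnova(cv)
      summary$Q2 <- cv$Q2
      summary$perm_p_Q2 <- pt$pQ2
      summary$perm_p_R2Y <- pt$pR2Y
      summary$cv_anova_F <- an$F
      summary$cv_anova_p <- an$p
    }
    models[[cmp]] <- summary
    volcano[[cmp]] <- buildVolcano(scr)
  }
  list(cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
       models = models, volcano = volcano)
}

pipelineLog <- function(lines, stage, event, detail = "") {
  line <- sprintf("stage=%s event=%s %s", stage, event, detail)
  message(line)
  c(lines, line)
}

#' Run the full pipeline from a configuration
#'
#' Stages per fluid: simulate (or load spectra) -> calibrate -> bin ->
#' assemble -> normalize -> quantify -> per-day model + screen -> report
#' + counts (-> enrichment when a pathway file is configured via
#' \code{pathways}). In \code{tables} mode the modelling stages are
#' skipped and the configured report tables are loaded and counted.
#' Identical config and seed give identical outputs and manifest hash.
#'
#' @param config a \code{run_config}, list, or YAML/JSON path (see
#'   \code{\link{validateConfig}}).
#' @param pathways optional GMT path for over-representation analysis.
#' @return the run manifest (list), invisibly written to
#'   \code{manifest.json} when \code{out_dir} is set.
#' @export
runPipeline <- function(config, pathways = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else validateConfig(config)
  log <- character()
  outDir <- cfg$out_dir
  files <- character()
  emit <- function(name, writer) {
    if (is.null(outDir)) return(invisible(NULL))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(outDir, name)
    writer(path)
    files[[length(files) + 1]] <<- path
    invisible(path)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("NMRScreen")),
    # hash covers the analytic configuration, not the output location
    config_hash = rlang::hash(jsonlite::toJSON(
      cfg[sort(setdiff(names(cfg), "out_dir"))], auto_unbox = TRUE,
      null = "null", digits = NA)),
    fluid = cfg$fluid, mode = cfg$mode)

  if (cfg$mode == "tables") {
    log <- pipelineLog(log, "tables", "load")
    tabs <- lapply(cfg$tables, readScreeningTable)
    counts <- summarizeCounts(tabs)
    manifest$counts <- counts[c("per_fluid", "union", "intersection")]
    emit("counts.json", function(p)
      jsonlite::write_json(manifest$counts, p, auto_unbox = TRUE))
    emit("run.log", function(p) writeLines(log, p))
    emit("manifest.json", function(p)
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA))
    return(manifest)
  }

  spec <- if (cfg$fluid == "plasma") plasmaBinSpec() else urineBinSpec()
  if (!is.null(cfg$bin$region)) spec$region <- as.numeric(cfg$bin$region)
  spec$spacing <- cfg$bin$spacing
  if (!is.null(cfg$bin$exclusions))
    spec$exclusions <- lapply(cfg$bin$exclusions, as.numeric)

  library <- buildDefaultLibrary(cfg$fluid)
  if (cfg$mode == "synthetic") {
    log <- pipelineLog(log, "simulate", "start",
                       sprintf("seed=%d n_per_cell=%d", cfg$seed,
                               cfg$n_per_cell))
    design <- cohortDesign(cfg$fluid, nPerCell = cfg$n_per_cell,
                           days = cfg$days)
    eff <- if (is.null(cfg$effects)) effectSpec()
           else effectSpec(vapply(cfg$effects, `[[`, "", "metabolite"),
                           vapply(cfg$effects, `[[`, "", "day"),
                           vapply(cfg$effects, function(e)
                             as.numeric(e$fold_change), numeric(1)))
    sim <- simulateCohort(design, eff, seed = cfg$seed)
    spectra <- sim$spectra
    manifest$truth_effects <- nrow(sim$truth$effects)
  } else {
    log <- pipelineLog(log, "read", "start", cfg$spectra_dir)
    paths <- list.files(cfg$spectra_dir,
                        pattern = "\\.(csv|jdx|dx)$", full.names = TRUE)
    if (!length(paths)) stop("no spectra found in ", cfg$spectra_dir)
    spectra <- lapply(paths, readSpectrum)
  }

  log <- pipelineLog(log, "preprocess", "calibrate+bin",
                     sprintf("n_spectra=%d spacing=%g", length(spectra),
                             spec$spacing))
  rows <- lapply(spectra, function(s)
    binSpectrum(calibrateSpectrum(s), spec))
  fm <- assembleMatrix(rows)
  fm <- normalizeMatrix(fm, cfg$normalize)
  emit("matrix.csv", function(p) writeFeatureMatrix(fm, p))

  assignments <- defaultAssignments(library, spec,
                                    halfWidth = cfg$assignment_half_width)
  qm <- quantifyMetabolites(fm, assignments)
  log <- pipelineLog(log, "quantify", "done",
                     sprintf("n_metabolites=%d", nrow(qm)))

  res <- screenCohort(qm, nOrth = cfg$model$n_orth,
                      folds = cfg$model$folds, nPerm = cfg$model$n_perm,
                      alpha = cfg$screen$alpha,
                      vipTop = cfg$screen$vip_top, rDf = cfg$screen$r_df,
                      scaling = cfg$scaling,
                      validate = isTRUE(cfg$model$validate),
                      seed = if (is.null(cfg$seed)) 1 else cfg$seed)
  log <- pipelineLog(log, "screen", "done",
                     sprintf("n_cells=%d", nrow(res$cells)))
  report <- buildReport(
    transform(res$cells, metabolite = feature),
    displayThreshold = criticalR(cfg$screen$alpha,
                                 cfg$screen$report_r_df),
    fluid = cfg$fluid)
  counts <- summarizeCounts(setNames(list(reportSignificantOnly(report)),
                                     cfg$fluid))
  manifest$models <- res$models
  manifest$counts <- counts[c("per_fluid", "union", "intersection")]

  emit("report.csv", function(p) writeScreeningTable(report, p))
  emit("cells.json", function(p)
    jsonlite::write_json(res$cells, p, dataframe = "rows", digits = NA))
  for (cmp in names(res$volcano)) {
    local({
      cmp2 <- cmp
      emit(sprintf("volcano_%s.csv", gsub("[^A-Za-z0-9]", "_", cmp2)),
           function(p) write.csv(res$volcano[[cmp2]], p,
                                 row.names = FALSE))
    })
  }
  if (!is.null(pathways)) {
    pws <- readPathways(pathways)
    hits <- normalizeMetaboliteNames(
      unique(res$cells$feature[res$cells$significant]))
    bg <- normalizeMetaboliteNames(unique(res$cells$feature))
    enr <- ora(hits, bg, pws)
    manifest$n_enriched <- sum(enr$p_adj < 0.05)
    emit("enrich.csv", function(p) write.csv(enr, p, row.names = FALSE))
    log <- pipelineLog(log, "enrich", "done",
                       sprintf("n_pathways=%d", nrow(enr)))
  }
  emit("counts.json", function(p)
    jsonlite::write_json(manifest$counts, p, auto_unbox = TRUE))
  emit("run.log", function(p) writeLines(log, p))
  manifest$files <- if (is.null(outDir)) character() else
    basename(unlist(files))
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA))
  manifest
}

# restrict a screening table to cells that passed the three-criterion
# screen, so summarizeCounts counts screened metabolites rather than
# display-threshold survivors
reportSignificantOnly <- function(report) {
  cells <- report$cells
  if (!is.null(cells$significant))
    cells$r[!cells$significant] <- NA_real_
  report$cells <- cells
  report
}
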