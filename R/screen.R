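# Differential-metabolite screening: the three-criterion rule (t-test p,
# correlation loading r, VIP percentile), fold changes, volcano datasets,
# and masked report tables in the style of the study's printed tables.

#' Critical value of the correlation coefficient
#'
#' Converts the two-sided Student-t critical value at significance level
#' \code{alpha} with \code{df} degrees of freedom into the corresponding
#' threshold on a Pearson correlation: r* = t / sqrt(t^2 + df). At
#' alpha = 0.05 and df = 7 this gives 0.666 (the report-table display
#' threshold); at df = 14 (pooled two-group df for n = 8 per group) it
#' gives about 0.497, matching the volcano screening rule |r| > 0.5.
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return threshold in (0, 1).
#' @examples
#' round(criticalR(0.05, 7), 3)   # 0.666
#' round(criticalR(0.05, 14), 3)  # 0.497
#' @export
criticalR <- function(alpha = 0.05, df) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  t <- qt(1 - alpha / 2, df)
  t / sqrt(t^2 + df)
}

#' Group-mean fold change (H over C)
#'
#' @param values per-sample quantities.
#' @param groups matching C/H labels.
#' @return mean(H) / mean(C), or NA (masked) if either mean is
#'   non-positive.
#' @export
foldChange <- function(values, groups) {
  groups <- as.character(groups)
  if (!any(groups == "H") || !any(groups == "C"))
    stop("both groups C and H must be non-empty")
  mh <- mean(values[groups == "H"])
  mc <- mean(values[groups == "C"])
  if (mh <= 0 || mc <= 0) return(NA_real_)
  mh / mc
}

#' Two-sided two-sample t-test p value
#'
#' @param values per-sample quantities.
#' @param groups matching C/H labels.
#' @param variant \code{"welch"} (default; robust to unequal variances)
#'   or \code{"student"} (pooled).
#' @return p value in [0, 1]; degenerate zero-variance data yield 1 when
#'   the means are equal and ~0 otherwise.
#' @export
groupTTest <- function(values, groups, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  groups <- as.character(groups)
  h <- values[groups == "H"]
  c0 <- values[groups == "C"]
  if (length(h) < 2 || length(c0) < 2)
    stop("each group needs at least 2 samples")
  if (var(h) == 0 && var(c0) == 0)
    return(if (isTRUE(all.equal(mean(h), mean(c0)))) 1 else 0)
  t.test(h, c0, var.equal = variant == "student")$p.value
}

#' Screen one comparison with the three-criterion rule
#'
#' A feature is significant when all three conditions hold: p < alpha,
#' |r| at or above the correlation threshold, and VIP in the top
#' \code{vipTop} fraction of the comparison (at or above the
#' 1 - vipTop quantile, linear interpolation). Masked (NA) r or p never
#' passes.
#'
#' @param stats data.frame with columns \code{feature}, \code{r},
#'   \code{p}, \code{vip}, \code{fold_change}.
#' @param alpha t-test significance level (default 0.05).
#' @param rThreshold fixed correlation threshold; if NULL, computed as
#'   \code{criticalR(alpha, rDf)}.
#' @param rDf degrees of freedom for the correlation threshold (default
#'   pooled two-group df, 2 n - 2 = 14 at n = 8 per group).
#' @param vipTop top VIP fraction required (default 0.10).
#' @return the input with added columns \code{significant},
#'   \code{r_threshold}, \code{vip_cut}.
#' @export
screenComparison <- function(stats, alpha = 0.05, rThreshold = NULL,
                             rDf = 14, vipTop = 0.10) {
  need <- c("feature", "r", "p", "vip", "fold_change")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("stats is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(stats$feature))
    stop("duplicate feature ids in stats")
  thr <- if (is.null(rThreshold)) criticalR(alpha, rDf) else rThreshold
  vipCut <- quantile(stats$vip, 1 - vipTop, na.rm = TRUE, names = FALSE,
                     type = 7)
  out <- stats
  out$significant <- !is.na(out$p) & out$p < alpha &
    !is.na(out$r) & abs(out$r) >= thr &
    !is.na(out$vip) & out$vip >= vipCut
  out$r_threshold <- thr
  out$vip_cut <- vipCut
  out
}

#' Volcano dataset from screening cells
#'
#' One point per feature with computable fold change and p:
#' x = log2(fold change), y = -log10(p), size keyed by VIP, colour keyed
#' by |r|. Masked cells are skipped (and counted in the
#' \code{n_skipped} attribute).
#'
#' @param cells data.frame with columns \code{feature},
#'   \code{fold_change}, \code{p}, \code{vip}, \code{r}.
#' @return data.frame(feature, log2fc, neglog10p, vip, abs_r).
#' @export
buildVolcano <- function(cells) {
  ok <- !is.na(cells$fold_change) & !is.na(cells$p)
  out <- data.frame(feature = cells$feature[ok],
                    log2fc = log2(cells$fold_change[ok]),
                    neglog10p = -log10(cells$p[ok]),
                    vip = cells$vip[ok],
                    abs_r = abs(cells$r[ok]),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Canonical metabolite names
#'
#' Folds the spelling variants that occur across the plasma and urine
#' report vocabularies onto one canonical form (e.g. the truncated
#' "N,N-Dimethylglycin", and the Greek-alpha form of
#' alpha-ketoglutarate), so that union/intersection counting compares
#' like with like.
#'
#' @param x character vector of metabolite names.
#' @return canonicalized character vector.
#' @export
normalizeMetaboliteNames <- function(x) {
  x <- trimws(x)
  x <- gsub("\u03b1", "alpha", x)      # Greek alpha
  x <- gsub("\u2013|\u2014", "-", x)  # en/em dashes
  fixes <- c("N,N-Dimethylglycin" = "N,N-Dimethylglycine",
             "alpha-Ketoglutarate" = "alpha-Ketoglutarate",
             "Lactic acid" = "Lactate",
             "Citric acid" = "Citrate")
  hit <- x %in% names(fixes)
  x[hit] <- fixes[x[hit]]
  x
}

#' Build a masked screening report table
#'
#' Assembles per-comparison screening cells into a metabolite x
#' comparison table in the style of the study report: the correlation
#' loading is rendered as the literal \code{"/"} when |r| falls below the
#' display threshold (default \code{criticalR(0.05, 7)} = 0.666), while
#' the fold change is shown whenever computable.
#'
#' @param cells data.frame with columns \code{metabolite},
#'   \code{comparison} (e.g. "C8-H8"), \code{r}, \code{fold_change}, and
#'   optionally \code{p}, \code{vip}, \code{significant}.
#' @param displayThreshold |r| display cut (default criticalR(0.05, 7)).
#' @param fluid label stored with the table.
#' @return a \code{screening_table}: list(cells, wide, comparisons,
#'   metabolites, display_threshold, fluid).
#' @export
buildReport <- function(cells, displayThreshold = criticalR(0.05, 7),
                        fluid = NA_character_) {
  need <- c("metabolite", "comparison", "r", "fold_change")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cells[c("metabolite", "comparison")]))
    stop("duplicate metabolite/comparison cells")
  metabolites <- unique(cells$metabolite)
  comparisons <- unique(cells$comparison)
  if (!nrow(cells)) {
    return(structure(list(cells = cells,
                          wide = matrix(character(), 0, 0),
                          comparisons = character(),
                          metabolites = character(),
                          display_threshold = displayThreshold,
                          fluid = fluid),
                     class = "screening_table"))
  }
  rend <- function(r, fc) {
    rtxt <- ifelse(is.na(r) | abs(r) < displayThreshold, "/",
                   sprintf("%.3g", r))
    ftxt <- ifelse(is.na(fc), "/", sprintf("%.3g", fc))
    c(rtxt, ftxt)
  }
  wide <- matrix("/", length(metabolites), 2 * length(comparisons),
                 dimnames = list(metabolites,
                   as.vector(rbind(paste0("r_", comparisons),
                                   paste0("fc_", comparisons)))))
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    wide[cc$metabolite, c(paste0("r_", cc$comparison),
                          paste0("fc_", cc$comparison))] <-
      rend(cc$r, cc$fold_change)
  }
  structure(list(cells = cells, wide = wide, comparisons = comparisons,
                 metabolites = metabolites,
                 display_threshold = displayThreshold, fluid = fluid),
            class = "screening_table")
}

#' @export
print.screening_table <- function(x, ...) {
  cat(sprintf("Screening table (%s): %d metabolites x %d comparisons, ",
              x$fluid, length(x$metabolites), length(x$comparisons)))
  cat(sprintf("|r| display threshold %.3f\n", x$display_threshold))
  invisible(x)
}

#' Write a screening table to CSV (with "/" masking)
#' @param table a \code{screening_table}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeScreeningTable <- function(table, path) {
  df <- data.frame(Metabolite = rownames(table$wide),
                   table$wide, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a screening report table from CSV
#'
#' Accepts the packaged report fixtures (and anything written by
#' \code{\link{writeScreeningTable}}): a \code{Metabolite} column followed
#' by r/fold-change column pairs per comparison, with \code{"/"} marking
#' masked cells.
#'
#' @param path CSV path.
#' @param fluid label stored with the table.
#' @param displayThreshold |r| display threshold the table was built with
#'   (default criticalR(0.05, 7)).
#' @return a \code{screening_table} whose cells carry NA for masked
#'   entries.
#' @export
readScreeningTable <- function(path, fluid = NA_character_,
                               displayThreshold = criticalR(0.05, 7)) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "Metabolite")
    stop("first column must be Metabolite")
  rcols <- grep("^r_", names(df), value = TRUE)
  comparisons <- sub("^r_", "", rcols)
  cells <- do.call(rbind, lapply(comparisons, function(cmp) {
    rv <- df[[paste0("r_", cmp)]]
    fv <- df[[paste0("fc_", cmp)]]
    data.frame(metabolite = df$Metabolite, comparison = cmp,
               r = suppressWarnings(as.numeric(ifelse(rv == "/", NA, rv))),
               fold_change = suppressWarnings(
                 as.numeric(ifelse(fv == "/", NA, fv))),
               stringsAsFactors = FALSE)
  }))
  buildReport(cells, displayThreshold = displayThreshold, fluid = fluid)
}

#' Count reported metabolites per fluid, union and intersection
#'
#' A metabolite counts for a fluid when it has at least one unmasked
#' (significant) comparison in that fluid's table. Names are canonicalized
#' with \code{\link{normalizeMetaboliteNames}} before union/intersection
#' counting, and the counts satisfy inclusion-exclusion exactly.
#'
#' @param tables named list of \code{screening_table}s (one per fluid).
#' @return list(per_fluid, union, intersection, union_names).
#' @export
summarizeCounts <- function(tables) {
  hitNames <- lapply(tables, function(tb) {
    byMet <- tapply(!is.na(tb$cells$r), tb$cells$metabolite, any)
    normalizeMetaboliteNames(names(byMet)[byMet])
  })
  perFluid <- vapply(hitNames, function(x) length(unique(x)), integer(1))
  un <- unique(unlist(hitNames))
  inter <- if (length(hitNames) >= 2)
    length(Reduce(intersect, lapply(hitNames, unique)))
  else perFluid[[1]]
  list(per_fluid = perFluid, union = length(un), intersection = inter,
       union_names = sort(un))
}
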