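test_that("critical correlation thresholds match the t-distribution", {
  expect_equal(round(criticalR(0.05, 7), 3), 0.666)
  # pooled two-group df at n = 8 per group reproduces the ~0.5 volcano rule
  expect_equal(criticalR(0.05, 14), 0.497, tolerance = 1e-3)
  # strictly decreasing in df, increasing as alpha shrinks
  dfs <- c(1, 2, 5, 7, 14, 30, 100, 1000)
  thr <- vapply(dfs, criticalR, numeric(1), alpha = 0.05)
  expect_true(all(diff(thr) < 0))
  expect_lt(thr[length(thr)], 0.07)
  expect_gt(criticalR(0.01, 7), criticalR(0.05, 7))
  expect_error(criticalR(1.2, 7))
  expect_error(criticalR(0.05, 0))

  # |r| of an independent pair at n = 9 stays below 0.666 ~95% of draws
  below <- withr::with_seed(17, vapply(1:400, function(i)
    abs(cor(rnorm(9), rnorm(9))) < criticalR(0.05, 7), logical(1)))
  expect_gte(mean(below), 0.90)
})

test_that("fold change is oriented H over C and masks non-positive means", {
  g <- rep(c("H", "C"), each = 3)
  expect_equal(foldChange(c(2, 2, 2, 1, 1, 1), g), 2)
  expect_equal(foldChange(rep(1, 6), g), 1)
  expect_true(is.na(foldChange(c(-1, -1, -1, 1, 1, 1), g)))
  expect_error(foldChange(1:3, rep("H", 3)), "both groups")
  # reciprocal under group swap
  v <- c(3, 4, 5, 1, 2, 3)
  expect_equal(foldChange(v, g) * foldChange(v, rev(g)), 1,
               tolerance = 1e-12)
})

test_that("group t-tests behave at degeneracies and match a permutation oracle", {
  g <- rep(c("H", "C"), each = 4)
  expect_equal(groupTTest(rep(2, 8), g), 1)
  v <- c(10, 10, 10, 10, 0.001, 0.002, 0.001, 0.003)
  p <- groupTTest(v, g)
  expect_lt(p, 0.001)
  # permutation oracle: observed |mean diff| is the most extreme over all
  # 70 label assignments, so the exact permutation p is 2/70
  combs <- utils::combn(8, 4)
  d0 <- abs(mean(v[g == "H"]) - mean(v[g == "C"]))
  dall <- apply(combs, 2, function(idx)
    abs(mean(v[idx]) - mean(v[-idx])))
  expect_equal(mean(dall >= d0 - 1e-12), 2 / 70, tolerance = 1e-12)
  # equal sizes and variances: Welch = Student
  v2 <- c(1, 2, 3, 4, 2, 3, 4, 5)
  expect_equal(groupTTest(v2, g, "welch"), groupTTest(v2, g, "student"),
               tolerance = 1e-12)
})

test_that("the three-criterion screen conjoins its rules monotonically", {
  stats <- data.frame(
    feature = paste0("m", 1:20),
    r = c(0.9, 0.3, 0.9, 0.9, seq(0.1, 0.9, length.out = 16)),
    p = c(0.01, 0.01, 0.5, 0.01, rep(0.6, 16)),
    vip = c(3, 3, 3, 0.1, seq(0.1, 1.5, length.out = 16)),
    fold_change = 1.5)
  out <- screenComparison(stats, alpha = 0.05, rThreshold = 0.5,
                          vipTop = 0.10)
  expect_true(out$significant[1])     # all three conditions met
  expect_false(out$significant[2])    # |r| below threshold
  expect_false(out$significant[3])    # p too large
  expect_false(out$significant[4])    # VIP below the top-decile cut
  expect_equal(out$vip_cut[1],
               unname(quantile(stats$vip, 0.9, type = 7)))

  # raising any threshold never grows the significant set
  base <- sum(out$significant)
  harder <- list(
    screenComparison(stats, alpha = 0.01, rThreshold = 0.5),
    screenComparison(stats, alpha = 0.05, rThreshold = 0.8),
    screenComparison(stats, alpha = 0.05, rThreshold = 0.5,
                     vipTop = 0.05))
  for (h in harder) expect_lte(sum(h$significant), base)
  expect_error(screenComparison(stats[, -2]), "missing column")
})

test_that("volcano coordinates are the log-transformed cell values", {
  cells <- data.frame(feature = c("a", "b", "c", "d"),
                      fold_change = c(1, 2, 0.5, NA),
                      p = c(1, 0.1, 0.01, 0.5),
                      vip = c(1, 2, 3, 4), r = c(0, 0.5, -0.9, 0.2))
  v <- buildVolcano(cells)
  expect_equal(v$log2fc, c(0, 1, -1))
  expect_equal(v$neglog10p, c(0, 1, 2))
  expect_equal(v$abs_r, c(0, 0.5, 0.9))
  expect_equal(attr(v, "n_skipped"), 1)
})

test_that("report tables mask sub-threshold correlations with '/'", {
  cells <- data.frame(
    metabolite = rep(c("Citrate", "Lactate"), each = 2),
    comparison = rep(c("C8-H8", "C20-H20"), 2),
    r = c(0.70, 0.60, -0.88, NA),
    fold_change = c(0.8, 1.2, NA, 1.1))
  tab <- buildReport(cells, displayThreshold = 0.666)
  expect_s3_class(tab, "screening_table")
  expect_equal(tab$wide["Citrate", "r_C20-H20"], "/")   # |r| = 0.60
  expect_equal(tab$wide["Citrate", "r_C8-H8"], "0.7")
  expect_equal(tab$wide["Lactate", "fc_C8-H8"], "/")    # masked fc
  # round-trip through CSV
  f <- withr::local_tempfile(fileext = ".csv")
  writeScreeningTable(tab, f)
  back <- readScreeningTable(f)
  expect_equal(back$wide, tab$wide)
  expect_error(buildReport(rbind(cells, cells)), "duplicate")
  empty <- buildReport(cells[0, ])
  expect_length(empty$metabolites, 0)
})

test_that("fixture report tables reproduce the reference counts", {
  t1 <- readScreeningTable(fixturePath("table1_plasma.csv"),
                           fluid = "plasma")
  t2 <- readScreeningTable(fixturePath("table2_urine.csv"),
                           fluid = "urine")
  expect_length(t1$metabolites, 30)
  expect_length(t1$comparisons, 5)
  expect_length(t2$metabolites, 29)
  cc <- summarizeCounts(list(plasma = t1, urine = t2))
  expect_equal(unname(cc$per_fluid), c(30L, 29L))
  expect_equal(cc$union, 50L)
  expect_equal(cc$intersection, 9L)
  # inclusion-exclusion holds exactly
  expect_equal(cc$union + cc$intersection, sum(cc$per_fluid))
  # every unmasked |r| in the fixtures clears the display threshold
  expect_true(all(abs(t1$cells$r) > 0.666, na.rm = TRUE))
  expect_true(all(abs(t2$cells$r) > 0.666, na.rm = TRUE))
  # the masked lipid-envelope rows keep r with fold change masked
  lip <- t1$cells[t1$cells$metabolite == "Lipid" &
                    t1$cells$comparison == "C8-H8", ]
  expect_equal(lip$r, 0.726)
  expect_true(is.na(lip$fold_change))
})

test_that("name normalization folds the report spelling variants", {
  expect_equal(normalizeMetaboliteNames("N,N-Dimethylglycin"),
               "N,N-Dimethylglycine")
  expect_equal(normalizeMetaboliteNames("α-Ketoglutarate"),
               "alpha-Ketoglutarate")
  expect_equal(normalizeMetaboliteNames(" Citrate "), "Citrate")
})

test_that("the screen recovers a planted effect from concentrations", {
  lib <- buildDefaultLibrary("plasma")
  bl <- defaultBaseLevels(lib)
  d <- cohortDesign("plasma", nPerCell = 8, days = "D8",
                    sigmaLog = 0.15)
  eff <- effectSpec("Glutamine", "D8", 2)
  hits <- vapply(1:30, function(s) {
    tr <- sampleConcentrations(d, eff, bl, seed = 500 + s)
    fm <- FeatureMatrix(tr$concentrations, tr$samples)
    res <- screenCohort(fm, validate = FALSE, seed = s)
    sig <- res$cells$feature[res$cells$significant]
    ("Glutamine" %in% sig) && length(sig) <= 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
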