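test_that("scaling modes follow their definitions", {
  X <- cbind(a = c(1, 3), b = c(0, 4), c = c(5, 5))
  sc <- scaleFeatures(X, "center")
  expect_equal(unname(sc$X[, "a"]), c(-1, 1))
  expect_true(sc$model$constant["c"])
  expect_equal(unname(sc$X[, "c"]), c(0, 0))

  # pareto scaling halves the variance exponent: sd 4 -> 2
  withr::with_seed(1, {
    x <- rnorm(50)
    x <- (x - mean(x)) / sd(x) * 4
  })
  Xp <- cbind(a = x, b = rnorm(50))
  sp <- scaleFeatures(Xp, "pareto")
  expect_equal(sd(sp$X[, "a"]), 2, tolerance = 1e-9)
  expect_equal(sd(scaleFeatures(Xp, "uv")$X[, "a"]), 1, tolerance = 1e-9)
})

test_that("PCA matches a dense eigendecomposition oracle", {
  withr::with_seed(11, X <- matrix(rnorm(6 * 4), 6, 4))
  colnames(X) <- paste0("v", 1:4)
  Xc <- scaleFeatures(X, "center")$X
  m <- fitPCA(Xc, 4)
  eig <- eigen(crossprod(Xc), symmetric = TRUE)
  expect_equal(m@R2X, eig$values[1:4] / sum(eig$values),
               tolerance = 1e-8)
  for (k in 1:4) {
    v <- eig$vectors[, k]
    expect_equal(abs(sum(m@loadings[, k] * v)), 1, tolerance = 1e-8)
  }
  # full-rank reconstruction
  expect_equal(m@scores %*% t(m@loadings), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign: largest-magnitude loading element positive
  for (k in 1:4)
    expect_gt(m@loadings[which.max(abs(m@loadings[, k])), k], 0)

  r1 <- tcrossprod(rnorm(5), rnorm(3))
  expect_equal(fitPCA(r1, 1)@R2X, 1, tolerance = 1e-9)
  expect_error(fitPCA(Xc, 6), "nComponents")
})

test_that("PLS-DA finds planted signal and reduces to simple regression", {
  tc <- randomTwoClass(100, 6, seed = 3)
  yc <- ifelse(tc$y == "H", 1, -1)
  X <- 0.3 * tc$X
  X[, 1] <- yc
  m <- fitPLSDA(scaleFeatures(X, "center")$X, tc$y, 1)
  expect_gt(abs(m@weights[1, 1]), 0.99)
  expect_gt(m@R2Y, 0.9)

  # null: R2Y stays small at large n
  withr::with_seed(5, {
    Xn <- matrix(rnorm(200 * 5), 200, 5)
    yn <- rep(c("C", "H"), each = 100)
  })
  expect_lt(fitPLSDA(scaleFeatures(Xn, "center")$X, yn, 1)@R2Y, 0.2)

  # one component, one feature: the simple least-squares fit of y on x
  withr::with_seed(6, x1 <- rnorm(12))
  y1 <- rep(c(-1, 1), 6)
  x1c <- x1 - mean(x1)
  m1 <- fitPLSDA(matrix(x1c, ncol = 1), y1, 1)
  beta <- sum(x1c * y1) / sum(x1c^2)
  expect_equal(predictY(m1, matrix(x1c, ncol = 1)),
               mean(y1) + beta * x1c, tolerance = 1e-9)
  expect_error(fitPLSDA(matrix(rnorm(10), 5, 2), rep("C", 5), 1),
               "two classes")
})

test_that("PLS-DA scores agree with an independent implementation", {
  tc <- randomTwoClass(16, 8, seed = 8)
  yc <- ifelse(tc$y == "H", 1, -1)
  X <- scaleFeatures(tc$X, "center")$X
  m <- fitPLSDA(X, tc$y, 2)
  ref <- mixOmics::pls(X, yc, ncomp = 2, mode = "regression",
                       scale = FALSE)
  for (k in 1:2)
    expect_gt(abs(cor(m@scores[, k], ref$variates$X[, k])), 1 - 1e-6)
})

test_that("OPLS-DA filters orthogonal variation and reduces to PLS", {
  tc <- randomTwoClass(16, 10, seed = 4)
  yc <- ifelse(tc$y == "H", 1, -1)
  X <- tc$X
  X[, 1] <- X[, 1] + 2 * yc
  Xs <- scaleFeatures(X, "pareto")$X

  # n_orth = 0 is the 1-component PLS-DA up to sign
  m0 <- fitOPLSDA(Xs, tc$y, 0)
  pls <- fitPLSDA(Xs, tc$y, 1)
  expect_equal(abs(m0@predictiveScores), abs(pls@scores[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)

  # every orthogonal score is uncorrelated with the class vector
  m1 <- fitOPLSDA(Xs, tc$y, 2)
  expect_lt(max(abs(cor(m1@orthoScores, yc))), 1e-8)
  expect_equal(mean(vipScores(m1)^2), 1, tolerance = 1e-8)
  expect_true(all(abs(corrLoadings(m1)) <= 1 + 1e-12))

  # a strong class-orthogonal direction hurts Q2 unless filtered
  withr::with_seed(9, {
    n <- 16; p <- 12
    yb <- rep(c(-1, 1), each = 8)
    ortho <- rnorm(n)
    ortho <- ortho - mean(ortho)
    ortho <- ortho - yb * sum(ortho * yb) / sum(yb^2)
    wsig <- c(rep(1, 4), rep(0, 8))
    worth <- c(rep(0, 8), rep(1, 4))
    Xq <- tcrossprod(yb, wsig) + 6 * tcrossprod(ortho, worth) +
      matrix(rnorm(n * p, 0, 0.3), n, p)
  })
  Xqs <- scaleFeatures(Xq, "center")$X
  q0 <- crossValidate(Xqs, yb, "oplsda", nOrth = 0, folds = 4,
                      seed = 1)$Q2
  q1 <- crossValidate(Xqs, yb, "oplsda", nOrth = 1, folds = 4,
                      seed = 1)$Q2
  expect_gte(q1, q0)

  expect_error(fitOPLSDA(Xs[, 1:2], tc$y, 5), "rank")
})

test_that("VIP follows the weighted-weights formula", {
  # 3 features, single component, w = (0.8, 0.6, 0):
  # VIP = sqrt(3 * w^2) = (1.386, 1.039, 0)
  X <- tcrossprod(c(-1, 1, -1, 1) * 2, c(0.8, 0.6, 0))
  y <- c("C", "H", "C", "H")
  m <- fitOPLSDA(X, y, 0)
  expect_equal(unname(computeVIP(m)),
               c(sqrt(3 * 0.64), sqrt(3 * 0.36), 0), tolerance = 1e-8)

  # single feature: VIP forced to 1
  m1 <- fitOPLSDA(matrix(c(-1, 1, -1, 1), ncol = 1), y, 0)
  expect_equal(unname(computeVIP(m1)), 1)

  # equal weights, two features: both 1
  X2 <- tcrossprod(c(-1, 1, -1, 1), c(1, 1))
  expect_equal(unname(computeVIP(fitOPLSDA(X2, y, 0))), c(1, 1),
               tolerance = 1e-8)

  # multi-component PLS VIP keeps mean(VIP^2) = 1
  tc <- randomTwoClass(14, 7, seed = 12)
  mp <- fitPLSDA(scaleFeatures(tc$X, "pareto")$X, tc$y, 3)
  expect_equal(mean(computeVIP(mp)^2), 1, tolerance = 1e-8)
})

test_that("correlation loadings are signed toward class H", {
  tc <- randomTwoClass(12, 4, seed = 13)
  Xs <- scaleFeatures(tc$X, "center")$X
  m <- fitOPLSDA(Xs, tc$y, 0)
  r <- correlationLoadings(m, Xs)
  expect_equal(unname(r[1]), cor(Xs[, 1], m@predictiveScores))
  # a column equal to the predictive score has r = 1, its negation -1
  X2 <- cbind(Xs, up = m@predictiveScores, down = -m@predictiveScores)
  r2 <- correlationLoadings(m, X2)
  expect_equal(unname(r2[c("up", "down")]), c(1, -1), tolerance = 1e-12)
  # predictive score is oriented toward H
  yc <- ifelse(tc$y == "H", 1, -1)
  expect_gte(cor(m@predictiveScores, yc), 0)
  # zero-variance column masked
  r3 <- correlationLoadings(m, cbind(Xs, flat = rep(1, 12)))
  expect_true(is.na(r3["flat"]))
})

test_that("cross-validation separates signal from permuted labels", {
  tc <- randomTwoClass(16, 8, seed = 14)
  yc <- ifelse(tc$y == "H", 1, -1)
  X <- tc$X
  X[, 1:3] <- X[, 1:3] + yc
  Xs <- scaleFeatures(X, "pareto")$X
  cv <- crossValidate(Xs, tc$y, "oplsda", folds = 7, seed = 2)
  expect_gt(cv$Q2, 0.5)

  # permuted labels: Q2 <= 0 in the majority of seeds
  qnull <- vapply(1:11, function(s) {
    yp <- withr::with_seed(100 + s, sample(tc$y))
    crossValidate(Xs, yp, "oplsda", folds = 7, seed = s)$Q2
  }, numeric(1))
  expect_gt(mean(qnull <= 0), 0.5)

  # leave-one-out boundary runs and is finite
  expect_true(is.finite(crossValidate(Xs, tc$y, "oplsda", folds = 16,
                                      seed = 3)$Q2))
})

test_that("permutation testing attains its minimal p on strong signal", {
  tc <- randomTwoClass(16, 6, seed = 15)
  yc <- ifelse(tc$y == "H", 1, -1)
  X <- tc$X
  X[, 1:2] <- X[, 1:2] + 2 * yc
  Xs <- scaleFeatures(X, "pareto")$X
  pt <- permutationTest(Xs, tc$y, "oplsda", nPerm = 200, seed = 4)
  expect_equal(pt$pR2Y, 1 / 201)
  expect_equal(pt$pQ2, 1 / 201)
  expect_length(pt$nullR2Y, 200)
  # add-one estimator can never reach 0
  expect_gt(min(pt$pR2Y, pt$pQ2), 0.004)
  # determinism
  pt2 <- permutationTest(Xs, tc$y, "oplsda", nPerm = 200, seed = 4)
  expect_identical(pt$nullQ2, pt2$nullQ2)
})

test_that("CV-ANOVA matches its F-ratio formula and flags degeneracy", {
  tc <- randomTwoClass(16, 6, seed = 16)
  yc <- ifelse(tc$y == "H", 1, -1)
  X <- tc$X
  X[, 1] <- X[, 1] + 3 * yc
  Xs <- scaleFeatures(X, "pareto")$X
  cv <- crossValidate(Xs, tc$y, "oplsda", folds = 7, seed = 5)
  an <- cvAnova(cv)
  d1 <- cv$nModelComponents
  d2 <- length(cv$y) - 1 - d1
  expect_equal(an$F, ((cv$ss - cv$press) / d1) / (cv$press / d2),
               tolerance = 1e-10)
  expect_lt(an$p, 0.001)

  # mean-only predictions: F ~ 0, p ~ 1
  cv0 <- cv
  cv0$predictions <- rep(mean(yc), 16)
  cv0$press <- sum((yc - mean(yc))^2)
  an0 <- cvAnova(cv0)
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)

  cvd <- cv
  cvd$press <- 0
  expect_true(cvAnova(cvd)$degenerate)
})
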