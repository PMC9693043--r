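# Latent-variable modelling. PCA uses mean-centred data; PLS-DA and
# OPLS-DA expect Pareto-scaled data, as is conventional for NMR binning
# tables. Class coding throughout: C = -1, H = +1, so positive weights,
# scores and correlation loadings mean "higher under hypoxia".

#' Scale the columns of a feature matrix
#'
#' \code{center} subtracts column means; \code{pareto} additionally divides
#' by the square root of the column SD (halving the variance exponent, the
#' usual compromise for NMR data where unit variance over-inflates noise
#' bins); \code{uv} divides by the SD. Constant columns pass through as
#' zeros and are flagged rather than failing.
#'
#' @param x a \linkS4class{FeatureMatrix} or samples x features matrix.
#' @param mode \code{"center"}, \code{"pareto"} or \code{"uv"}.
#' @return list(X = scaled samples x features matrix, model = list(mode,
#'   means, sds, constant)).
#' @examples
#' scaleFeatures(cbind(a = c(1, 3)), "center")$X
#' @export
scaleFeatures <- function(x, mode = c("center", "pareto", "uv")) {
  mode <- match.arg(mode)
  X <- if (is(x, "FeatureMatrix")) featureValues(x) else as.matrix(x)
  if (nrow(X) < 2) stop("scaling needs at least 2 samples")
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  constant <- sds == 0
  Xc <- sweep(X, 2, mu)
  div <- switch(mode, center = rep(1, ncol(X)), pareto = sqrt(sds),
                uv = sds)
  div[div == 0] <- 1  # constant columns: centred zeros pass through
  Xs <- sweep(Xc, 2, div, `/`)
  list(X = Xs, model = list(mode = mode, means = mu, sds = sds,
                            constant = constant))
}

codeClasses <- function(y) {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(-1, 1))) stop("numeric y must be coded -1/+1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  u <- sort(unique(y))
  if (length(u) != 2) stop("exactly two classes required, found: ",
                           paste(u, collapse = ", "))
  # C -> -1, H -> +1; otherwise alphabetical first -> -1
  if (all(u %in% GROUP_LEVELS)) ifelse(y == "H", 1, -1)
  else ifelse(y == u[2], 1, -1)
}

fixSign <- function(w) if (w[which.max(abs(w))] < 0) -w else w

#' Fit PCA by singular value decomposition
#'
#' Input is taken as already scaled (typically mean-centred). Components
#' are ordered by explained variance with a deterministic sign convention:
#' the largest-magnitude loading element is positive.
#'
#' @param X scaled samples x features matrix (or FeatureMatrix, used
#'   as-is).
#' @param nComponents number of components, at most min(n - 1, p).
#' @return a \linkS4class{PcaModel}.
#' @export
fitPCA <- function(X, nComponents = 2) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (nComponents > kmax)
    stop("nComponents must be <= min(samples - 1, features) = ", kmax)
  sv <- svd(X, nu = nComponents, nv = nComponents)
  P <- sv$v
  Tm <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  for (k in seq_len(nComponents)) {
    j <- which.max(abs(P[, k]))
    if (P[j, k] < 0) { P[, k] <- -P[, k]; Tm[, k] <- -Tm[, k] }
  }
  r2 <- sv$d[seq_len(nComponents)]^2 / sum(X^2)
  ids <- colnames(X) %||% sprintf("V%d", seq_len(ncol(X)))
  rownames(P) <- ids
  new("PcaModel", scores = Tm, loadings = P, R2X = r2, featureIDs = ids)
}

#' Fit PLS-DA (NIPALS with deflation, single binary response)
#'
#' @param X scaled samples x features matrix.
#' @param y class labels (C/H, a two-level factor, or -1/+1 coding).
#' @param nComponents number of latent components (>= 1).
#' @return a \linkS4class{PlsdaModel}.
#' @export
fitPLSDA <- function(X, y, nComponents = 2) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  yc <- codeClasses(y)
  if (length(unique(yc)) < 2) stop("both classes must be present")
  if (nComponents < 1) stop("nComponents must be >= 1")
  ym <- mean(yc)
  f <- yc - ym
  ss_y0 <- sum(f^2)
  ss_x0 <- sum(X^2)
  E <- X
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, nComponents)
  P <- matrix(0, p, nComponents)
  Tm <- matrix(0, n, nComponents)
  q <- numeric(nComponents)
  for (k in seq_len(nComponents)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { nComponents <- k - 1L; break }
    w <- fixSign(w / nw)
    t <- E %*% w
    tt <- sum(t^2)
    pvec <- crossprod(E, t) / tt
    qk <- sum(f * t) / tt
    E <- E - t %*% t(pvec)
    f <- f - qk * t
    W[, k] <- w; P[, k] <- pvec; Tm[, k] <- t; q[k] <- qk
  }
  if (nComponents < 1) stop("X carries no covariance with y")
  keep <- seq_len(nComponents)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]
  r2y <- 1 - sum(f^2) / ss_y0
  r2x <- 1 - sum(E^2) / ss_x0
  ids <- colnames(X) %||% sprintf("V%d", seq_len(p))
  rownames(W) <- rownames(P) <- ids
  new("PlsdaModel", weights = W, loadings = P, yloadings = q, scores = Tm,
      R2X = r2x, R2Y = max(0, r2y), yMean = ym, featureIDs = ids)
}

#' Fit OPLS-DA (orthogonal signal filtering + one predictive component)
#'
#' Iteratively removes \code{nOrth} components of X-variation orthogonal
#' to the class vector, then fits a single predictive PLS component on the
#' filtered matrix. With \code{nOrth = 0} the predictive component equals
#' the first PLS-DA component (up to sign).
#'
#' @param X scaled samples x features matrix.
#' @param y class labels (C/H or -1/+1).
#' @param nOrth number of orthogonal components (>= 0, < rank(X)).
#' @return an \linkS4class{OplsdaModel} with per-feature VIP and
#'   correlation loadings.
#' @export
fitOPLSDA <- function(X, y, nOrth = 1) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  yc <- codeClasses(y)
  if (length(unique(yc)) < 2) stop("both classes must be present")
  rk <- qr(X)$rank
  if (nOrth >= rk)
    stop("nOrth (", nOrth, ") must be smaller than rank(X) = ", rk)
  ym <- mean(yc)
  f <- yc - ym
  n <- nrow(X); p <- ncol(X)
  E <- X
  To <- matrix(0, n, nOrth)
  Wo <- matrix(0, p, nOrth)
  Po <- matrix(0, p, nOrth)
  w <- crossprod(X, f)
  w <- w / sqrt(sum(w^2))
  if (nOrth > 0) {
    for (k in seq_len(nOrth)) {
      t <- E %*% w / sum(w^2)
      pvec <- crossprod(E, t) / sum(t^2)
      wo <- pvec - as.numeric(crossprod(w, pvec)) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12)
        stop("no orthogonal variation left at component ", k)
      wo <- fixSign(wo / nwo)
      to <- E %*% wo
      po <- crossprod(E, to) / sum(to^2)
      E <- E - to %*% t(po)
      To[, k] <- to; Wo[, k] <- wo; Po[, k] <- po
    }
  }
  # predictive component on the filtered matrix
  wp <- crossprod(E, f)
  wp <- fixSign(as.numeric(wp / sqrt(sum(wp^2))))
  tp <- as.numeric(E %*% wp)
  tt <- sum(tp^2)
  pp <- as.numeric(crossprod(E, tp) / tt)
  qv <- sum(f * tp) / tt
  # orient the predictive score toward class H (+1)
  if (qv < 0) { wp <- -wp; tp <- -tp; pp <- -pp; qv <- -qv }
  r2y <- 1 - sum((f - qv * tp)^2) / sum(f^2)
  explained <- tp %*% t(pp)
  if (nOrth > 0) explained <- explained + To %*% t(Po)
  r2x <- sum(explained^2) / sum(X^2)
  vip <- sqrt(p) * abs(wp)  # single predictive component
  sds <- apply(X, 2, sd)
  r <- rep(NA_real_, p)
  ok <- sds > 0
  r[ok] <- as.numeric(cor(X[, ok, drop = FALSE], tp))
  ids <- colnames(X) %||% sprintf("V%d", seq_len(p))
  rownames(Wo) <- rownames(Po) <- ids
  new("OplsdaModel", predictiveScores = tp, predictiveWeights = wp,
      predictiveLoadings = pp, yloading = qv, orthoScores = To,
      orthoWeights = Wo, orthoLoadings = Po, nOrth = as.integer(nOrth),
      vip = setNames(vip, ids), r = setNames(r, ids),
      R2X = r2x, R2Y = max(0, r2y), yMean = ym, featureIDs = ids)
}

#' Predict the coded response for new samples
#'
#' @param model a \linkS4class{PlsdaModel} or \linkS4class{OplsdaModel}.
#' @param Xnew samples x features matrix on the training scale.
#' @return numeric predictions of the coded response (around -1/+1).
#' @export
predictY <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (is(model, "OplsdaModel")) {
    E <- Xnew
    if (model@nOrth > 0) {
      for (k in seq_len(model@nOrth)) {
        to <- E %*% model@orthoWeights[, k]
        E <- E - to %*% t(model@orthoLoadings[, k])
      }
    }
    tp <- E %*% model@predictiveWeights
    as.numeric(model@yMean + model@yloading * tp)
  } else {
    W <- model@weights; P <- model@loadings; q <- model@yloadings
    B <- W %*% solve(crossprod(P, W), q)
    as.numeric(model@yMean + Xnew %*% B)
  }
}

#' Variable importance in projection
#'
#' VIP_j = sqrt(F * sum_k SSY_k (w_jk / ||w_k||)^2 / sum_k SSY_k) with F
#' the number of features and SSY_k the Y sum of squares explained by
#' component k; squared VIPs average to 1 by construction. For OPLS-DA the
#' predictive component alone carries the class information, so VIP
#' reduces to sqrt(F) |w_p|.
#'
#' @param model a fitted \linkS4class{PlsdaModel} or
#'   \linkS4class{OplsdaModel}.
#' @return named per-feature VIP vector.
#' @export
computeVIP <- function(model) {
  if (is(model, "OplsdaModel")) return(model@vip)
  if (!is(model, "PlsdaModel")) stop("need a fitted PLS-DA/OPLS-DA model")
  W <- model@weights
  Tm <- model@scores
  q <- model@yloadings
  ssy <- q^2 * colSums(Tm^2)
  p <- nrow(W)
  wnorm <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
  vip <- sqrt(p * as.numeric(wnorm^2 %*% ssy) / sum(ssy))
  setNames(vip, model@featureIDs)
}

#' Correlation loadings against the predictive score
#'
#' Pearson correlation between each (scaled) feature and the predictive
#' score, oriented so positive r means higher levels in class H.
#' Zero-variance features are returned as NA.
#'
#' @param model an \linkS4class{OplsdaModel}.
#' @param X the scaled matrix the model was fitted on.
#' @return named per-feature correlation vector in [-1, 1].
#' @export
correlationLoadings <- function(model, X) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  tp <- model@predictiveScores
  sds <- apply(X, 2, sd)
  r <- rep(NA_real_, ncol(X))
  ok <- sds > 0
  r[ok] <- as.numeric(cor(X[, ok, drop = FALSE], tp))
  setNames(r, colnames(X) %||% model@featureIDs)
}

stratifiedFolds <- function(y, folds, seed) {
  yc <- codeClasses(y)
  id <- integer(length(yc))
  withr::with_seed(seed, {
    for (cls in unique(yc)) {
      idx <- sample(which(yc == cls))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  id
}

#' Cross-validated predictive ability Q2
#'
#' Class-stratified K-fold cross-validation; Q2 = 1 - PRESS / SS over the
#' centred class vector. Every training split must contain both classes.
#' Negative Q2 is reported as-is.
#'
#' @param X scaled samples x features matrix.
#' @param y class labels.
#' @param method \code{"oplsda"} or \code{"plsda"}.
#' @param nOrth orthogonal components (oplsda).
#' @param nComponents components (plsda).
#' @param folds number of folds (default 7; \code{folds = n} gives
#'   leave-one-out).
#' @param seed integer seed for the fold assignment.
#' @return list(Q2, press, ss, predictions, y, folds, nModelComponents).
#' @export
crossValidate <- function(X, y, method = c("oplsda", "plsda"), nOrth = 1,
                          nComponents = 1, folds = 7, seed = 1) {
  method <- match.arg(method)
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  yc <- codeClasses(y)
  folds <- min(folds, nrow(X))
  if (folds < 2) stop("folds must be >= 2")
  id <- stratifiedFolds(yc, folds, seed)
  pred <- numeric(length(yc))
  for (k in seq_len(folds)) {
    tr <- id != k
    if (length(unique(yc[tr])) < 2)
      stop("fold ", k, " leaves a single-class training set; ",
           "reduce folds or rebalance")
    m <- if (method == "oplsda")
      fitOPLSDA(X[tr, , drop = FALSE], yc[tr],
                nOrth = min(nOrth, qr(X[tr, , drop = FALSE])$rank - 1L))
    else fitPLSDA(X[tr, , drop = FALSE], yc[tr], nComponents)
    pred[!tr] <- predictY(m, X[!tr, , drop = FALSE])
  }
  press <- sum((yc - pred)^2)
  ss <- sum((yc - mean(yc))^2)
  ncomp <- if (method == "oplsda") 1L + as.integer(nOrth)
           else as.integer(nComponents)
  list(Q2 = 1 - press / ss, press = press, ss = ss, predictions = pred,
       y = yc, folds = folds, nModelComponents = ncomp)
}

#' Permutation test of R2Y and Q2
#'
#' The class vector is permuted uniformly \code{nPerm} times (default 200)
#' and the model refitted each time; empirical p values use the add-one
#' estimator (1 + exceedances) / (nPerm + 1), so the smallest attainable p
#' at the default is 1/201.
#'
#' @param X scaled samples x features matrix.
#' @param y class labels.
#' @param method,nOrth,nComponents,folds model specification as in
#'   \code{\link{crossValidate}}.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list(nPerm, observedR2Y, observedQ2, nullR2Y, nullQ2, pR2Y,
#'   pQ2) of class \code{permutation_result}.
#' @export
permutationTest <- function(X, y, method = c("oplsda", "plsda"),
                            nOrth = 1, nComponents = 1, folds = 7,
                            nPerm = 200, seed = 1) {
  method <- match.arg(method)
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  yc <- codeClasses(y)
  if (nPerm < 1) stop("nPerm must be >= 1")
  fitR2Y <- function(yy) {
    m <- if (method == "oplsda") fitOPLSDA(X, yy, nOrth)
         else fitPLSDA(X, yy, nComponents)
    m@R2Y
  }
  obsR2Y <- fitR2Y(yc)
  obsQ2 <- crossValidate(X, yc, method, nOrth, nComponents, folds,
                         seed = seed)$Q2
  perms <- withr::with_seed(seed,
    replicate(nPerm, sample(yc), simplify = FALSE))
  nullR2Y <- numeric(nPerm)
  nullQ2 <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    yp <- perms[[b]]
    nullR2Y[b] <- fitR2Y(yp)
    nullQ2[b] <- crossValidate(X, yp, method, nOrth, nComponents, folds,
                               seed = seed + b)$Q2
  }
  structure(list(nPerm = nPerm, observedR2Y = obsR2Y, observedQ2 = obsQ2,
                 nullR2Y = nullR2Y, nullQ2 = nullQ2,
                 pR2Y = (1 + sum(nullR2Y >= obsR2Y)) / (nPerm + 1),
                 pQ2 = (1 + sum(nullQ2 >= obsQ2)) / (nPerm + 1)),
            class = "permutation_result")
}

#' CV-ANOVA significance test of a cross-validated model
#'
#' F test comparing the Y variation explained by the cross-validated
#' predictions against the predictive residual sum of squares (PRESS),
#' following the published CV-ANOVA formulation for PLS/OPLS models:
#' F = ((SS - PRESS) / d1) / (PRESS / d2) with d1 = number of model
#' components and d2 = n - 1 - d1.
#'
#' @param cv result of \code{\link{crossValidate}}.
#' @return list(F, df1, df2, p) of class \code{cv_anova}; degenerate
#'   all-zero residuals are flagged and reported as p below machine
#'   epsilon.
#' @export
cvAnova <- function(cv) {
  ss <- cv$ss
  press <- cv$press
  d1 <- cv$nModelComponents
  d2 <- length(cv$y) - 1L - d1
  if (d2 < 1) stop("too few samples for CV-ANOVA with ", d1,
                   " model components")
  if (press <= .Machine$double.eps * ss) {
    return(structure(list(F = Inf, df1 = d1, df2 = d2,
                          p = .Machine$double.eps, degenerate = TRUE),
                     class = "cv_anova"))
  }
  f <- max(0, ((ss - press) / d1) / (press / d2))
  structure(list(F = f, df1 = d1, df2 = d2,
                 p = pf(f, d1, d2, lower.tail = FALSE),
                 degenerate = FALSE),
            class = "cv_anova")
}
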