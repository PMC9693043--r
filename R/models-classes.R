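# S4 containers for the latent-variable models. Scores/loadings are stored
# per component; accessors avoid slot access in user code.

#' Principal component analysis model
#'
#' @slot scores samples x components score matrix T.
#' @slot loadings features x components loading matrix P (orthonormal).
#' @slot R2X per-component explained-variance ratio of the scaled matrix.
#' @slot featureIDs feature identifiers.
#' @export
setClass("PcaModel",
  representation(scores = "matrix", loadings = "matrix", R2X = "numeric",
                 featureIDs = "character"))

setValidity("PcaModel", function(object) {
  msg <- character()
  P <- object@loadings
  if (ncol(P)) {
    g <- crossprod(P)
    if (max(abs(g - diag(ncol(P)))) > 1e-8)
      msg <- c(msg, "loadings must be orthonormal")
  }
  if (any(diff(object@R2X) > 1e-9))
    msg <- c(msg, "explained variance must be non-increasing")
  if (sum(object@R2X) > 1 + 1e-9)
    msg <- c(msg, "explained variance ratios must sum to <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d components, R2X(cum) = %.3f\n",
              ncol(object@scores), sum(object@R2X)))
})

#' PLS-DA model (NIPALS, single binary response)
#'
#' Class membership is coded C = -1, H = +1 so that positive correlation
#' with the predictive score means higher levels in group H.
#'
#' @slot weights features x components weight matrix W (unit columns).
#' @slot loadings features x components X-loading matrix P.
#' @slot yloadings per-component y-loadings q.
#' @slot scores samples x components score matrix T.
#' @slot R2X,R2Y fractions of X and Y sum of squares explained.
#' @slot yMean mean of the coded response (removed before fitting).
#' @slot featureIDs feature identifiers.
#' @export
setClass("PlsdaModel",
  representation(weights = "matrix", loadings = "matrix",
                 yloadings = "numeric", scores = "matrix",
                 R2X = "numeric", R2Y = "numeric", yMean = "numeric",
                 featureIDs = "character"))

setValidity("PlsdaModel", function(object) {
  msg <- character()
  T <- object@scores
  if (ncol(T) > 1) {
    g <- crossprod(T)
    off <- g - diag(diag(g), ncol(g))
    if (max(abs(off)) > 1e-6 * max(diag(g)))
      msg <- c(msg, "score vectors must be mutually orthogonal")
  }
  if (object@R2Y < -1e-9 || object@R2Y > 1 + 1e-9)
    msg <- c(msg, "R2Y must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlsdaModel", function(object) {
  cat(sprintf("PlsdaModel: %d components, R2X = %.3f, R2Y = %.3f\n",
              ncol(object@scores), object@R2X, object@R2Y))
})

#' OPLS-DA model (one predictive + n orthogonal components)
#'
#' Structured-noise filtering in the Trygg-Wold style: variation in X
#' orthogonal to the class vector is peeled off into orthogonal components
#' before a single predictive PLS component is fitted.
#'
#' @slot predictiveScores predictive score vector t_p (samples).
#' @slot predictiveWeights unit weight vector w_p (features).
#' @slot predictiveLoadings X-loading p_p (features).
#' @slot yloading scalar y-loading q.
#' @slot orthoScores samples x n_orth orthogonal scores T_o.
#' @slot orthoWeights,orthoLoadings features x n_orth W_o and P_o.
#' @slot nOrth number of orthogonal components.
#' @slot vip per-feature variable importance in projection.
#' @slot r per-feature correlation loading (Pearson r with t_p, oriented
#'   so positive means higher in class H); NA for constant features.
#' @slot R2X,R2Y explained fractions of X and (coded) Y.
#' @slot yMean mean of the coded response.
#' @slot featureIDs feature identifiers.
#' @export
setClass("OplsdaModel",
  representation(predictiveScores = "numeric", predictiveWeights = "numeric",
                 predictiveLoadings = "numeric", yloading = "numeric",
                 orthoScores = "matrix", orthoWeights = "matrix",
                 orthoLoadings = "matrix", nOrth = "integer",
                 vip = "numeric", r = "numeric",
                 R2X = "numeric", R2Y = "numeric", yMean = "numeric",
                 featureIDs = "character"))

setValidity("OplsdaModel", function(object) {
  msg <- character()
  if (any(object@vip < -1e-12, na.rm = TRUE))
    msg <- c(msg, "VIP values must be non-negative")
  v2 <- mean(object@vip^2, na.rm = TRUE)
  if (abs(v2 - 1) > 1e-8)
    msg <- c(msg, "mean of squared VIP must equal 1")
  if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "correlation loadings must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OplsdaModel", function(object) {
  cat(sprintf(
    "OplsdaModel: 1 predictive + %d orthogonal, R2X = %.3f, R2Y = %.3f\n",
    object@nOrth, object@R2X, object@R2Y))
})

#' @describeIn OplsdaModel per-feature VIP accessor.
#' @param object a fitted model.
#' @export
vipScores <- function(object) object@vip

#' @describeIn OplsdaModel correlation-loading accessor.
#' @export
corrLoadings <- function(object) object@r

#' Score matrix of a fitted model
#' @param object a PcaModel, PlsdaModel or OplsdaModel.
#' @return samples x components matrix (predictive score first for OPLS-DA).
#' @export
modelScores <- function(object) {
  if (is(object, "OplsdaModel"))
    cbind(predictive = object@predictiveScores, object@orthoScores)
  else object@scores
}

#' Loading matrix of a fitted model
#' @param object a PcaModel, PlsdaModel or OplsdaModel.
#' @export
modelLoadings <- function(object) {
  if (is(object, "OplsdaModel"))
    cbind(predictive = object@predictiveLoadings, object@orthoLoadings)
  else object@loadings
}
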