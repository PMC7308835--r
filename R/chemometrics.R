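#' @include AllClasses.R
NULL

# ---- PLS (NIPALS, PLS1) -----------------------------------------------------

# Core NIPALS decomposition on mean-centred data. Returns the per-LV
# coefficient matrix B (p x A), so predictions at every LV count come
# from one decomposition. Extraction stops early if the residual
# covariance vanishes (perfect fit); remaining columns repeat the last.
.plsCore <- function(X, y, maxLV) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xMean <- colMeans(X); yMean <- mean(y)
  E <- sweep(X, 2, xMean); f <- y - yMean
  if (all(abs(f) < 1e-14)) stop("constant response: PLS undefined")
  if (all(abs(E) < 1e-14)) stop("degenerate spectra: zero variance everywhere")
  A <- min(maxLV, n - 1, p)
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  achieved <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-24) break
    pl <- crossprod(E, t_) / tt
    qa <- sum(f * t_) / tt
    E <- E - t_ %*% t(pl)
    f <- f - qa * t_
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
    achieved <- a
  }
  if (achieved == 0L) stop("PLS extracted no components")
  B <- matrix(0, p, A)
  for (a in seq_len(achieved)) {
    Wa <- W[, 1:a, drop = FALSE]
    Ba <- Wa %*% solve(crossprod(P[, 1:a, drop = FALSE], Wa), q[1:a])
    B[, a] <- Ba
  }
  if (achieved < A) for (a in (achieved + 1):A) B[, a] <- B[, achieved]
  list(xMean = xMean, yMean = yMean, W = W[, 1:achieved, drop = FALSE],
       P = P[, 1:achieved, drop = FALSE], q = q[1:achieved], B = B,
       achieved = achieved)
}

#' Fit a PLS calibration with RMSECV-selected latent variables
#'
#' NIPALS PLS1 on mean-centred spectra and response. The latent-variable
#' count is chosen at the minimum leave-one-out RMSECV over 1..`maxLV`;
#' ties are broken toward fewer latent variables.
#'
#' @param X Samples x bands matrix.
#' @param y FP values, mg/g.
#' @param maxLV Largest latent-variable count examined (capped at
#'   min(n - 1, p)).
#' @param wavelength Band centres; defaults to column names of `X`.
#' @return A [PLSModel-class] whose `cv` slot records RMSECV per LV.
#' @export
plsFit <- function(X, y, maxLV = 15L,
                   wavelength = as.numeric(colnames(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  A <- min(maxLV, n - 1, ncol(X))
  loo <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    fit <- .plsCore(X[-i, , drop = FALSE], y[-i], A)
    xc <- X[i, ] - fit$xMean
    loo[i, ] <- as.numeric(xc %*% fit$B) + fit$yMean
  }
  rmsecv <- sqrt(colMeans((loo - y)^2))
  chosen <- which(rmsecv <= min(rmsecv) + 1e-12)[1]
  cv <- new("CVResult", candidates = data.frame(n_lv = seq_len(A)),
            rmsecv = rmsecv, chosen = as.integer(chosen))
  full <- .plsCore(X, y, A)
  nLV <- min(chosen, full$achieved)
  if (length(wavelength) != ncol(X) || anyNA(wavelength))
    wavelength <- seq_len(ncol(X))
  new("PLSModel", nLV = as.integer(nLV), xMean = full$xMean,
      yMean = full$yMean, weights = full$W, loadings = full$P,
      yLoadings = full$q, coef = full$B[, nLV],
      wavelength = as.numeric(wavelength), cv = cv)
}

#' Predict FP from spectra with a PLS model
#'
#' @param object A [PLSModel-class].
#' @param newdata Samples x bands matrix (or single spectrum).
#' @param ... Ignored.
#' @return Numeric predictions, mg/g.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
             else as.matrix(newdata)
  if (ncol(newdata) != length(object@coef))
    stop("band count mismatch: model has ", length(object@coef), " bands")
  as.numeric(sweep(newdata, 2, object@xMean) %*% object@coef + object@yMean)
})

#' @rdname refit
setMethod("refit", "PLSModel", function(object, X, y) {
  full <- .plsCore(as.matrix(X), y, object@nLV)
  nLV <- min(object@nLV, full$achieved)
  new("PLSModel", nLV = as.integer(nLV), xMean = full$xMean,
      yMean = full$yMean, weights = full$W, loadings = full$P,
      yLoadings = full$q, coef = full$B[, nLV],
      wavelength = object@wavelength, cv = object@cv)
})

# ---- LS-SVM (RBF) -----------------------------------------------------------

# RBF kernel, LS-SVMlab convention: exp(-||xi - xj||^2 / sig2).
.rbfKernel <- function(X1, X2, sig2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-pmax(d2, 0) / sig2)
}

# Solve the LS-SVM dual (KKT) system
#   [ 0   1' ] [ b     ]   [ 0 ]
#   [ 1  K+I/gam ] [ alpha ] = [ y ]
.lssvmSolve <- function(K, y, gam) {
  n <- length(y)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gam))
  sol <- tryCatch(solve(A, c(0, y)),
                  error = function(e) stop("singular LS-SVM system: ",
                                           conditionMessage(e)))
  resid <- A %*% sol - c(0, y)
  list(bias = sol[1], alpha = sol[-1],
       kkt = max(abs(resid)) / max(1, max(abs(sol))))
}

#' Fit an LS-SVM calibration with grid-searched (gam, sig2)
#'
#' Least-squares support vector regression with RBF kernel
#' `exp(-||xi - xj||^2 / sig2)`. For every candidate pair the dual
#' linear system is solved and scored by leave-one-out RMSECV; the best
#' pair (ties toward smaller gam, then sig2) is refined once on a
#' narrower log-spaced grid around it, then refitted on all data.
#'
#' @param X Samples x bands matrix.
#' @param y FP values, mg/g.
#' @param gamGrid,sig2Grid Positive candidate grids (log-spaced by
#'   default, matching the magnitudes typical of reflectance data).
#' @param refine Run the second-stage local refinement.
#' @param wavelength Band centres; defaults to column names of `X`.
#' @return An [LSSVMModel-class].
#' @export
lssvmFit <- function(X, y, gamGrid = 10^(0:7), sig2Grid = 10^(0:6),
                     refine = TRUE, wavelength = as.numeric(colnames(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  if (length(gamGrid) == 0 || length(sig2Grid) == 0 ||
      any(gamGrid <= 0) || any(sig2Grid <= 0))
    stop("gam and sig2 grids must be non-empty and positive")
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  d2 <- pmax(d2, 0)
  looRmse <- function(gam, sig2) {
    K <- exp(-d2 / sig2)
    err <- numeric(n)
    for (i in seq_len(n)) {
      s <- .lssvmSolve(K[-i, -i, drop = FALSE], y[-i], gam)
      err[i] <- sum(K[i, -i] * s$alpha) + s$bias - y[i]
    }
    sqrt(mean(err^2))
  }
  evalGrid <- function(gams, sig2s) {
    cand <- expand.grid(gam = sort(gams), sig2 = sort(sig2s))
    cand <- cand[order(cand$gam, cand$sig2), ]
    r <- mapply(function(g, s) tryCatch(looRmse(g, s),
                                        error = function(e) Inf),
                cand$gam, cand$sig2)
    list(cand = cand, rmsecv = as.numeric(r))
  }
  g1 <- evalGrid(gamGrid, sig2Grid)
  best <- which(g1$rmsecv <= min(g1$rmsecv) + 1e-12)[1]
  cand <- g1$cand; rmsecv <- g1$rmsecv
  if (refine && length(gamGrid) > 1 && length(sig2Grid) > 1) {
    g0 <- g1$cand$gam[best]; s0 <- g1$cand$sig2[best]
    fac <- 10^seq(-0.5, 0.5, by = 0.25)
    g2 <- evalGrid(g0 * fac, s0 * fac)
    cand <- rbind(cand, g2$cand)
    rmsecv <- c(rmsecv, g2$rmsecv)
  }
  ord <- order(cand$gam, cand$sig2)
  cand <- cand[ord, , drop = FALSE]; rmsecv <- rmsecv[ord]
  dup <- duplicated(cand)
  cand <- cand[!dup, , drop = FALSE]; rmsecv <- rmsecv[!dup]
  rownames(cand) <- NULL
  chosen <- which(rmsecv <= min(rmsecv) + 1e-12)[1]
  cv <- new("CVResult", candidates = cand, rmsecv = rmsecv,
            chosen = as.integer(chosen))
  gam <- cand$gam[chosen]; sig2 <- cand$sig2[chosen]
  s <- .lssvmSolve(exp(-d2 / sig2), y, gam)
  if (length(wavelength) != ncol(X) || anyNA(wavelength))
    wavelength <- seq_len(ncol(X))
  new("LSSVMModel", alpha = s$alpha, bias = s$bias, gam = gam, sig2 = sig2,
      Xtrain = X, kktResidual = s$kkt, wavelength = as.numeric(wavelength),
      cv = cv)
}

#' Predict FP from spectra with an LS-SVM model
#'
#' @param object An [LSSVMModel-class].
#' @param newdata Samples x bands matrix (or single spectrum).
#' @param ... Ignored.
#' @return Numeric predictions, mg/g.
#' @export
setMethod("predict", "LSSVMModel", function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
             else as.matrix(newdata)
  if (ncol(newdata) != ncol(object@Xtrain))
    stop("band count mismatch: model has ", ncol(object@Xtrain), " bands")
  K <- .rbfKernel(newdata, object@Xtrain, object@sig2)
  as.numeric(K %*% object@alpha + object@bias)
})

#' @rdname refit
setMethod("refit", "LSSVMModel", function(object, X, y) {
  X <- as.matrix(X)
  K <- .rbfKernel(X, X, object@sig2)
  s <- .lssvmSolve(K, y, object@gam)
  new("LSSVMModel", alpha = s$alpha, bias = s$bias, gam = object@gam,
      sig2 = object@sig2, Xtrain = X, kktResidual = s$kkt,
      wavelength = object@wavelength, cv = object@cv)
})

# ---- ELM --------------------------------------------------------------------

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Random hidden layer for up to nMax nodes, drawn uniform(-1, 1) from the
# seed. Node count k uses the first k rows, so models are nested in k and
# fully reproducible from (seed, nMax, p).
.elmLayer <- function(seed, nMax, p) {
  .withSeed(seed, {
    W <- matrix(stats::runif(nMax * p, -1, 1), nMax, p)
    b <- stats::runif(nMax, -1, 1)
    list(W = W, b = b)
  })
}

# Min-norm least-squares output weights and exact LOO residuals via the
# hat-matrix identity e_loo = e / (1 - h); h from the thin SVD. The
# identity is exact for the unregularised least-squares refit as long as
# H has full column rank on every fold.
.elmSolve <- function(H, y) {
  sv <- svd(H)
  tol <- max(dim(H)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  if (!any(pos)) return(NULL)
  U <- sv$u[, pos, drop = FALSE]
  beta <- sv$v[, pos, drop = FALSE] %*% ((crossprod(U, y)) / sv$d[pos])
  h <- rowSums(U^2)
  e <- y - H %*% beta
  looE <- ifelse(1 - h < 1e-10, Inf, e / (1 - h))
  list(beta = as.numeric(beta), loo = as.numeric(looE),
       fitted = as.numeric(H %*% beta), rank = sum(pos))
}

#' Fit an ELM calibration with node-count selection
#'
#' Extreme learning machine: random input weights and biases (uniform on
#' (-1, 1), generated from `seed` and never trained), sigmoid hidden
#' layer, least-squares output weights. Candidate node counts span
#' `nodeRange` (by default 1..n, the training-set size); the default
#' criterion is leave-one-out RMSECV. `criterion = "rmsep"` instead picks
#' the node count minimising RMSE on a supplied prediction set - the
#' historical selection rule for this assay, kept behind a switch because
#' it lets the held-out set leak into model choice.
#'
#' @param X Samples x bands matrix.
#' @param y FP values, mg/g.
#' @param seed Integer seed for the random layer.
#' @param nodeRange Candidate hidden-node counts, within [1, n].
#' @param criterion "loocv" (default) or "rmsep".
#' @param Xpred,ypred Prediction set, required for `criterion = "rmsep"`.
#' @param wavelength Band centres; defaults to column names of `X`.
#' @return An [ELMModel-class]; `cv` records the criterion value per
#'   candidate node count.
#' @export
elmFit <- function(X, y, seed = 1L, nodeRange = seq_len(nrow(X)),
                   criterion = c("loocv", "rmsep"),
                   Xpred = NULL, ypred = NULL,
                   wavelength = as.numeric(colnames(X))) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  nodeRange <- sort(unique(as.integer(nodeRange)))
  if (length(nodeRange) == 0) stop("empty node range")
  if (any(nodeRange < 1) || any(nodeRange > n))
    stop("nodeRange must lie within [1, n]")
  if (criterion == "rmsep" && (is.null(Xpred) || is.null(ypred)))
    stop("criterion = 'rmsep' needs Xpred and ypred")
  layer <- .elmLayer(seed, max(nodeRange), p)
  H <- .sigmoid(X %*% t(layer$W) + matrix(layer$b, n, max(nodeRange),
                                          byrow = TRUE))
  score <- numeric(length(nodeRange))
  for (j in seq_along(nodeRange)) {
    k <- nodeRange[j]
    s <- .elmSolve(H[, 1:k, drop = FALSE], y)
    if (is.null(s)) { score[j] <- Inf; next }
    if (criterion == "loocv") {
      score[j] <- sqrt(mean(s$loo^2))
    } else {
      Hp <- .sigmoid(as.matrix(Xpred) %*% t(layer$W[1:k, , drop = FALSE]) +
                       matrix(layer$b[1:k], nrow(as.matrix(Xpred)), k,
                              byrow = TRUE))
      score[j] <- sqrt(mean((Hp %*% s$beta - ypred)^2))
    }
  }
  chosen <- which(score <= min(score) + 1e-12)[1]
  k <- nodeRange[chosen]
  s <- .elmSolve(H[, 1:k, drop = FALSE], y)
  cv <- new("CVResult", candidates = data.frame(n_nodes = nodeRange),
            rmsecv = score, chosen = as.integer(chosen))
  if (length(wavelength) != p || anyNA(wavelength)) wavelength <- seq_len(p)
  new("ELMModel", nNodes = as.integer(k),
      inputWeights = layer$W[1:k, , drop = FALSE],
      inputBias = layer$b[1:k], outputWeights = s$beta,
      seed = as.integer(seed), wavelength = as.numeric(wavelength), cv = cv)
}

#' Predict FP from spectra with an ELM model
#'
#' @param object An [ELMModel-class].
#' @param newdata Samples x bands matrix (or single spectrum).
#' @param ... Ignored.
#' @return Numeric predictions, mg/g.
#' @export
setMethod("predict", "ELMModel", function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
             else as.matrix(newdata)
  if (ncol(newdata) != ncol(object@inputWeights))
    stop("band count mismatch: model has ", ncol(object@inputWeights),
         " bands")
  H <- .sigmoid(newdata %*% t(object@inputWeights) +
                  matrix(object@inputBias, nrow(newdata), object@nNodes,
                         byrow = TRUE))
  as.numeric(H %*% object@outputWeights)
})

#' @rdname refit
setMethod("refit", "ELMModel", function(object, X, y) {
  X <- as.matrix(X)
  H <- .sigmoid(X %*% t(object@inputWeights) +
                  matrix(object@inputBias, nrow(X), object@nNodes,
                         byrow = TRUE))
  s <- .elmSolve(H, y)
  if (is.null(s)) stop("degenerate hidden layer on refit")
  methods::initialize(object, outputWeights = s$beta)
})

# ---- Generic leave-one-out cross-validation ---------------------------------

#' Leave-one-out RMSECV of an arbitrary fit procedure
#'
#' For each sample: refit on the remainder, predict the left-out sample.
#' `fitPredict(Xtrain, ytrain, xtest)` may return one prediction per
#' candidate model, in which case one RMSECV per candidate is returned.
#' A fit failure on any fold is propagated with the fold index.
#'
#' @param fitPredict Function (Xtrain, ytrain, xtest) -> prediction(s).
#' @param X Samples x bands matrix.
#' @param y Response values.
#' @return Numeric RMSECV (one value per candidate).
#' @export
loocvRmsecv <- function(fitPredict, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  preds <- NULL
  for (i in seq_len(n)) {
    p_i <- tryCatch(
      fitPredict(X[-i, , drop = FALSE], y[-i], X[i, , drop = FALSE]),
      error = function(e) stop("fit failed on fold ", i, ": ",
                               conditionMessage(e)))
    if (is.null(preds)) preds <- matrix(NA_real_, n, length(p_i))
    preds[i, ] <- p_i
  }
  sqrt(colMeans((preds - y)^2))
}
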