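test_that("full-rank PLS reproduces the least-squares solution", {
  set.seed(1)
  X <- matrix(rnorm(50), 10, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(10, 0, 0.1)
  m <- plsFit(X, y, maxLV = 5)
  bOLS <- unname(coef(lm(y ~ X)))
  full <- hyperFP:::.plsCore(X, y, 5)
  expect_equal(unname(full$B[, 5]), bOLS[-1], tolerance = 1e-8)
  expect_equal(full$yMean - sum(full$B[, 5] * full$xMean), bOLS[1],
               tolerance = 1e-8)
})

test_that("an exact one-component system is solved with one LV", {
  set.seed(2)
  X <- outer(rnorm(12), c(1, 2, 3))      # rank-1 spectra
  y <- 2 * X[, 2]
  m <- plsFit(X, y, maxLV = 3)
  expect_equal(m@nLV, 1L)
  expect_lt(cvResult(m)@rmsecv[cvResult(m)@chosen], 1e-10)
  expect_equal(predict(m, X), y, tolerance = 1e-10)
})

test_that("reported RMSECV equals a brute-force leave-one-out loop", {
  set.seed(3)
  X <- matrix(rnorm(80), 10, 8)
  y <- rnorm(10)
  m <- plsFit(X, y, maxLV = 4)
  for (a in 1:4) {
    brute <- loocvRmsecv(function(Xtr, ytr, xte) {
      fit <- hyperFP:::.plsCore(Xtr, ytr, a)
      drop((xte - fit$xMean) %*% fit$B[, a]) + fit$yMean
    }, X, y)
    expect_equal(cvResult(m)@rmsecv[a], brute, tolerance = 1e-12)
  }
})

test_that("PLS predictions are an affine map centred on the training data", {
  set.seed(4)
  X <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12)
  m <- plsFit(X, y, maxLV = 3)
  expect_equal(predict(m, colMeans(X)), mean(y), tolerance = 1e-12)
  a <- 0.35
  x1 <- X[1, ]; x2 <- X[2, ]
  expect_equal(predict(m, a * x1 + (1 - a) * x2),
               a * predict(m, x1) + (1 - a) * predict(m, x2),
               tolerance = 1e-12)
  expect_error(predict(m, matrix(0, 1, 4)), "band count mismatch")
})

test_that("PLS training error is non-increasing in the LV count", {
  set.seed(5)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  full <- hyperFP:::.plsCore(X, y, 8)
  rmse <- vapply(1:8, function(a) {
    pred <- drop(sweep(X, 2, full$xMean) %*% full$B[, a]) + full$yMean
    sqrt(mean((pred - y)^2))
  }, 0)
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("PLS rejects degenerate inputs", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(plsFit(X, rep(1, 10), maxLV = 2), "constant response")
  expect_error(plsFit(matrix(1, 10, 3), rnorm(10), maxLV = 2),
               "zero variance")
  expect_error(plsFit(X[1:2, ], rnorm(2), maxLV = 1), "at least 3")
})

test_that("LS-SVM solution matches a direct dense KKT solve", {
  set.seed(6)
  X <- matrix(rnorm(25), 5, 5)
  y <- rnorm(5)
  gam <- 50; sig2 <- 8
  m <- lssvmFit(X, y, gamGrid = gam, sig2Grid = sig2, refine = FALSE)
  # independent oracle: assemble and solve the bordered system directly
  D2 <- as.matrix(dist(X))^2
  K <- exp(-D2 / sig2)
  A <- rbind(c(0, rep(1, 5)), cbind(1, K + diag(5) / gam))
  sol <- solve(A, c(0, y))
  expect_equal(m@bias, unname(sol[1]), tolerance = 1e-10)
  expect_equal(m@alpha, unname(sol[-1]), tolerance = 1e-10)
  expect_lte(m@kktResidual, 1e-8)
})

test_that("LS-SVM approaches interpolation and the mean in the gam limits", {
  set.seed(7)
  X <- matrix(rnorm(25), 5, 5)
  y <- rnorm(5)
  hard <- lssvmFit(X, y, gamGrid = 1e8, sig2Grid = 10, refine = FALSE)
  expect_lt(max(abs(predict(hard, X) - y)), 1e-4)
  soft <- lssvmFit(X, y, gamGrid = 1e-6, sig2Grid = 10, refine = FALSE)
  expect_equal(predict(soft, X), rep(mean(y), 5), tolerance = 1e-4)
})

test_that("LS-SVM cross-validation matches the brute-force double loop", {
  set.seed(8)
  X <- matrix(rnorm(32), 8, 4)
  y <- rnorm(8)
  gam <- 20; sig2 <- 5
  m <- lssvmFit(X, y, gamGrid = gam, sig2Grid = sig2, refine = FALSE)
  brute <- loocvRmsecv(function(Xtr, ytr, xte) {
    K <- exp(-as.matrix(dist(Xtr))^2 / sig2)
    A <- rbind(c(0, rep(1, nrow(Xtr))), cbind(1, K + diag(nrow(Xtr)) / gam))
    sol <- solve(A, c(0, ytr))
    k <- exp(-colSums((t(Xtr) - drop(xte))^2) / sig2)
    sum(k * sol[-1]) + sol[1]
  }, X, y)
  expect_equal(cvResult(m)@rmsecv[cvResult(m)@chosen], brute,
               tolerance = 1e-10)
  expect_error(lssvmFit(X, y, gamGrid = numeric(0), sig2Grid = 1),
               "non-empty")
  expect_error(lssvmFit(X, y, gamGrid = -1, sig2Grid = 1), "positive")
})

test_that("the chosen LS-SVM hyperparameters are reported as two scalars", {
  set.seed(9)
  X <- matrix(rnorm(40), 10, 4)
  y <- drop(X %*% rnorm(4))
  m <- lssvmFit(X, y, gamGrid = 10^(0:3), sig2Grid = 10^(0:2))
  expect_true(m@gam > 0 && m@sig2 > 0)
  expect_length(m@gam, 1)
  expect_length(m@sig2, 1)
})

test_that("ELM is deterministic in its seed and can interpolate", {
  set.seed(10)
  X <- matrix(rnorm(40), 8, 5)
  y <- rnorm(8)
  e1 <- elmFit(X, y, seed = 7)
  e2 <- elmFit(X, y, seed = 7)
  expect_identical(e1@outputWeights, e2@outputWeights)
  expect_identical(e1@nNodes, e2@nNodes)
  full <- elmFit(X, y, seed = 7, nodeRange = 8)
  expect_lt(sqrt(mean((predict(full, X) - y)^2)), 1e-6)
})

test_that("ELM leave-one-out shortcut equals the brute-force refit loop", {
  set.seed(11)
  X <- matrix(rnorm(32), 8, 4)
  y <- rnorm(8)
  m <- elmFit(X, y, seed = 3, nodeRange = 1:6)
  for (k in c(2, 4)) {
    layer <- hyperFP:::.elmLayer(3, 6, 4)
    brute <- loocvRmsecv(function(Xtr, ytr, xte) {
      H <- hyperFP:::.sigmoid(Xtr %*% t(layer$W[1:k, , drop = FALSE]) +
        matrix(layer$b[1:k], nrow(Xtr), k, byrow = TRUE))
      s <- hyperFP:::.elmSolve(H, ytr)
      Hp <- hyperFP:::.sigmoid(xte %*% t(layer$W[1:k, , drop = FALSE]) +
        matrix(layer$b[1:k], 1, k, byrow = TRUE))
      drop(Hp %*% s$beta)
    }, X, y)
    expect_equal(cvResult(m)@rmsecv[k], brute, tolerance = 1e-10)
  }
})

test_that("ELM explores node counts up to the training-set size", {
  set.seed(12)
  X <- matrix(rnorm(75 * 4), 75, 4)
  y <- drop(X %*% rnorm(4)) + rnorm(75, 0, 0.1)
  m <- elmFit(X, y, seed = 1)
  expect_equal(cvResult(m)@candidates$n_nodes, 1:75)
  expect_error(elmFit(X, y, nodeRange = integer(0)), "empty node range")
  expect_error(elmFit(X, y, nodeRange = 80), "within")
})

test_that("ELM paper-literal mode selects nodes by prediction-set RMSE", {
  set.seed(13)
  X <- matrix(rnorm(60), 15, 4)
  y <- drop(X %*% rnorm(4)) + rnorm(15, 0, 0.05)
  Xp <- matrix(rnorm(20), 5, 4)
  yp <- rnorm(5)
  m <- elmFit(X, y, seed = 2, nodeRange = 1:10, criterion = "rmsep",
              Xpred = Xp, ypred = yp)
  k <- m@nNodes
  rmsep <- sqrt(mean((predict(m, Xp) - yp)^2))
  expect_equal(cvResult(m)@rmsecv[cvResult(m)@chosen], rmsep,
               tolerance = 1e-10)
  expect_error(elmFit(X, y, criterion = "rmsep"), "needs Xpred")
})

test_that("a constant-mean predictor attains the closed-form RMSECV", {
  y <- c(0, 1, 2)
  got <- loocvRmsecv(function(Xtr, ytr, xte) mean(ytr),
                     matrix(0, 3, 1) + seq_len(3), y)
  expect_equal(got, sqrt(1.5), tolerance = 1e-12)  # sd(y) * sqrt(n/(n-1))
})

test_that("engines are invariant to training-sample order", {
  set.seed(14)
  X <- matrix(rnorm(48), 12, 4)
  y <- drop(X %*% rnorm(4)) + rnorm(12, 0.05)
  perm <- sample(12)
  xnew <- matrix(rnorm(8), 2, 4)
  p1 <- plsFit(X, y, maxLV = 3)
  p2 <- plsFit(X[perm, ], y[perm], maxLV = 3)
  expect_equal(predict(p1, xnew), predict(p2, xnew), tolerance = 1e-9)
  l1 <- lssvmFit(X, y, gamGrid = 100, sig2Grid = 10, refine = FALSE)
  l2 <- lssvmFit(X[perm, ], y[perm], gamGrid = 100, sig2Grid = 10,
                 refine = FALSE)
  expect_equal(predict(l1, xnew), predict(l2, xnew), tolerance = 1e-9)
  e1 <- elmFit(X, y, seed = 5, nodeRange = 4)
  e2 <- elmFit(X[perm, ], y[perm], seed = 5, nodeRange = 4)
  expect_equal(predict(e1, xnew), predict(e2, xnew), tolerance = 1e-9)
})
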