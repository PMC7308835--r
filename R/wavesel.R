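#' @include AllClasses.R
NULL

# PLS regression-coefficient vector at a fixed LV count (no CV), used
# inside the selection loops.
.plsCoef <- function(X, y, maxLV) {
  fit <- .plsCore(X, y, maxLV)
  fit$B[, min(maxLV, fit$achieved)]
}

# LOO-RMSECV of a PLS model on a band subset, minimised over 1..maxLV.
.plsSubsetRmsecv <- function(X, y, idx, maxLV) {
  Xs <- X[, idx, drop = FALSE]
  A <- min(maxLV, nrow(Xs) - 1, ncol(Xs))
  n <- nrow(Xs)
  loo <- matrix(NA_real_, n, A)
  for (i in seq_len(n)) {
    fit <- .plsCore(Xs[-i, , drop = FALSE], y[-i], A)
    loo[i, ] <- as.numeric((Xs[i, ] - fit$xMean) %*% fit$B) + fit$yMean
  }
  min(sqrt(colMeans((loo - y)^2)))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength elimination: at iteration i a PLS model is fitted
#' on a Monte Carlo subset of the samples, bands are ranked by the
#' absolute regression coefficient |b|, the retained fraction follows the
#' exponentially decreasing function r_i = a exp(-k i) with constants
#' fixed by r_1 = 1 and r_N = 2/p, and adaptive reweighted sampling
#' (weighted by |b|, with replacement) competitively eliminates further
#' bands among the survivors. Each iteration's retained set is scored by
#' the leave-one-out RMSECV of a PLS model on all samples; the set with
#' the minimum RMSECV over the whole trace is returned.
#'
#' @param X Samples x bands matrix.
#' @param y FP values, mg/g.
#' @param nIterations Number of elimination iterations (>= 2).
#' @param mcRatio Fraction of samples drawn per Monte Carlo run.
#' @param maxLV Largest LV count for the internal PLS models.
#' @param seed Integer seed for all sampling.
#' @param wavelength Band centres; defaults to column names of `X`.
#' @return A [SelectionResult-class]; `trace` has columns iteration,
#'   n_retained, rmsecv.
#' @export
carsSelect <- function(X, y, nIterations = 50L, mcRatio = 0.8,
                       maxLV = 10L, seed = 1L,
                       wavelength = as.numeric(colnames(X))) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (nIterations < 2) stop("nIterations must be >= 2")
  if (p < 2) stop("need at least 2 bands")
  if (length(wavelength) != p || anyNA(wavelength)) wavelength <- seq_len(p)
  # EDF constants from the boundary conditions r_1 = 1, r_N = 2/p
  k <- log(p / 2) / (nIterations - 1)
  a <- exp(k)
  .withSeed(seed, {
    retained <- seq_len(p)
    sets <- vector("list", nIterations)
    trace <- data.frame(iteration = seq_len(nIterations),
                        n_schedule = NA_integer_,
                        n_retained = NA_integer_, rmsecv = NA_real_)
    for (i in seq_len(nIterations)) {
      m <- max(3, ceiling(mcRatio * n))
      mc <- sample.int(n, m)
      b <- .plsCoef(X[mc, retained, drop = FALSE], y[mc],
                    min(maxLV, m - 1, length(retained)))
      w <- abs(b)
      keepN <- max(2, round(a * exp(-k * i) * p))
      keepN <- min(keepN, length(retained))
      forced <- retained[order(w, decreasing = TRUE)[seq_len(keepN)]]
      wF <- w[match(forced, retained)]
      if (sum(wF) <= 0) wF <- rep(1, length(forced))
      ars <- unique(sample(forced, size = keepN, replace = TRUE,
                           prob = wF / sum(wF)))
      # competitive sampling may whittle below the schedule's floor of
      # two variables; keep the top-2 by weight rather than eliminate all
      if (length(ars) < 2)
        ars <- forced[order(wF, decreasing = TRUE)[1:2]]
      retained <- sort(ars)
      if (length(retained) == 0)
        stop("all bands eliminated at iteration ", i)
      sets[[i]] <- retained
      trace$n_schedule[i] <- keepN
      trace$n_retained[i] <- length(retained)
      trace$rmsecv[i] <- .plsSubsetRmsecv(X, y, retained, maxLV)
    }
    best <- which(trace$rmsecv <= min(trace$rmsecv) + 1e-12)[1]
    idx <- sets[[best]]
    new("SelectionResult", method = "CARS", indices = as.integer(idx),
        wavelength = wavelength[idx], trace = trace,
        seed = as.integer(seed))
  })
}

#' Characteristic wavelengths from the PLS coefficient profile (Bw)
#'
#' Takes the signed regression-coefficient vector of a fitted PLS model
#' and returns the bands at its strict interior local maxima (peaks) and
#' strict local minima (valleys); plateaus are excluded. Optionally the
#' extrema are further filtered to those whose |b| exceeds a quantile of
#' the full |b| profile.
#'
#' @param model A fitted [PLSModel-class].
#' @param quantile Quantile of |b| below which extrema are dropped
#'   (0 = keep all extrema).
#' @return A [SelectionResult-class]; `trace` carries the coefficient
#'   profile.
#' @export
bwSelect <- function(model, quantile = 0) {
  stopifnot(is(model, "PLSModel"))
  b <- model@coef
  p <- length(b)
  if (p < 3) stop("need at least 3 bands")
  if (max(b) - min(b) < 1e-15) stop("constant coefficient vector: no extrema")
  i <- 2:(p - 1)
  peaks <- i[b[i] > b[i - 1] & b[i] > b[i + 1]]
  valleys <- i[b[i] < b[i - 1] & b[i] < b[i + 1]]
  idx <- sort(unique(c(peaks, valleys)))
  if (quantile > 0) {
    thr <- stats::quantile(abs(b), quantile)
    idx <- idx[abs(b[idx]) >= thr]
  }
  if (length(idx) == 0) stop("no extrema found")
  new("SelectionResult", method = "Bw", indices = as.integer(idx),
      wavelength = model@wavelength[idx],
      trace = data.frame(index = seq_len(p),
                         wavelength_nm = model@wavelength, coef = b),
      seed = NA_integer_)
}

#' Genetic-algorithm wavelength selection
#'
#' Binary chromosomes over the bands; fitness is the negative
#' leave-one-out RMSECV of a PLS model restricted to the encoded bands
#' (all-zero chromosomes get -Inf and are never returned). Tournament
#' selection (size 2), single-point crossover, per-gene bit-flip
#' mutation and elitism of one.
#'
#' @param X Samples x bands matrix.
#' @param y FP values, mg/g.
#' @param popSize Population size (even, >= 4).
#' @param nGenerations Generations to run.
#' @param pCrossover,pMutation Crossover and per-gene mutation rates.
#' @param initProb Per-gene inclusion probability of the random initial
#'   population.
#' @param maxLV Largest LV count for the fitness PLS models.
#' @param seed Integer seed.
#' @param initialPopulation Optional popSize x p 0/1 matrix overriding
#'   the random initialisation.
#' @param wavelength Band centres; defaults to column names of `X`.
#' @return A [SelectionResult-class]; `trace` has columns generation,
#'   best_fitness, n_selected.
#' @export
gaSelect <- function(X, y, popSize = 30L, nGenerations = 100L,
                     pCrossover = 0.6, pMutation = 0.01, initProb = 0.3,
                     maxLV = 10L, seed = 1L, initialPopulation = NULL,
                     wavelength = as.numeric(colnames(X))) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (popSize < 4 || popSize %% 2 != 0) stop("popSize must be even and >= 4")
  if (length(wavelength) != p || anyNA(wavelength)) wavelength <- seq_len(p)
  cache <- new.env(parent = emptyenv())
  fitness <- function(chrom) {
    if (!any(chrom)) return(-Inf)
    key <- paste(which(chrom), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- tryCatch(-.plsSubsetRmsecv(X, y, which(chrom), maxLV),
                  error = function(e) -Inf)
    cache[[key]] <- f
    f
  }
  .withSeed(seed, {
    if (is.null(initialPopulation)) {
      pop <- matrix(stats::runif(popSize * p) < initProb, popSize, p)
      for (r in seq_len(popSize))
        while (!any(pop[r, ])) pop[r, ] <- stats::runif(p) < initProb
    } else {
      pop <- initialPopulation > 0
      stopifnot(nrow(pop) == popSize, ncol(pop) == p)
    }
    fit <- apply(pop, 1, fitness)
    trace <- data.frame(generation = seq_len(nGenerations),
                        best_fitness = NA_real_, n_selected = NA_integer_)
    for (g in seq_len(nGenerations)) {
      elite <- pop[which.max(fit), ]
      newPop <- matrix(FALSE, popSize, p)
      for (j in seq(1, popSize, by = 2)) {
        pick <- function() {
          c2 <- sample.int(popSize, 2)
          pop[c2[which.max(fit[c2])], ]
        }
        c1 <- pick(); c2 <- pick()
        if (stats::runif(1) < pCrossover && p > 1) {
          cut <- sample.int(p - 1, 1)
          tmp <- c1
          c1 <- c(c1[1:cut], c2[(cut + 1):p])
          c2 <- c(c2[1:cut], tmp[(cut + 1):p])
        }
        flip1 <- stats::runif(p) < pMutation
        flip2 <- stats::runif(p) < pMutation
        newPop[j, ] <- xor(c1, flip1)
        newPop[j + 1, ] <- xor(c2, flip2)
      }
      newPop[1, ] <- elite  # elitism of one
      pop <- newPop
      fit <- apply(pop, 1, fitness)
      trace$best_fitness[g] <- max(fit)
      trace$n_selected[g] <- sum(pop[which.max(fit), ])
    }
    best <- pop[which.max(fit), ]
    idx <- which(best)
    new("SelectionResult", method = "GA", indices = as.integer(idx),
        wavelength = wavelength[idx], trace = trace,
        seed = as.integer(seed))
  })
}
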