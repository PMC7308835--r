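#' @include AllClasses.R
NULL

#' Rank-based 3:1 calibration/prediction split
#'
#' Samples are ranked from low to high response; within each consecutive
#' block of four, the third goes to the prediction set and the rest to
#' calibration. A trailing partial block goes entirely to calibration,
#' which keeps the prediction set interior to the calibration range.
#' The split depends only on the values of `y` (ties broken by original
#' index), not on input order.
#'
#' @param y Response values (n >= 4).
#' @param blockSize Block length (position `blockSize - 1` is held out).
#' @return List with sorted integer vectors `calibration`, `prediction`.
#' @examples
#' rankSplit(c(3, 1, 4, 2))$prediction   # the sample with y = 3
#' @export
rankSplit <- function(y, blockSize = 4L) {
  n <- length(y)
  if (n < blockSize) stop("need at least ", blockSize, " samples")
  ord <- order(y, seq_along(y))   # stable: ties by original index
  nBlocks <- n %/% blockSize
  predPos <- (seq_len(nBlocks) - 1) * blockSize + (blockSize - 1)
  pred <- ord[predPos]
  list(calibration = sort(setdiff(seq_len(n), pred)),
       prediction = sort(pred))
}

.safeCor <- function(a, b) {
  if (stats::sd(a) < 1e-14 || stats::sd(b) < 1e-14) {
    warning("constant predictions: correlation undefined, reported as 0")
    return(0)
  }
  stats::cor(a, b)
}

#' @rdname evaluateModel
setMethod("evaluateModel", "ANY", function(object, Xc, yc, Xp, yp) {
  Xc <- as.matrix(Xc); Xp <- as.matrix(Xp)
  if (nrow(Xp) == 0) stop("empty prediction set")
  n <- nrow(Xc)
  loo <- numeric(n)
  for (i in seq_len(n)) {
    m <- refit(object, Xc[-i, , drop = FALSE], yc[-i])
    loo[i] <- predict(m, Xc[i, , drop = FALSE])
  }
  predP <- predict(object, Xp)
  new("EvaluationReport",
      Rc = .safeCor(loo, yc),
      RMSECV = sqrt(mean((loo - yc)^2)),
      Rp = .safeCor(predP, yp),
      RMSEP = sqrt(mean((predP - yp)^2)),
      nCal = as.integer(n), nPred = as.integer(nrow(Xp)))
})

#' Per-wavelength one-way ANOVA profile
#'
#' For each band, a one-way fixed-effects ANOVA F-test of reflectance
#' against the grouping factor (by default Cd concentration within one
#' stress day). Bands with p < `alpha` are flagged as important
#' wavelengths. No multiple-testing correction is applied across bands.
#'
#' @param st A [SpectraTable-class].
#' @param day If non-NULL, restrict to samples of this stress day.
#' @param factor Grouping column: "cd_um" or "day".
#' @param alpha Significance level for the flag.
#' @return data.frame with columns wavelength_nm, f, p, significant.
#' @export
wavelengthAnova <- function(st, day = NULL, factor = "cd_um",
                            alpha = 0.05) {
  stopifnot(is(st, "SpectraTable"))
  lab <- groupLabels(st)
  keep <- if (is.null(day)) seq_len(nrow(lab)) else which(lab$day == day)
  g <- factor(lab[[factor]][keep])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("singleton group: ANOVA undefined")
  X <- spectraMatrix(st)[keep, , drop = FALSE]
  n <- nrow(X); kg <- nlevels(g)
  # vectorised one-way ANOVA across bands
  grand <- colMeans(X)
  ssb <- matrix(0, 1, ncol(X)); ssw <- matrix(0, 1, ncol(X))
  for (lev in levels(g)) {
    rows <- g == lev
    m <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - grand)^2
    ssw <- ssw + colSums(sweep(X[rows, , drop = FALSE], 2, m)^2)
  }
  df1 <- kg - 1; df2 <- n - kg
  f <- as.numeric((ssb / df1) / (ssw / df2))
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  data.frame(wavelength_nm = wavelengths(st), f = f, p = p,
             significant = p < alpha)
}

# Compact letter display from a logical "not significantly different"
# adjacency matrix: letters are the maximal cliques of the graph, so two
# groups share a letter exactly when their pairwise comparison is not
# significant. Cliques (and their letters) are ordered by descending
# group mean.
.cldFromAdjacency <- function(adj, means) {
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  cl <- igraph::max_cliques(gr)   # singletons are maximal cliques too
  cliqueMean <- vapply(cl, function(v) max(means[as.integer(v)]), 0)
  cl <- cl[order(cliqueMean, decreasing = TRUE)]
  letters_ <- letters[seq_along(cl)]
  out <- rep("", nrow(adj))
  for (j in seq_along(cl))
    for (v in as.integer(cl[[j]]))
      out[v] <- paste0(out[v], letters_[j])
  out
}

#' Tukey HSD compact letter display of treatment groups
#'
#' All-pairs comparisons of group means (Tukey honest significant
#' difference at level `alpha`) summarised as a compact letter display:
#' two groups share a letter if and only if their pairwise comparison is
#' not significant. Letters are assigned in order of decreasing group
#' mean ('a' = highest).
#'
#' @param values Numeric response values (e.g. FP, mg/g).
#' @param groups Group labels (coerced to factor).
#' @param alpha Significance level.
#' @return data.frame with columns group, n, mean, letters, plus the
#'   pairwise Tukey p-value matrix as attribute `p_matrix`.
#' @export
groupLetters <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("singleton group: post-hoc test undefined")
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  k <- nlevels(g)
  pmat <- matrix(1, k, k, dimnames = list(levels(g), levels(g)))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[r, "p adj"]
  }
  means <- tapply(values, g, mean)
  adj <- pmat >= alpha
  lets <- .cldFromAdjacency(adj, as.numeric(means))
  out <- data.frame(group = levels(g), n = as.integer(table(g)),
                    mean = as.numeric(means), letters = lets)
  attr(out, "p_matrix") <- pmat
  out
}

#' Format evaluation reports as a performance table
#'
#' @param reports Named list of [EvaluationReport-class] objects.
#' @param parameters Character vector of model-parameter descriptions
#'   (LV count, "gam; sig2", node count), same length as `reports`.
#' @return data.frame with columns Model, Parameter, Rc, RMSECV, Rp,
#'   RMSEP.
#' @export
reportTable <- function(reports, parameters = rep("", length(reports))) {
  data.frame(
    Model = names(reports),
    Parameter = parameters,
    Rc = vapply(reports, function(r) r@Rc, 0),
    RMSECV = vapply(reports, function(r) r@RMSECV, 0),
    Rp = vapply(reports, function(r) r@Rp, 0),
    RMSEP = vapply(reports, function(r) r@RMSEP, 0),
    row.names = NULL)
}
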