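test_that("rank split holds out the third of every block of four", {
  s <- rankSplit(rnorm(100))
  expect_length(s$calibration, 75)
  expect_length(s$prediction, 25)
  expect_length(intersect(s$calibration, s$prediction), 0)
  # single block: the sample ranked third is held out
  s4 <- rankSplit(c(3, 1, 4, 2))
  expect_equal(s4$prediction, 1L)   # y = 3 is the third smallest
  # trailing partial block goes to calibration
  s6 <- rankSplit(c(10, 20, 30, 40, 50, 60))
  expect_equal(s6$prediction, 3L)
  expect_error(rankSplit(1:3), "at least 4")
})

test_that("prediction-set values are interior to the calibration range", {
  set.seed(1)
  for (rep in 1:20) {
    y <- rnorm(4 * sample(2:30, 1) + sample(0:3, 1))
    s <- rankSplit(y)
    expect_gte(min(y[s$prediction]), min(y[s$calibration]))
    expect_lte(max(y[s$prediction]), max(y[s$calibration]))
  }
})

test_that("rank split depends only on values, not input order", {
  set.seed(2)
  y <- rnorm(41)
  perm <- sample(41)
  s1 <- rankSplit(y)
  s2 <- rankSplit(y[perm])
  expect_equal(sort(y[s1$prediction]), sort(y[perm][s2$prediction]))
  # ties broken by original index
  expect_equal(rankSplit(rep(1, 8))$prediction, c(3L, 7L))
})

test_that("evaluation reports the four figures of merit correctly", {
  # perfect linear system: every engine's report must show Rp = 1
  set.seed(3)
  X <- matrix(rnorm(100), 20, 5)
  y <- drop(X %*% c(1, 2, -1, 0.5, 0))
  s <- rankSplit(y)
  m <- plsFit(X[s$calibration, ], y[s$calibration], maxLV = 5)
  r <- evaluateModel(m, X[s$calibration, ], y[s$calibration],
                     X[s$prediction, ], y[s$prediction])
  expect_equal(r@Rp, 1, tolerance = 1e-8)
  expect_lt(r@RMSEP, 1e-8)
  expect_equal(r@nCal + r@nPred, 20L)
})

test_that("prediction-set errors follow the hand-computed RMSEP", {
  # stub engine with fixed predictions, exercising the generic path
  setClass("shiftModel", representation(shift = "numeric"),
           where = environment())
  setMethod("refit", "shiftModel", function(object, X, y) object,
            where = environment())
  setMethod("predict", "shiftModel", function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    newdata[, 1] + object@shift
  }, where = environment())
  m <- new("shiftModel", shift = 0)
  Xp <- matrix(c(0, 1, 3), 3, 1)   # predicts (0, 1, 3)
  r <- evaluateModel(m, matrix(c(0, 1, 2, 4), 4, 1), c(0, 1, 2, 4),
                     Xp, c(0, 1, 2))
  expect_equal(r@RMSEP, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(r@Rc, 1)
  expect_error(evaluateModel(m, matrix(0, 3, 1), 1:3,
                             matrix(0, 0, 1), numeric(0)),
               "empty prediction set")
})

test_that("constant predictors report R = 0 with a warning", {
  setClass("constModel", representation(value = "numeric"),
           where = environment())
  setMethod("refit", "constModel", function(object, X, y) object,
            where = environment())
  setMethod("predict", "constModel", function(object, newdata, ...)
    rep(object@value, nrow(as.matrix(newdata))), where = environment())
  m <- new("constModel", value = 0.5)
  # both Rc (LOO) and Rp are undefined, so the warning fires twice
  expect_warning(expect_warning(
    r <- evaluateModel(m, matrix(rnorm(8), 4, 2), rnorm(4),
                       matrix(rnorm(6), 3, 2), rnorm(3)),
    "constant predictions"), "constant predictions")
  expect_equal(r@Rp, 0)
})

test_that("two-group wavelength ANOVA reduces to the squared t test", {
  set.seed(4)
  X <- matrix(rnorm(12 * 6), 12, 6)
  st <- SpectraTable(X, seq(500, 900, length.out = 6),
                     fp = runif(12, 0.1, 0.2),
                     day = rep(5, 12), cd_um = rep(c(0, 100), each = 6))
  prof <- wavelengthAnova(st, day = 5)
  for (b in 1:6) {
    tt <- t.test(X[1:6, b], X[7:12, b], var.equal = TRUE)
    expect_equal(prof$f[b], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(prof$p[b], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(prof$significant, prof$p < 0.05)
})

test_that("wavelength ANOVA agrees with the stats::aov oracle", {
  st <- trimBands(defaultStudyTable(), c(600, 620))
  prof <- wavelengthAnova(st, day = 20)
  X <- spectraMatrix(trimBands(st, c(600, 620)))
  lab <- groupLabels(st)
  keep <- lab$day == 20
  g <- factor(lab$cd_um[keep])
  for (b in c(1, ncol(X))) {
    a <- summary(aov(X[keep, b] ~ g))[[1]]
    expect_equal(prof$f[b], a[["F value"]][1], tolerance = 1e-10)
    expect_equal(prof$p[b], a[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("spectral group differences broaden with stress time", {
  st <- defaultStudyTable()
  f5 <- mean(wavelengthAnova(st, day = 5)$significant)
  f20 <- mean(wavelengthAnova(st, day = 20)$significant)
  expect_gte(f20, f5)
  expect_error(wavelengthAnova(st[, 1:3], day = 5), "2 groups|singleton")
})

test_that("compact letter display matches the pairwise test matrix", {
  set.seed(5)
  vals <- c(rnorm(6, 0), rnorm(6, 0.2), rnorm(6, 5))
  grp <- rep(c("A", "B", "C"), each = 6)
  cld <- groupLetters(vals, grp)
  pm <- attr(cld, "p_matrix")
  # brute-force oracle: share a letter <=> pairwise comparison not
  # significant
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    share <- any(strsplit(cld$letters[i], "")[[1]] %in%
                   strsplit(cld$letters[j], "")[[1]])
    expect_equal(share, pm[cld$group[i], cld$group[j]] >= 0.05)
  }
})

test_that("letters collapse for identical groups and separate for distant ones", {
  set.seed(6)
  same <- groupLetters(rnorm(25, 0.15, 0.01), rep(1:5, each = 5))
  expect_true(all(same$letters == same$letters[1]))
  apart <- groupLetters(rnorm(25, rep(seq(0, 4, 1), each = 5), 0.1),
                        rep(1:5, each = 5))
  expect_setequal(apart$letters, c("a", "b", "c", "d", "e"))
  expect_error(groupLetters(rnorm(5), rep(1, 5)), "2 groups")
  expect_error(groupLetters(rnorm(3), c(1, 1, 2)), "singleton")
})

test_that("letter display agrees with the multcomp reference", {
  skip_if_not_installed("multcomp")
  set.seed(7)
  vals <- rnorm(20, rep(c(0, 0.05, 1, 1.02), each = 5), 0.08)
  grp <- factor(rep(c("g1", "g2", "g3", "g4"), each = 5))
  cld <- groupLetters(vals, grp)
  ref <- multcomp::cld(multcomp::glht(aov(vals ~ grp),
                                      linfct = multcomp::mcp(grp = "Tukey")))
  refLetters <- ref$mcletters$Letters[as.character(cld$group)]
  # same partition: groups share a letter in ours iff they do in multcomp
  for (i in 1:4) for (j in 1:4) {
    s1 <- any(strsplit(cld$letters[i], "")[[1]] %in%
                strsplit(cld$letters[j], "")[[1]])
    s2 <- any(strsplit(refLetters[i], "")[[1]] %in%
                strsplit(refLetters[j], "")[[1]])
    expect_equal(s1, s2)
  }
})
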